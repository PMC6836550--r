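# cytowgs

Whole-genome sequencing (WGS) as a first-line cytogenomic test, as an R
package. `cytowgs` is aimed at clinical-genomics developers and
methodologists who want the computational steps of a WGS-first workflow —
the analyses that let short-read WGS replace chromosomal microarray
analysis (CMA) — as tested, scriptable functions exercised entirely on
simulated data with known truth.

## What it does

* **Structural-variant call handling** — merge the calls of two
  complementary caller families (read-depth and discordant-pair) by
  single-linkage clustering (same SV type, breakpoints within 200 bp *or*
  reciprocal overlap ≥ 0.7); build and query SV frequency databases
  (carrier count / samples indexed); apply the clinical filtering cascade
  (size: intergenic > 10 kb, intragenic > 2 kb; quality: ≥ 6 discordant
  pairs or ≥ 5 kb; frequency: population AF ≤ 0.5%, internal AF < 1%;
  decoy removal) with gene-panel rescue of small exonic calls, and a
  per-stage rejection tally.
* **Array emulation** — export calls as an array-CGH-style XML probe
  document (log2(CN/2) on an 18-kb grid); call CNVs from probe series by
  the clinical consecutive-probe rule (≥ 3 probes beyond −0.65 / 0.35);
  interpret MLPA ratios (< 0.75 deletion, > 1.3 duplication); compare WGS
  and array call sets with direction-matched overlap.
* **Derivative chromosomes** — cluster SVs into rearrangements, walk the
  breakend graph to reconstruct derivative chromosomes (rings included),
  classify topology (`DEL-INV-DEL`, `reciprocal-translocation`,
  `insertional-translocation`, `ring`, ...), and analyze breakpoint
  junctions for microhomology, insertions and templated fragments,
  inferring formation mechanism (NHEJ-like / replicative-like /
  NAHR-like).
* **ROH / UPD** — windowed homozygous-SNV fraction tracks (10-kb
  windows), run-of-homozygosity calling, and uniparental-disomy
  classification from trio or duo genotypes (isodisomy vs heterodisomy,
  whole-chromosome vs segmental).
* **STR expansions** — repeat-unit genotyping from short reads: exact
  counts from spanning reads, and for expansions longer than the read
  length an in-repeat-read estimator, `L = r + n_irr · r / d` (read
  length `r`, per-allele coverage `d`), converted to repeat units. A
  17-gene screening catalog ships as editable JSON.
* **Mosaicism** — robust per-chromosome coverage ratios from depth bins;
  a ratio of `1 + f/2` inverts to the mosaic fraction `f = 2(ratio − 1)`.
* **Simulators** — seeded generators for every input above (caller
  outputs with stylized blind spots, probe series, SNV sites with planted
  UPD, STR reads, depth bins), each returning its truth record.

## Worked example

```r
library(cytowgs)

## STR: a proband carrying 10 and 233 CAG units in ATXN7, 30x, 151-bp reads
catalog <- read_str_catalog()
reads <- simulate_str_reads(catalog$ATXN7, alleles = c(10, 233),
                            depth = 30, seed = 42)
genotype_str(catalog$ATXN7, reads, depth = 30)
#> ATXN7: 10/242 (inrepeat-estimated) PATHOGENIC-RANGE [spanning reads: 7, in-repeat reads: 57]
```

The short allele is counted exactly from spanning reads; the expansion
exceeds the read length, so it is estimated from the 57 fully-in-repeat
reads (242 units here; the estimator is unbiased with ~10% spread per
genome at this depth) and flagged against the catalog threshold.

```r
## UPD: maternal segmental isodisomy 22.9-33.7 Mb on chromosome 15
len15 <- hg19_contigs()[["chr15"]]
sites <- simulate_snp_sites(len15,
  upd = list(start = 22.9e6, end = 33.7e6,
             parent = "maternal", kind = "isodisomy"),
  trio = TRUE, seed = 42)
roh <- call_roh(zygosity_track(sites, chrom_len = len15))
roh
#>      start      end n_windows mean_hom_fraction
#> 1 22900000 33700000      1075         0.9998439
classify_upd(sites, roh, chrom_len = len15)
#> UPD call: segmental-isodisomy (maternal); evidence: informative=3170, in_roh=3153

## Mosaicism: chromosome 9 trisomic in 46% of cells, 1-kb bins at 30x
bins <- simulate_depth_bins(genome_model(),
                            list(chrom = "chr9", fraction = 0.46), seed = 42)
mosaic_fraction(chrom_ratio(bins, "chr9"), "gain")
#> [1] 0.46

## Derivative chromosome: two deletions flanking an inverted segment
recs <- sv_records(id = c("del1", "inv", "del2"), chrom = "chr2",
                   start = c(166050817, 166679228, 166818453),
                   end   = c(166679227, 166818452, 166939516),
                   sv_type = c("DEL", "INV", "DEL"))
st <- reconstruct_derivative(recs, hg19_contigs())
st[[1]]
#> derivative structure (linear, 5 segment(s))
#>   chr2:        0-166050817 +
#>   chr2:166679227-166679228 +
#>   chr2:166679228-166818452 -
#>   chr2:166818452-166818453 +
#>   chr2:166939516-243199373 +
classify_structure(st, recs)
#> [1] "DEL-INV-DEL"
```

The reconstruction keeps both flanks in reference orientation, drops the
deleted material, and carries the 139-kb middle segment inverted (the two
1-bp slivers are the printed-coordinate adjacencies between events).

A command-line interface wrapping these functions installs to
`exec/cytowgs` (`cytowgs convert`, `merge`, `cma-call`, `compare`, `roh`,
`str`, `mosaic`, `simulate ...`).

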