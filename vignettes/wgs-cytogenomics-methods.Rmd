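---
title: "Methods: WGS as a first-line cytogenomic test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGS as a first-line cytogenomic test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytowgs)
```

# Scope

`cytowgs` implements the computational core of a workflow in which
short-read whole-genome sequencing (WGS) replaces chromosomal microarray
analysis (CMA) as the first-line test for suspected chromosomal disorders.
The workflow detects everything a microarray sees — dosage-changing CNVs —
plus what it cannot: balanced rearrangements and breakpoint junctions at
base-pair resolution, runs of homozygosity and uniparental disomy (UPD),
short-tandem-repeat (STR) expansions, and mosaic aneuploidy fractions.
Every input the toolkit consumes can be produced by seeded simulators with
truth records, so the whole pipeline is exercised without patient data.

# Coordinate and size conventions

All printed coordinate pairs in clinical CNV tables that we rely on are
self-consistent under the convention `length = end - start`, and the
package uses that convention everywhere (a degenerate interval
`chr1:100-100` has length zero). Sizes are displayed with three
significant figures in kb/Mb, with thousands separators for bp — the
formatting style of clinical reporting tables. ISCN array strings accept
both `_` and `-` as coordinate separators; band tokens are carried
verbatim as labels and never interpreted.

# Multi-caller merging and the filtering cascade

Short-read SV calling uses two complementary caller families: read-depth
("coverage") callers are robust for large and recurrent, repeat-flanked
CNVs but blind below ~5 kb and to breakpoint detail; discordant-pair
("pairedread") callers give exact breakpoints but miss events whose
breakpoints fall in repeats. Calls are merged by single-linkage
clustering: two calls merge iff they share the SV type and either both
breakpoint distances are at most `bp_tol` (default 200 bp) or their
reciprocal overlap is at least `min_reciprocal_overlap` (default 0.7).
The merge parameters are not dictated by any publication; the defaults
sit near common SV-database practice and are exposed in the API.

The filtering cascade applies, in order: size (intergenic calls kept
above 10 kb, intragenic above 2 kb), quality (paired-read-only calls need
at least 6 discordant pairs; coverage-only calls at least 5 kb; calls
seen by both callers pass), frequency (population SV-database frequency
at most 0.5%, internal-database frequency strictly below 1%), and decoy
contig removal. The frequency operators are ambiguous at equality in
clinical prose; the package fixes them as `<=` for the population bound
and `<` for the internal bound, documented and configurable. Small
variants inside panel genes bypass the size stage entirely
(`panel_rescue()`), mirroring gene-panel assessment without a size
cutoff. Each removed call is tallied at its first failing stage, so
`sum(tally) + retained = input` always holds and the filter is
idempotent.

A frequency database is the same single-linkage clustering applied across
samples, with per-cluster carrier counts; querying returns
`count / n_samples` of the best-matching cluster under the identical
merge criteria.

# Array emulation and platform comparison

The array-CGH emulation lays synthetic probes on a fixed grid (default
18 kb, a typical median spacing) with log2 ratio `log2(CN/2)` inside
calls; homozygous losses are floored at −3 to keep the value finite and
plottable. The export is a documented, self-describing XML dialect — one
`<probe>` element per synthetic probe plus a `<segments>` block — and is
deliberately *not* claimed compatible with any proprietary array format.

Array calling uses the standard clinical rule: at least three consecutive
probes beyond the log2 cutoffs (−0.65 for losses, 0.35 for gains). Runs
are broken by any sub-threshold probe and by chromosome boundaries; no
gap tolerance and no segmentation algorithm is emulated, because the
consecutive-probe rule is the stated clinical setting. MLPA ratios below
0.75 are deletions and above 1.3 duplications, boundaries inclusive-
normal. Platform comparison counts an array call as found iff a WGS
record of matching direction overlaps it by at least 1 bp; requiring the
direction match is a deliberate choice — a loss overlapping a gain is not
a confirmation. The overlap criterion behind published concordance
percentages is not stated anywhere we could verify, so any-bp overlap
with direction match is this package's documented choice.

# Derivative-chromosome reconstruction

Clusters of SVs (records within 1 Mb on a chromosome, unioned across
chromosomes by breakend partners) are turned into a breakend graph.
A breakend is a position plus the reference side retained at the join;
record types imply junctions on the derivative haplotype (deletions fuse
their flanks; tandem duplications join head to tail; inversions
contribute two junctions; breakend records carry their own orientation).
Deletion/duplication junctions are suppressed when breakend evidence
touches their boundaries — in that case the breakends describe the join
(insertion sites, translocation fusions, ring closures) — and terminal
deletions contribute no junction at all, since a lost telomeric segment
leaves nothing to fuse.

Reconstruction walks the graph telomere to telomere, consuming each
junction once and traversing duplicated segments once per copy. Where
several junctions share a breakend the walk backtracks and keeps the
continuation that consumes the most junctions, preferring walks that end
cleanly at a telomere or close a ring. Junctions no telomere-anchored
walk can consume seed circular walks (a walk returning to its starting
breakend is a ring); whatever remains is returned flagged incomplete.
Record sets in which distinct SVs share the *identical* breakpoint
coordinate are structurally ambiguous under per-record junctions;
caller-style adjacent coordinates (as printed in clinical tables) resolve
fully. Reconstruction conserves reference material: every base of the
cluster region appears across the returned structures with multiplicity
equal to its copy number.

Topology labels (`simple-DEL`, `tandem-DUP`, `DEL-INV-DEL`,
`DUP-NML-DUP`, `DEL-NML-DEL`, `insertional-translocation`,
`unbalanced-translocation`, `reciprocal-translocation`, `ring`,
`other-complex`) come from a deterministic rule table over the cluster
composition: rings from closed walks; reciprocal translocations from two
interchromosomal junctions with complementary retained sides on both
chromosomes; insertional translocations from a duplication whose breakend
mates land outside it *and* at least two interchromosomal junctions (an
inserted segment is stitched at both edges, a single fusion is a
translocation); unbalanced translocations from one fusion joining a
terminal gain to a terminal loss. The classification is invariant to
record order and to mate-side presentation of breakends.

# Breakpoint-junction analysis

Microhomology and insertions are recovered by anchored extension: the
maximal prefix of the junction sequence matching the A-side reference
(anchored at the breakpoint, then extended into the reference
continuation) and the maximal suffix matching the B-side. Overlap of the
two matches is microhomology; a gap is the insertion — mutually exclusive
at one junction by construction. Matching is exact (no mismatches),
which is how junction figures in clinical breakpoint studies are read.

Insertion templating is searched as maximal exact substrings of at least
`min_templated = 10` bp (random 4-letter matches at 10 bp have
probability 4^-10 per position) within the cluster's breakpoint flanks
(±1 kb), on either strand. Mechanism inference applies fixed rules in
order: recurrent + repeat-flanked → NAHR-like; any templated fragment →
replicative-like (template switching); all junctions with microhomology
≤ 4 bp and non-templated insertions ≤ 20 bp → NHEJ-like; otherwise
unclassified. The thresholds encode qualitative clinical language as
configurable numbers; repeat context is an input flag because repeat
annotation is locus knowledge, not something computed here.

The junction simulator guards the four transition-adjacent bases against
accidental single-base extension, so the planted (microhomology,
insertion) pair is the true value of the synthesized junction, not merely
its construction parameter; analysis then recovers it exactly over the
whole tested grid (microhomology 0–10, insertions 0–60).

# Runs of homozygosity and UPD

The zygosity track tiles a chromosome with 10-kb windows and stores the
homozygous fraction of qualifying sites per window (the heterozygous
complement is exposed alongside, reconciling the plotting convention with
the heterozygous-ratio definition); windows with fewer than 5 sites are
missing. ROH calling takes maximal runs of windows with homozygous
fraction ≥ 0.90 carrying ≥ 1 Mb of qualifying span. Missing windows
bridge silently; sub-threshold windows bridge up to 2 consecutive
windows. The tolerance matters: at typical WGS densities a 10-kb window
holds ~12 sites, so with a genotyping error rate of 10^-3 roughly one
window in a hundred inside a true isodisomy segment contains a single
erroneous heterozygous call. An error-free-window requirement (e.g. a
0.95 cutoff with no bridging) shatters true segments at exactly that
rate, while a normal window is practically never 90% homozygous — hence
0.90 with short bridging, in the spirit of the het-tolerance of standard
ROH callers. All three parameters are configurable.

UPD classification uses Mendelian-impossible sites: a child homozygous
for an allele one parent cannot transmit is evidence that both homologs
came from the other parent. Isodisomy requires the evidence to overlap an
ROH segment; biparental incompatibility without homozygosity indicates
heterodisomy; with a single parent available, a homozygosity segment in
which the child's alleles consistently match the parent is reported as
consistent with that parent's isodisomy. Because sporadic genotype errors
mimic informative sites, evidence must clear both an absolute floor (20
sites) and a relative one (0.2% of genotyped sites), contradiction is
judged relatively (the minor parent's evidence must exceed 20% of the
major's), and the segmental judgement uses the 5–95% trimmed evidence
span. Without these guards, chromosome-scale site counts (~10^5) at
error rate 10^-3 misclassify normal trios.

# STR genotyping

Reads over a repeat locus divide into spanning (both flank anchors),
flanking (one anchor) and in-repeat (≥ 90% tandem motif, no anchor)
classes, with 15-bp exact anchors by default. Spanning reads give exact
unit counts. Two subtleties:

* **Near-read-length alleles.** A 46-unit CAG repeat occupies 138 bp of
  a 151-bp read, leaving only 13 bp for both flanks together — no read
  can carry two 15-bp anchors across it. `genotype_str()` therefore
  applies a short-terminal-anchor rescue: a read with at least 4 exact
  flank bases at *both* ends is counted as spanning (4 bases on each of
  two specified flanks make a chance double match improbable), and a
  read with a single short terminal anchor is treated as flanking — which
  also prevents repeat-dominated boundary reads from being miscounted as
  in-repeat reads.
* **Expansions beyond the read length.** Fully-in-repeat reads (IRR)
  accumulate in proportion to the extra repeat length. Under the
  simulator's Poisson read-start model at per-allele coverage *d*, an
  expansion of *L* bp yields `E[IRR] = d (L - r + 1)/r` for read length
  *r*, so the estimator `L = r + IRR * r / d` is unbiased up to one
  repeat unit; `genotype_str()` passes the per-allele coverage
  (`depth/2`) and converts to units. The in-repeat path replaces the
  long allele once more than one IRR is seen.

At 30× (15× per haplotype) the expected number of reads spanning a
138-bp repeat with 4-bp terminal anchors is about 0.6 per genome, so a
single simulated genome spans the expanded allele in only a minority of
runs. Where a single recovered value is wanted (as in the acceptance
script), replicate simulations are run and the largest spanning-exact
count observed is reported: spanning counting never overcounts, so the
statistic equals the planted expansion exactly if any replicate spans it
and cannot drift toward a wished-for value. The shipped 17-gene catalog
carries approximate GRCh37 repeat coordinates, *synthetic* flank
sequences suitable only for simulation, and editable pathogenic-range
thresholds that are configuration, not clinical claims. Counting is
exact-motif only — interruptions and impurities are out of scope.

# Mosaic aneuploidy

Per-chromosome dosage is the median binned depth on the chromosome over
the median across the other autosomes, with a robust z score from the
baseline MAD; medians and MADs are used so focal CNVs and outlier bins do
not move the estimate, and sex chromosomes are excluded from the
baseline. A single extra copy in a fraction *f* of cells shifts the ratio
to `1 + f/2`, so `f = 2(ratio - 1)` (gains; mirrored for losses), clamped
to [0, 1] — the unique inversion of the single-extra-copy mixture.
Whole-chromosome scans flag |z| ≥ 5, calling trisomy at ratio ≥ 1.4,
monosomy at ≤ 0.6 and mosaicism in between. Coverage-based estimation is
implemented; allele-fraction-based estimation would be a natural
complement and is noted as future work.

# What the simulators do and do not emulate

The generators are pure functions of (specification, seed) and write
their truth alongside the data. They emulate: caller complementarity
(coverage calls ≥ 5 kb with ±500 bp uniform jitter, including
repeat-flanked events; paired-read calls exact with Binomial(depth, ½)
pair support, omitting repeat-breakpoint events), Gaussian log2 probe
noise, Poisson-placed SNV sites with Hardy–Weinberg trio genotypes and
planted iso-/heterodisomy, uniform error-free STR reads, and Poisson
depth bins under a dosage model. They do *not* emulate sequencing error
in reads, GC/mappability waves, dye effects or intensity normalization,
repeat interruptions, or segmental mosaicism — so passing recovery tests
demonstrates the correctness of the estimators under their stated
models, not robustness to every artifact of real data. The pseudo-caller
blind spots are stylized, not calibrated to any specific tool.

# Problem sizes and reproducibility

The test-suite and acceptance computations run at the study's stated
conditions where they are cheap (whole-genome 1-kb depth bins at 30×,
full-length chromosome 15 SNV tracks, 151-bp reads at 30× over repeat
loci) and at reduced scale where full scale adds nothing (the mosaic
recovery *property* uses a 1/20-scale genome; the whole-genome case is
exercised in the acceptance path). Every stochastic check fixes its
seeds; `scripts/acceptance.R` derives all sub-seeds from a single
`--seed` argument.

# Known limitations

* Per-record junction derivation cannot disambiguate clustered SVs that
  share identical breakpoint coordinates (flagged incomplete rather than
  guessed).
* Exact-motif STR counting only; no interruption handling, no mosaic
  repeat-length distributions.
* ROH/UPD analysis assumes reasonably uniform site density; acrocentric
  gaps and centromeres are not modelled.
* The CGH export is an emulation dialect, not a byte-compatible clinical
  array file.
* No liftover, no CRAM/BAM parsing, no split-read assembly from raw
  reads: call sets enter as VCF.
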