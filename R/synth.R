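# Seeded simulators for every input the toolkit consumes. Each generator is
# a pure function of (specification, seed) and returns its truth record
# alongside the data, standing in for patient data in tests and examples.

#' Simulate SV calls from two complementary pseudo-callers
#'
#' Emulates the caller complementarity of a coverage-based and a
#' paired-read-based SV caller. The coverage pseudo-caller reports
#' dosage-changing CNVs of at least 5 kb with uniform breakpoint jitter of
#' up to 500 bp, including events flanked by repeats; the paired-read
#' pseudo-caller reports exact breakpoints with discordant-pair support
#' drawn Binomial(depth, 1/2), but omits events whose breakpoints fall in
#' repeat regions (its blind spot). The blind spots are stylised from the
#' observed behaviour of real callers, not calibrated to them.
#'
#' @param model A [genome_model()].
#' @param events Data frame of planted events: `chrom`, `start`, `end`,
#'   `sv_type` (DEL/DUP/INV), optional `copy_number`.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param depth Sequencing depth (drives paired-read support).
#' @return `list(truth, coverage, pairedread)` with two [caller_output()]
#'   objects.
#' @export
simulate_sv_sample <- function(model, events, seed, sample_id = "S1",
                               depth = 30) {
  set.seed(seed)
  stopifnot(all(events$chrom %in% names(model$contigs)))
  if (any(events$end > model$contigs[events$chrom]) || any(events$start < 0)) {
    stop("planted event outside contig bounds", call. = FALSE)
  }
  if (nrow(events) > 1) {
    for (a in seq_len(nrow(events) - 1)) {
      for (b in (a + 1):nrow(events)) {
        if (events$sv_type[a] == events$sv_type[b] &&
            events$chrom[a] == events$chrom[b] &&
            events$start[a] < events$end[b] && events$start[b] < events$end[a]) {
          stop("overlapping planted events of the same type", call. = FALSE)
        }
      }
    }
  }
  if (is.null(events$copy_number)) {
    events$copy_number <- ifelse(events$sv_type == "DEL", 1L,
                                 ifelse(events$sv_type == "DUP", 3L, NA))
  }
  n <- nrow(events)
  cov_keep <- (events$end - events$start) >= 5000 &
    events$sv_type %in% c("DEL", "DUP")
  cov <- events[cov_keep, , drop = FALSE]
  jit <- function(m) round(stats::runif(m, -500, 500))
  cov_rec <- if (nrow(cov)) {
    sv_records(
      id = sprintf("%s_cov_%d", sample_id, seq_len(nrow(cov))),
      chrom = cov$chrom,
      start = pmax(0, cov$start + jit(nrow(cov))),
      end = cov$end + jit(nrow(cov)),
      sv_type = cov$sv_type, caller = "coverage",
      copy_number = cov$copy_number
    )
  } else sv_records()

  bp_in_repeat <- in_regions(events$chrom, events$start, model$repeat_regions) |
    in_regions(events$chrom, events$end, model$repeat_regions)
  pr <- events[!bp_in_repeat, , drop = FALSE]
  pr_rec <- if (nrow(pr)) {
    sv_records(
      id = sprintf("%s_pr_%d", sample_id, seq_len(nrow(pr))),
      chrom = pr$chrom, start = pr$start, end = pr$end,
      sv_type = pr$sv_type, caller = "pairedread",
      pe_support = stats::rbinom(nrow(pr), depth, 0.5),
      copy_number = pr$copy_number
    )
  } else sv_records()

  list(truth = list(events = events, seed = seed, sample_id = sample_id),
       coverage = caller_output(sample_id, "coverage", cov_rec),
       pairedread = caller_output(sample_id, "pairedread", pr_rec))
}

#' Simulate an array probe series over planted CNVs
#'
#' Gaussian log2 noise around 0 outside events and around `log2(CN/2)`
#' inside them, on a fixed probe grid (default spacing 18 kb, the emulated
#' platform's median).
#'
#' @param model A [genome_model()] (or a subset of its contigs via
#'   `contigs`).
#' @param events Planted CNVs (`chrom`, `start`, `end`, `sv_type`,
#'   optional `copy_number`).
#' @param spacing Probe spacing in bp.
#' @param noise_sd Log2 noise standard deviation.
#' @param seed Integer seed.
#' @param contigs Optional character vector restricting the simulated
#'   contigs.
#' @return A [probe_series()] data frame.
#' @export
simulate_probe_series <- function(model, events, spacing = 18000,
                                  noise_sd = 0.15, seed = 1,
                                  contigs = names(model$contigs)) {
  set.seed(seed)
  stopifnot(spacing > 0)
  if (is.null(events$copy_number) && nrow(events)) {
    events$copy_number <- ifelse(events$sv_type == "DEL", 1L, 3L)
  }
  out <- list()
  for (ctg in contigs) {
    k <- floor(model$contigs[[ctg]] / spacing)
    if (k < 1) next
    pos <- spacing * seq_len(k)
    mu <- rep(0, k)
    for (i in which(events$chrom == ctg)) {
      inside <- pos > events$start[i] & pos <= events$end[i]
      cn <- events$copy_number[i]
      mu[inside] <- if (cn == 0) -3 else log2(cn / 2)
    }
    out[[ctg]] <- data.frame(chrom = ctg, pos = pos,
                             log2 = mu + stats::rnorm(k, 0, noise_sd),
                             stringsAsFactors = FALSE)
  }
  probe_series(do.call(rbind, out))
}

#' Simulate SNV sites on one chromosome with optional planted UPD
#'
#' Sites are Poisson-placed with separate heterozygous and homozygous
#' densities (defaults reflect typical WGS: about one heterozygous site
#' per 1.5 kb). Inside a planted isodisomy segment the heterozygous
#' probability drops to the genotyping error rate. In trio mode parental
#' genotypes are drawn from Hardy-Weinberg at allele frequency 0.5 and
#' the child's genotype is built from transmitted alleles — both copies
#' from a single parental homolog inside an isodisomy segment, both
#' parental homologs for heterodisomy.
#'
#' @param chrom_len Chromosome length in bp.
#' @param het_rate,hom_rate Per-bp densities of heterozygous and
#'   homozygous sites.
#' @param upd Optional planted UPD: `list(start, end, parent =
#'   "maternal"/"paternal", kind = "isodisomy"/"heterodisomy")`.
#' @param error_rate Genotype error rate.
#' @param trio Also simulate parental genotypes?
#' @param seed Integer seed.
#' @return Data frame with `pos`, `genotype` (child), `quality`, and in
#'   trio mode `gt_child`, `gt_mother`, `gt_father`; planted truth in
#'   attribute `"truth"`.
#' @export
simulate_snp_sites <- function(chrom_len, het_rate = 1 / 1500,
                               hom_rate = 1 / 1800, upd = NULL,
                               error_rate = 0.001, trio = FALSE, seed = 1) {
  set.seed(seed)
  rate <- het_rate + hom_rate
  n <- stats::rpois(1, chrom_len * rate)
  pos <- sort(round(stats::runif(n, 1, chrom_len)))
  in_upd <- if (is.null(upd)) rep(FALSE, n) else
    pos >= upd$start & pos <= upd$end
  gt_levels <- c("hom_ref", "het", "hom_alt")

  if (!trio) {
    p_het <- het_rate / rate
    het <- stats::runif(n) < ifelse(in_upd, error_rate, p_het)
    genotype <- ifelse(het, "het",
                       sample(c("hom_ref", "hom_alt"), n, replace = TRUE))
    df <- data.frame(pos = pos, genotype = genotype, quality = 60)
  } else {
    mo <- matrix(stats::rbinom(2 * n, 1, 0.5), ncol = 2)
    fa <- matrix(stats::rbinom(2 * n, 1, 0.5), ncol = 2)
    mo_trans <- sample(1:2, n, replace = TRUE)
    fa_trans <- sample(1:2, n, replace = TRUE)
    child_a <- mo[cbind(seq_len(n), mo_trans)]
    child_b <- fa[cbind(seq_len(n), fa_trans)]
    if (!is.null(upd)) {
      par_m <- if (upd$parent == "maternal") mo else fa
      if (identical(upd$kind, "heterodisomy")) {
        child_a[in_upd] <- par_m[in_upd, 1]
        child_b[in_upd] <- par_m[in_upd, 2]
      } else {
        homolog <- sample(1:2, 1)
        child_a[in_upd] <- par_m[in_upd, homolog]
        child_b[in_upd] <- par_m[in_upd, homolog]
      }
    }
    err <- stats::runif(n) < error_rate
    flip <- sample(0:2, sum(err), replace = TRUE)
    child_sum <- child_a + child_b
    child_sum[err] <- flip
    df <- data.frame(
      pos = pos,
      genotype = gt_levels[child_sum + 1L],
      gt_child = gt_levels[child_sum + 1L],
      gt_mother = gt_levels[rowSums(mo) + 1L],
      gt_father = gt_levels[rowSums(fa) + 1L],
      quality = 60
    )
  }
  attr(df, "truth") <- list(upd = upd, seed = seed, chrom_len = chrom_len,
                            het_rate = het_rate, hom_rate = hom_rate)
  df
}

#' Simulate short reads over an STR locus
#'
#' Builds one haplotype per allele (`flank_a` + motif repeats + `flank_b`,
#' padded with random sequence so reads can extend past the flanks) and
#' samples error-free reads whose start positions follow a Poisson process
#' at per-allele coverage `depth / 2`. Spanning, flanking and in-repeat
#' reads arise naturally from the allele length.
#'
#' @param locus An [str_locus()].
#' @param alleles Integer vector of two repeat-unit counts.
#' @param depth Diploid mean coverage.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return Character vector of reads; truth in attribute `"truth"`.
#' @export
simulate_str_reads <- function(locus, alleles, depth = 30, read_len = 151,
                               seed = 1) {
  set.seed(seed)
  stopifnot(length(alleles) == 2, all(alleles >= 0), depth > 0)
  reads <- character(0)
  for (units in alleles) {
    hap <- paste0(random_dna(read_len), locus$flank_a,
                  strrep(locus$motif, units), locus$flank_b,
                  random_dna(read_len))
    n_start <- nchar(hap) - read_len + 1L
    lambda <- (depth / 2) / read_len
    n_reads <- stats::rpois(1, lambda * n_start)
    starts <- sample.int(n_start, n_reads, replace = TRUE)
    reads <- c(reads, substring(hap, starts, starts + read_len - 1L))
  }
  reads <- sample(reads)
  attr(reads, "truth") <- list(gene = locus$gene, alleles = sort(alleles),
                               depth = depth, read_len = read_len,
                               seed = seed)
  reads
}

#' Simulate whole-genome read-depth bins with optional mosaic aneuploidy
#'
#' Per-bin counts are Poisson with mean `depth * bin_bp * dosage`, where
#' dosage is 1 everywhere except the affected chromosome, which carries an
#' extra copy in a fraction `f` of cells (dosage `1 + f/2`).
#'
#' @param model A [genome_model()].
#' @param aneuploidy Optional `list(chrom, fraction)` (fraction 1 = full
#'   trisomy).
#' @param depth Mean per-base coverage.
#' @param bin_bp Bin size in bp.
#' @param seed Integer seed.
#' @return Data frame `chrom`, `start`, `depth`; truth in attribute
#'   `"truth"`.
#' @export
simulate_depth_bins <- function(model, aneuploidy = NULL, depth = 30,
                                bin_bp = 1000, seed = 1) {
  set.seed(seed)
  stopifnot(bin_bp > 0, depth > 0)
  n_bins <- floor(model$contigs / bin_bp)
  n_bins <- n_bins[n_bins > 0]
  chrom <- rep(names(n_bins), n_bins)
  start <- unlist(lapply(n_bins, function(k) bin_bp * (seq_len(k) - 1L)),
                  use.names = FALSE)
  dosage <- rep(1, length(chrom))
  if (!is.null(aneuploidy)) {
    stopifnot(aneuploidy$fraction >= 0, aneuploidy$fraction <= 1)
    dosage[chrom == aneuploidy$chrom] <- 1 + aneuploidy$fraction / 2
  }
  df <- data.frame(chrom = chrom, start = start,
                   depth = stats::rpois(length(chrom), depth * bin_bp * dosage),
                   stringsAsFactors = FALSE)
  attr(df, "truth") <- list(aneuploidy = aneuploidy, depth = depth,
                            bin_bp = bin_bp, seed = seed)
  df
}
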