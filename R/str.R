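#' Short-tandem-repeat locus definition
#'
#' @param gene Gene symbol.
#' @param chrom,start,end Reference repeat interval.
#' @param motif Repeat unit (e.g. `"CAG"`).
#' @param reference_units Repeat units in the reference.
#' @param pathogenic_min Pathogenic repeat-count threshold, or `NA`
#'   (thresholds are configuration, not clinical claims).
#' @param flank_a,flank_b Reference flank sequences immediately left and
#'   right of the repeat (the shipped catalog uses synthetic flanks).
#' @return An `str_locus` object.
#' @export
str_locus <- function(gene, chrom, start, end, motif, reference_units,
                      pathogenic_min = NA, flank_a, flank_b) {
  stopifnot(nchar(motif) >= 1, nchar(flank_a) >= 20, nchar(flank_b) >= 20)
  structure(list(gene = gene, chrom = chrom, start = start, end = end,
                 motif = toupper(motif),
                 reference_units = reference_units,
                 pathogenic_min = pathogenic_min,
                 flank_a = toupper(flank_a), flank_b = toupper(flank_b)),
            class = "str_locus")
}

#' Load an STR locus catalog from JSON
#'
#' The package ships `inst/extdata/str_catalog_17.json`, a catalog of the
#' 17 repeat-disorder genes assessed by the screening workflow (AR, ATN1,
#' ATXN1, ATXN10, ATXN2, ATXN3, ATXN7, C9ORF72, CACNA1A, CBL, CSTB, DMPK,
#' FMR1, FXN, HTT, JPH3, PPP2R2B) with approximate GRCh37 repeat
#' coordinates and synthetic flank sequences.
#'
#' @param path Catalog path; defaults to the shipped catalog.
#' @return Named list of [str_locus()] objects.
#' @export
read_str_catalog <- function(path = system.file("extdata",
                                                "str_catalog_17.json",
                                                package = "cytowgs")) {
  cat <- jsonlite::read_json(path)
  loci <- lapply(cat$loci, function(x) {
    str_locus(x$gene, x$chrom, x$start, x$end, x$motif, x$reference_units,
              x$pathogenic_min %||% NA, x$flank_a, x$flank_b)
  })
  names(loci) <- vapply(loci, `[[`, character(1), "gene")
  loci
}

# Locate flank anchors in a read. Full anchors are exact matches of the
# `anchor_min` flank bases adjacent to the repeat; terminal anchors are
# shorter exact matches of flank sequence at the very read end (the case
# of a read spanning a repeat nearly as long as itself).
str_anchors <- function(seq, locus, anchor_min = 15) {
  n <- nchar(seq)
  fa <- locus$flank_a; fb <- locus$flank_b
  left_len <- 0L; left_end <- NA_integer_
  full_a <- substr(fa, nchar(fa) - anchor_min + 1, nchar(fa))
  pos <- regexpr(full_a, seq, fixed = TRUE)
  if (pos > 0) {
    left_len <- anchor_min
    left_end <- as.integer(pos) + anchor_min - 1L
  } else {
    for (a in seq(min(anchor_min - 1L, n, nchar(fa)), 1L)) {
      if (substr(seq, 1, a) == substr(fa, nchar(fa) - a + 1, nchar(fa))) {
        left_len <- a; left_end <- a
        break
      }
    }
  }
  right_len <- 0L; right_start <- NA_integer_
  full_b <- substr(fb, 1, anchor_min)
  pos <- regexpr(full_b, seq, fixed = TRUE)
  if (pos > 0) {
    right_len <- anchor_min
    right_start <- as.integer(pos)
  } else {
    for (b in seq(min(anchor_min - 1L, n, nchar(fb)), 1L)) {
      if (substr(seq, n - b + 1, n) == substr(fb, 1, b)) {
        right_len <- b; right_start <- n - b + 1L
        break
      }
    }
  }
  list(left_len = left_len, left_end = left_end,
       right_len = right_len, right_start = right_start)
}

# Fraction of the read covered by the longest tandem run of the motif
# (any rotation phase).
motif_fraction <- function(seq, motif) {
  n <- nchar(seq)
  if (n == 0L) return(0)
  k <- nchar(motif)
  doubled <- paste0(motif, motif)
  best <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n) {
      phase <- ((j - i) %% k) + 1L
      if (substr(seq, j, j) != substr(doubled, phase, phase)) break
      j <- j + 1L
    }
    run <- j - i
    if (run > best) best <- run
    i <- if (run > 0L) j + 1L else i + 1L
  }
  # also consider runs starting at any motif phase
  for (off in seq_len(k - 1)) {
    i <- 1L
    while (i <= n) {
      j <- i
      while (j <= n) {
        phase <- ((j - i + off) %% k) + 1L
        if (substr(seq, j, j) != substr(doubled, phase, phase)) break
        j <- j + 1L
      }
      run <- j - i
      if (run > best) best <- run
      i <- if (run > 0L) j + 1L else i + 1L
    }
  }
  best / n
}

#' Classify a read with respect to an STR locus
#'
#' `spanning` iff both flank anchors (at least `anchor_min` bp of exact
#' flank sequence) are present; `flanking` iff exactly one is;
#' `inrepeat` iff no anchor is present and at least 90% of the read is
#' tandem motif copies.
#'
#' @param seq Read sequence.
#' @param locus An [str_locus()].
#' @param anchor_min Minimum exact anchor length in bp.
#' @return One of `"spanning"`, `"flanking"`, `"inrepeat"`.
#' @export
classify_read <- function(seq, locus, anchor_min = 15) {
  a <- str_anchors(seq, locus, anchor_min)
  n_anchor <- (a$left_len >= anchor_min) + (a$right_len >= anchor_min)
  if (n_anchor == 2L) return("spanning")
  if (n_anchor == 1L) return("flanking")
  if (motif_fraction(seq, locus$motif) >= 0.9) return("inrepeat")
  "flanking"
}

count_units <- function(region, motif) {
  k <- nchar(motif)
  n <- nchar(region)
  if (n %% k != 0L) return(NA_integer_)
  units <- n %/% k
  if (region == strrep(motif, units)) units else NA_integer_
}

#' Count repeat units in a spanning read
#'
#' Exact tandem motif copies between the two flank anchors.
#'
#' @param seq Read sequence classified as spanning.
#' @param locus An [str_locus()].
#' @param anchor_min Anchor length used to locate the flanks.
#' @return Integer unit count.
#' @export
count_spanning <- function(seq, locus, anchor_min = 15) {
  a <- str_anchors(seq, locus, anchor_min)
  if (a$left_len < 1L || a$right_len < 1L ||
      is.na(a$left_end) || is.na(a$right_start)) {
    stop("read does not span the repeat (missing flank anchor)", call. = FALSE)
  }
  region <- substr(seq, a$left_end + 1L, a$right_start - 1L)
  u <- count_units(region, locus$motif)
  if (is.na(u)) {
    stop("sequence between anchors is not an exact tandem array of the motif",
         call. = FALSE)
  }
  u
}

#' Estimate an expansion size from in-repeat reads
#'
#' For expansions longer than the read length, fully-in-repeat reads (IRR)
#' accumulate proportionally to the extra repeat length. Under uniform
#' read sampling at per-allele coverage `depth`, the expected IRR count is
#' `depth * (L - read_len) / read_len` for an expansion of `L` bp, so the
#' inversion `L = read_len + n_irr * read_len / depth` estimates the
#' expansion, converted to repeat units by the motif length.
#'
#' @param n_irr Number of in-repeat reads observed.
#' @param read_len Read length in bp.
#' @param depth Per-allele (haploid) mean coverage of the expanded allele.
#' @param motif_len Motif length in bp.
#' @return Estimated repeat units (0 when `n_irr == 0`).
#' @export
estimate_inrepeat <- function(n_irr, read_len, depth, motif_len) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  stopifnot(n_irr >= 0, read_len > 0, motif_len >= 1)
  if (n_irr == 0) return(0L)
  bp <- read_len + n_irr * read_len / depth
  as.integer(round(bp / motif_len))
}

#' Genotype an STR locus from reads
#'
#' Repeat-unit alleles are the two best-supported exact counts from
#' spanning reads. Alleles approaching the read length are rescued by
#' short terminal anchors: a read carrying at least `min_terminal_anchor`
#' exact flank bases at both ends is counted as spanning even when it
#' cannot fit the default `anchor_min` anchors, and reads with a single
#' short terminal anchor are treated as flanking rather than in-repeat.
#' When more in-repeat reads than the expected background (`irr_trigger`)
#' are seen, the long allele is replaced by the in-repeat estimate
#' ([estimate_inrepeat()] at per-allele coverage `depth / 2`) and tagged
#' `inrepeat-estimated`.
#'
#' @param locus An [str_locus()].
#' @param reads Character vector of read sequences from one sample.
#' @param depth Sample mean coverage (diploid).
#' @param anchor_min Full anchor length for classification.
#' @param min_terminal_anchor Minimum exact terminal flank match for the
#'   short-anchor spanning rescue.
#' @param irr_trigger In-repeat read count that must be exceeded before
#'   the in-repeat estimator replaces the long allele.
#' @return An `str_genotype`: `list(gene, allele_short, allele_long,
#'   method_long, pathogenic_flag, n_spanning, n_irr, spanning_counts)`.
#' @export
genotype_str <- function(locus, reads, depth = 30, anchor_min = 15,
                         min_terminal_anchor = 4, irr_trigger = 1) {
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  read_len <- as.integer(stats::median(nchar(reads)))
  counts <- integer(0)
  n_irr <- 0L
  for (seq in reads) {
    a <- str_anchors(seq, locus, anchor_min)
    left_ok <- a$left_len >= min_terminal_anchor
    right_ok <- a$right_len >= min_terminal_anchor
    if (left_ok && right_ok) {
      u <- count_units(substr(seq, a$left_end + 1L, a$right_start - 1L),
                       locus$motif)
      if (!is.na(u)) counts <- c(counts, u)
    } else if (!left_ok && !right_ok &&
               motif_fraction(seq, locus$motif) >= 0.9) {
      n_irr <- n_irr + 1L
    }
  }
  if (length(counts) == 0L && n_irr == 0L) {
    stop("no informative reads at locus ", locus$gene, call. = FALSE)
  }
  alleles <- if (length(counts)) {
    tab <- sort(table(counts), decreasing = TRUE)
    top <- as.integer(names(tab))[seq_len(min(2L, length(tab)))]
    if (length(top) == 1L) c(top, top) else sort(top)
  } else c(0L, 0L)
  allele_short <- alleles[1]
  allele_long <- alleles[2]
  method_long <- "spanning-exact"
  if (n_irr > irr_trigger) {
    allele_long <- estimate_inrepeat(n_irr, read_len, depth / 2,
                                     nchar(locus$motif))
    method_long <- "inrepeat-estimated"
    if (allele_long < allele_short) {
      tmp <- allele_short; allele_short <- allele_long; allele_long <- tmp
    }
  }
  flag <- !is.na(locus$pathogenic_min) &&
    allele_long >= locus$pathogenic_min
  structure(list(gene = locus$gene, allele_short = allele_short,
                 allele_long = allele_long, method_long = method_long,
                 pathogenic_flag = flag,
                 n_spanning = length(counts), n_irr = n_irr,
                 spanning_counts = counts),
            class = "str_genotype")
}

#' @export
print.str_genotype <- function(x, ...) {
  cat(sprintf("%s: %d/%d (%s)%s [spanning reads: %d, in-repeat reads: %d]\n",
              x$gene, x$allele_short, x$allele_long, x$method_long,
              if (x$pathogenic_flag) " PATHOGENIC-RANGE" else "",
              x$n_spanning, x$n_irr))
  invisible(x)
}
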