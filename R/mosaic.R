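#' Chromosome-to-baseline coverage ratio
#'
#' Ratio of the median binned depth on one chromosome to the median over
#' all other autosomes, with a robust z score from the baseline spread.
#' Median/MAD statistics are used so that focal CNVs and outlier bins do
#' not move the estimate; sex chromosomes are excluded from the baseline.
#'
#' @param bins Data frame with `chrom`, `start`, `depth` (bin read
#'   counts).
#' @param chrom Chromosome to test.
#' @param min_chrom_bins,min_baseline_bins Minimum bin counts.
#' @return A `chrom_ratio`: `list(chrom, ratio, z, n_bins)`.
#' @export
chrom_ratio <- function(bins, chrom, min_chrom_bins = 100,
                        min_baseline_bins = 1000) {
  sex <- c("chrX", "chrY", "X", "Y")
  on_c <- bins$depth[bins$chrom == chrom]
  base <- bins$depth[bins$chrom != chrom & !(bins$chrom %in% sex)]
  if (length(on_c) < min_chrom_bins) {
    stop("fewer than ", min_chrom_bins, " bins on ", chrom, call. = FALSE)
  }
  if (length(base) < min_baseline_bins) {
    stop("fewer than ", min_baseline_bins, " baseline bins", call. = FALSE)
  }
  med_c <- stats::median(on_c)
  med_b <- stats::median(base)
  mad_b <- stats::mad(base)
  z <- (med_c - med_b) / (mad_b / sqrt(length(on_c)))
  structure(list(chrom = chrom, ratio = med_c / med_b, z = z,
                 n_bins = length(on_c)),
            class = "chrom_ratio")
}

#' Mosaic fraction from a coverage ratio
#'
#' A single extra copy present in a fraction `f` of cells shifts the
#' coverage ratio to `1 + f/2` (a lost copy to `1 - f/2`); inverting the
#' mixture gives `f = 2(ratio - 1)` for gains and `f = 2(1 - ratio)` for
#' losses, clamped to \[0, 1\].
#'
#' @param ratio Coverage ratio (> 0), e.g. from [chrom_ratio()].
#' @param direction `"gain"` or `"loss"`.
#' @return Estimated fraction of cells carrying the aberration.
#' @export
mosaic_fraction <- function(ratio, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (inherits(ratio, "chrom_ratio")) ratio <- ratio$ratio
  stopifnot(ratio > 0)
  f <- if (direction == "gain") 2 * (ratio - 1) else 2 * (1 - ratio)
  min(max(f, 0), 1)
}

#' Scan all chromosomes for aneuploidy
#'
#' Flags chromosomes whose coverage ratio deviates from the autosomal
#' baseline with `|z| >= z_min`; flagged chromosomes are called trisomy at
#' ratio >= 1.4, monosomy at <= 0.6, and mosaic gain/loss (with estimated
#' fraction) in between.
#'
#' @param bins Whole-genome depth bins (`chrom`, `start`, `depth`).
#' @param z_min Robust z threshold.
#' @return Data frame: `chrom`, `ratio`, `z`, `call`, `fraction`.
#' @export
detect_aneuploidy <- function(bins, z_min = 5) {
  chroms <- unique(bins$chrom)
  rows <- lapply(chroms, function(ctg) {
    cr <- chrom_ratio(bins, ctg)
    call <- "normal"
    fraction <- NA_real_
    if (is.finite(cr$z) && abs(cr$z) >= z_min) {
      if (cr$ratio >= 1.4) {
        call <- "trisomy"; fraction <- 1
      } else if (cr$ratio <= 0.6) {
        call <- "monosomy"; fraction <- 1
      } else if (cr$ratio > 1) {
        call <- "mosaic-gain"; fraction <- mosaic_fraction(cr$ratio, "gain")
      } else {
        call <- "mosaic-loss"; fraction <- mosaic_fraction(cr$ratio, "loss")
      }
    }
    data.frame(chrom = ctg, ratio = cr$ratio, z = cr$z, call = call,
               fraction = fraction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
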