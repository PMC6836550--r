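#' Call CNVs from an array probe series by the consecutive-probe rule
#'
#' Emulates standard clinical array-CGH calling: a maximal run of at least
#' `min_run` consecutive probes all below `del_cut` becomes a loss call,
#' and all above `dup_cut` a gain call. Runs never mix directions and are
#' broken by chromosome boundaries and by any probe not passing the cutoff
#' (no gap tolerance; segmentation algorithms are deliberately not
#' emulated). The call interval spans the first to the last aberrant probe
#' position.
#'
#' @param series Probe series data frame (`chrom`, `pos`, `log2`), sorted
#'   within chromosome (see [probe_series()]).
#' @param del_cut,dup_cut log2-ratio cutoffs (clinical defaults -0.65 and
#'   0.35).
#' @param min_run Minimum consecutive aberrant probes (clinical default 3).
#' @return `cma_calls` data frame: `chrom`, `start`, `end`, `direction`
#'   (loss/gain), `n_probes`, `mean_log2`.
#' @export
call_probes <- function(series, del_cut = -0.65, dup_cut = 0.35, min_run = 3) {
  series <- probe_series(as.data.frame(series))
  out <- list()
  for (ctg in unique(series$chrom)) {
    s <- series[series$chrom == ctg, , drop = FALSE]
    state <- ifelse(s$log2 < del_cut, "loss",
                    ifelse(s$log2 > dup_cut, "gain", "normal"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "normal" || r$lengths[k] < min_run) next
      ix <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ctg, start = s$pos[ix[1]], end = s$pos[ix[length(ix)]],
        direction = r$values[k], n_probes = length(ix),
        mean_log2 = mean(s$log2[ix]), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               direction = character(), n_probes = integer(),
               mean_log2 = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("cma_calls", "data.frame")
  res
}

#' Interpret an MLPA normalized ratio
#'
#' Clinical thresholds: a normalized quotient below 0.75 is a deletion,
#' above 1.3 a duplication; the boundaries themselves are normal.
#'
#' @param ratio Non-negative normalized quotient(s).
#' @return Character vector in `{deletion, normal, duplication}`.
#' @export
mlpa_call <- function(ratio) {
  if (any(ratio < 0)) stop("MLPA ratio must be non-negative", call. = FALSE)
  ifelse(ratio < 0.75, "deletion", ifelse(ratio > 1.3, "duplication", "normal"))
}

#' Compare a WGS SV call set with array CNV calls
#'
#' An array call counts as found iff it overlaps a WGS record of matching
#' direction (DEL vs loss, DUP vs gain) by at least 1 bp. A loss
#' overlapping only a gain is not a confirmation. The report carries the
#' found fraction and the size/direction composition of found and
#' not-found calls, the quantities used to argue that unconfirmed array
#' calls are small duplication-biased artifacts.
#'
#' @param wgs [sv_records()] table (DEL/DUP records are considered).
#' @param cma `cma_calls` data frame from [call_probes()].
#' @return `cma_comparison` list: `n_cma`, `n_found`, `fraction_found`,
#'   per-group size medians/quartiles and gain fractions, and the per-call
#'   `found` flags.
#' @export
compare_callsets <- function(wgs, cma) {
  if (nrow(cma) == 0L) {
    return(structure(list(n_cma = 0L, n_found = 0L, fraction_found = NA_real_,
                          found = logical(0)), class = "cma_comparison"))
  }
  dir_of <- c(DEL = "loss", DUP = "gain")
  w <- wgs[wgs$sv_type %in% names(dir_of), , drop = FALSE]
  found <- vapply(seq_len(nrow(cma)), function(i) {
    cand <- w$chrom == cma$chrom[i] & dir_of[w$sv_type] == cma$direction[i]
    any(cand & pmin(w$end, cma$end[i]) - pmax(w$start, cma$start[i]) >= 1)
  }, logical(1))
  sizes <- cma$end - cma$start
  qs <- function(x) if (length(x)) stats::quantile(x, c(.25, .5, .75), names = FALSE)
  else c(NA_real_, NA_real_, NA_real_)
  gain_frac <- function(ix) if (any(ix)) mean(cma$direction[ix] == "gain") else NA_real_
  structure(list(
    n_cma = nrow(cma), n_found = sum(found),
    fraction_found = mean(found),
    size_found = stats::setNames(qs(sizes[found]), c("q1", "median", "q3")),
    size_not_found = stats::setNames(qs(sizes[!found]), c("q1", "median", "q3")),
    gain_fraction_found = gain_frac(found),
    gain_fraction_not_found = gain_frac(!found),
    found = found
  ), class = "cma_comparison")
}

#' @export
print.cma_comparison <- function(x, ...) {
  cat(sprintf("array calls: %d, found in WGS: %d (%.1f%%)\n",
              x$n_cma, x$n_found, 100 * x$fraction_found))
  fmt <- function(v) if (is.na(v)) "n/a" else format_size(v)
  if (x$n_cma > 0) {
    cat(sprintf("median size found: %s, not found: %s\n",
                fmt(x$size_found[["median"]]),
                fmt(x$size_not_found[["median"]])))
  }
  invisible(x)
}
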