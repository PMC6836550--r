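#' Windowed zygosity track from SNV genotypes
#'
#' Tiles one chromosome with fixed windows (default 10 kb) and computes,
#' per window, the fraction of qualifying SNV sites that are homozygous.
#' Windows with fewer than `min_snps` qualifying sites are flagged missing
#' (`NA`). The complementary heterozygous fraction — the "zygosity ratio"
#' of heterozygous to total high-quality variants in a local region — is
#' exposed alongside, so the track serves both the homozygous-fraction
#' plotting convention and the heterozygous-ratio definition.
#'
#' @param sites Data frame with columns `pos`, `genotype` (one of
#'   `het`, `hom_ref`, `hom_alt`) and optionally `quality`.
#' @param window_bp Window size in bp.
#' @param min_quality Minimum site quality; sites below are ignored
#'   (ignored when `sites` carries no `quality` column).
#' @param min_snps Minimum qualifying sites per window.
#' @param chrom_len Optional chromosome length; defaults to the last site.
#' @return A `zygosity_track` data frame: `start`, `end`, `n_snps`,
#'   `hom_fraction`, `het_fraction`, with `window_bp` as attribute.
#' @export
zygosity_track <- function(sites, window_bp = 10000, min_quality = 20,
                           min_snps = 5, chrom_len = NULL) {
  stopifnot(window_bp > 0, min_snps >= 0)
  stopifnot(all(sites$genotype %in% c("het", "hom_ref", "hom_alt")))
  if (!is.null(sites$quality)) {
    stopifnot(all(sites$quality >= 0))
    sites <- sites[sites$quality >= min_quality, , drop = FALSE]
  }
  if (is.null(chrom_len)) {
    chrom_len <- if (nrow(sites)) max(sites$pos) else window_bp
  }
  n_win <- ceiling(chrom_len / window_bp)
  win <- pmin(floor(sites$pos / window_bp), n_win - 1L) + 1L
  hom <- sites$genotype != "het"
  n_snps <- tabulate(win, nbins = n_win)
  n_hom <- tabulate(win[hom], nbins = n_win)
  hom_fraction <- ifelse(n_snps >= pmax(min_snps, 1L), n_hom / n_snps, NA_real_)
  out <- data.frame(
    start = window_bp * (seq_len(n_win) - 1L),
    end = pmin(window_bp * seq_len(n_win), chrom_len),
    n_snps = n_snps,
    hom_fraction = hom_fraction,
    het_fraction = 1 - hom_fraction
  )
  attr(out, "window_bp") <- window_bp
  class(out) <- c("zygosity_track", "data.frame")
  out
}

#' Call runs of homozygosity from a zygosity track
#'
#' Maximal runs of windows with homozygous fraction at least
#' `min_hom_fraction` become segments when the run carries at least
#' `min_len` of qualifying window span. Missing windows (too few SNVs)
#' never break a run — they are bridged — but contribute no
#' length-qualifying evidence; sub-threshold windows are likewise bridged
#' up to `max_interruption` consecutive windows, so that a single
#' genotyping error among the dozen sites of a 10-kb window does not
#' shatter a true isodisomy segment. Segments start and end at qualifying
#' windows. The defaults (0.90, 1 Mb, 2 windows) are set so that, at
#' typical WGS heterozygous-site density of roughly one per 1.5 kb, an
#' isodisomic segment is unambiguous against chance runs of homozygous
#' windows (a normal window is practically never 90% homozygous) while one
#' erroneous heterozygous call among ten or more window sites is
#' tolerated.
#'
#' @param track A [zygosity_track()].
#' @param min_hom_fraction Minimum per-window homozygous fraction.
#' @param min_len Minimum qualifying length in bp.
#' @param max_interruption Maximum consecutive sub-threshold windows
#'   bridged inside a run.
#' @return A `roh_segments` data frame: `start`, `end`, `n_windows`,
#'   `mean_hom_fraction` (disjoint, sorted).
#' @export
call_roh <- function(track, min_hom_fraction = 0.90, min_len = 1e6,
                     max_interruption = 2) {
  state <- ifelse(is.na(track$hom_fraction), "na",
                  ifelse(track$hom_fraction >= min_hom_fraction, "hom", "low"))
  out <- list()
  run_start <- NA_integer_
  low_streak <- 0L
  flush <- function(run_start, i_last) {
    ix <- run_start:i_last
    qual <- ix[state[ix] == "hom"]
    if (length(qual) == 0L) return(NULL)
    qual_len <- sum(track$end[qual] - track$start[qual])
    if (qual_len < min_len) return(NULL)
    data.frame(start = track$start[qual[1]],
               end = track$end[qual[length(qual)]],
               n_windows = length(qual),
               mean_hom_fraction = mean(track$hom_fraction[qual]))
  }
  for (i in seq_len(nrow(track))) {
    if (state[i] == "hom") {
      if (is.na(run_start)) run_start <- i
      low_streak <- 0L
    } else if (state[i] == "low") {
      low_streak <- low_streak + 1L
      if (!is.na(run_start) && low_streak > max_interruption) {
        seg <- flush(run_start, i - 1L)
        if (!is.null(seg)) out[[length(out) + 1L]] <- seg
        run_start <- NA_integer_
      }
    }
    # missing windows bridge silently
  }
  if (!is.na(run_start)) {
    seg <- flush(run_start, nrow(track))
    if (!is.null(seg)) out[[length(out) + 1L]] <- seg
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = numeric(), end = numeric(), n_windows = integer(),
               mean_hom_fraction = numeric())
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

#' Classify uniparental disomy from trio (or duo) genotypes
#'
#' With both parents available, sites where the child carries no allele
#' transmissible from one parent (e.g. child homozygous alt, parent
#' homozygous ref) count as evidence that both homologs came from the
#' other parent. Isodisomy additionally requires the evidence to overlap a
#' run of homozygosity; biparental incompatibility without homozygosity
#' points to heterodisomy. With a single parent (the duo situation of a
#' suspected imprinting disorder), a homozygosity segment in which the
#' child's homozygous alleles consistently match an allele carried by the
#' available parent is reported as consistent with that parent's
#' isodisomy. Evidence confined to a subinterval of the chromosome is
#' labelled segmental. At least `min_informative` informative sites are
#' required, and they must make up at least `min_informative_frac` of the
#' genotyped sites (so that sporadic genotype errors across a whole
#' chromosome cannot masquerade as UPD evidence); otherwise `none` is
#' returned.
#'
#' @param sites Data frame with `pos`, `gt_child` and optionally
#'   `gt_mother` / `gt_father` columns (values `het`, `hom_ref`,
#'   `hom_alt`, or `NA`).
#' @param roh A [call_roh()] result for the same chromosome.
#' @param chrom_len Chromosome length (for the segmental judgement);
#'   defaults to the last site position.
#' @param min_informative Minimum informative sites.
#' @param min_informative_frac Minimum informative fraction of genotyped
#'   sites.
#' @param segmental_max_span Fraction of the chromosome below which the
#'   evidence region is called segmental.
#' @return An `upd_call`: `list(kind, parent, evidence)` with `kind` one
#'   of `isodisomy`, `heterodisomy`, `segmental-isodisomy`, `none`.
#' @export
classify_upd <- function(sites, roh, chrom_len = NULL, min_informative = 20,
                         min_informative_frac = 0.002,
                         segmental_max_span = 0.8) {
  if (is.null(chrom_len)) chrom_len <- max(sites$pos)
  has_mo <- !is.null(sites$gt_mother) && any(!is.na(sites$gt_mother))
  has_fa <- !is.null(sites$gt_father) && any(!is.na(sites$gt_father))
  in_roh <- function(pos) {
    if (nrow(roh) == 0L) rep(FALSE, length(pos))
    else vapply(pos, function(p) any(roh$start <= p & roh$end >= p), logical(1))
  }
  none <- structure(list(kind = "none", parent = "undetermined",
                         evidence = c(informative = 0L)), class = "upd_call")

  if (has_mo && has_fa) {
    # child homozygous for an allele one parent cannot transmit
    opp <- c(hom_ref = "hom_alt", hom_alt = "hom_ref")
    child_hom <- sites$gt_child %in% names(opp)
    not_from_fa <- child_hom & !is.na(sites$gt_father) &
      sites$gt_father == opp[sites$gt_child]
    not_from_mo <- child_hom & !is.na(sites$gt_mother) &
      sites$gt_mother == opp[sites$gt_child]
    n_mat <- sum(not_from_fa)  # both alleles maternal
    n_pat <- sum(not_from_mo)
    n_considered <- sum(!is.na(sites$gt_mother) & !is.na(sites$gt_father))
    if (max(n_mat, n_pat) < min_informative ||
        max(n_mat, n_pat) < min_informative_frac * n_considered) {
      return(none)
    }
    contradictory <- min(n_mat, n_pat) >= min_informative &&
      min(n_mat, n_pat) > 0.2 * max(n_mat, n_pat)
    if (contradictory) {
      return(structure(list(kind = "none", parent = "undetermined",
                            evidence = c(maternal = n_mat, paternal = n_pat,
                                         warning = 1L)),
                       class = "upd_call"))
    }
    parent <- if (n_mat >= n_pat) "maternal" else "paternal"
    ev_pos <- sites$pos[if (parent == "maternal") not_from_fa else not_from_mo]
    iso <- mean(in_roh(ev_pos)) >= 0.5
    # trimmed span: sporadic genotype errors scattered over the chromosome
    # must not make confined evidence look chromosome-wide
    core <- stats::quantile(ev_pos, c(0.05, 0.95), names = FALSE)
    segmental <- (core[2] - core[1]) < segmental_max_span * chrom_len
    kind <- if (iso && segmental) "segmental-isodisomy"
    else if (iso) "isodisomy" else "heterodisomy"
    return(structure(list(kind = kind, parent = parent,
                          evidence = c(informative = max(n_mat, n_pat),
                                       in_roh = sum(in_roh(ev_pos)))),
                     class = "upd_call"))
  }

  if (has_mo || has_fa) {
    parent <- if (has_mo) "maternal" else "paternal"
    gp <- if (has_mo) sites$gt_mother else sites$gt_father
    if (nrow(roh) == 0L) return(none)
    hom <- sites$gt_child %in% c("hom_ref", "hom_alt") & !is.na(gp) &
      in_roh(sites$pos)
    if (sum(hom) < min_informative) return(none)
    # parent carries the child's homozygous allele unless homozygous for
    # the opposite allele
    opp <- c(hom_ref = "hom_alt", hom_alt = "hom_ref")
    compatible <- gp[hom] != opp[sites$gt_child[hom]]
    if (mean(compatible) < 0.99) return(none)
    span <- sum(roh$end - roh$start)
    segmental <- span < segmental_max_span * chrom_len
    kind <- if (segmental) "segmental-isodisomy" else "isodisomy"
    return(structure(list(kind = kind, parent = parent,
                          evidence = c(informative = sum(hom),
                                       compatible = sum(compatible))),
                     class = "upd_call"))
  }
  none
}

#' @export
print.upd_call <- function(x, ...) {
  cat(sprintf("UPD call: %s (%s); evidence: %s\n", x$kind, x$parent,
              paste(names(x$evidence), x$evidence, sep = "=",
                    collapse = ", ")))
  invisible(x)
}
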