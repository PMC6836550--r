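#' Caller output container
#'
#' One pseudo-caller's call set for one sample. The toolkit abstracts the
#' two complementary short-read SV callers as `coverage` (read-depth based:
#' robust for large and repeat-flanked CNVs, blind below ~5 kb and to
#' breakpoint detail) and `pairedread` (discordant-pair based: exact
#' breakpoints, blind inside repeats).
#'
#' @param sample_id Sample label.
#' @param caller `"coverage"` or `"pairedread"`.
#' @param records [sv_records()] table; all rows must carry this caller.
#' @return A `caller_output` object.
#' @export
caller_output <- function(sample_id, caller, records) {
  caller <- match.arg(caller, c("coverage", "pairedread"))
  validate_sv_records(records)
  if (nrow(records) > 0 && !all(records$caller == caller)) {
    stop("all records must carry caller '", caller, "'", call. = FALSE)
  }
  structure(list(sample_id = sample_id, caller = caller, records = records),
            class = "caller_output")
}

#' Merge SV calls from multiple callers
#'
#' Single-linkage clustering of SV calls in the style of multi-caller SV
#' database merging: two records merge iff they have the same `sv_type` and
#' either both breakpoint distances are at most `bp_tol` or their
#' reciprocal overlap is at least `min_reciprocal_overlap`. Merging is
#' transitive; the output is independent of input order. Each cluster's
#' representative is the member with the highest `pe_support` (ties broken
#' by smallest start, then id).
#'
#' @param outputs List of [caller_output()] objects (or a single one).
#' @param bp_tol Breakpoint distance tolerance in bp.
#' @param min_reciprocal_overlap Reciprocal overlap fraction in (0, 1].
#' @return A `merged_calls` data frame: representative columns plus
#'   `callers` (comma-separated set), `n_members`, and a `members`
#'   list-column of (sample_id, caller, record) data frames.
#' @export
merge_callers <- function(outputs, bp_tol = 200, min_reciprocal_overlap = 0.7) {
  stopifnot(bp_tol >= 0, min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  if (inherits(outputs, "caller_output")) outputs <- list(outputs)
  pooled <- pool_outputs(outputs)
  if (nrow(pooled) == 0L) return(empty_merged())
  comp <- sv_link_components(pooled, bp_tol, min_reciprocal_overlap)
  build_merged(pooled, comp)
}

pool_outputs <- function(outputs) {
  dfs <- lapply(outputs, function(o) {
    if (inherits(o, "caller_output")) {
      r <- as.data.frame(o$records)
      if (nrow(r) > 0) r$sample_id <- o$sample_id
      else r$sample_id <- character(0)
      r
    } else {
      stop("merge_callers expects caller_output objects", call. = FALSE)
    }
  })
  out <- do.call(rbind, dfs)
  if (is.null(out)) out <- cbind(as.data.frame(sv_records()), sample_id = character(0))
  out
}

# Single-linkage components under the merge criterion, via a start-sorted
# sweep per (chrom, sv_type) group and union-find.
sv_link_components <- function(df, bp_tol, min_ro) {
  n <- nrow(df)
  uf <- uf_new(n)
  groups <- split(seq_len(n), paste(df$chrom, df$sv_type))
  for (idx in groups) {
    idx <- idx[order(df$start[idx], df$end[idx])]
    m <- length(idx)
    if (m < 2L) next
    s <- df$start[idx]; e <- df$end[idx]
    for (a in seq_len(m - 1L)) {
      horizon <- max(e[a], s[a] + bp_tol)
      for (b in (a + 1L):m) {
        if (s[b] > horizon) break
        if (sv_pair_match(s[a], e[a], s[b], e[b], bp_tol, min_ro)) {
          uf <- uf_union(uf, idx[a], idx[b])
        }
      }
    }
  }
  uf_components(uf)
}

sv_pair_match <- function(s1, e1, s2, e2, bp_tol, min_ro) {
  if (abs(s1 - s2) <= bp_tol && abs(e1 - e2) <= bp_tol) return(TRUE)
  ov <- min(e1, e2) - max(s1, s2)
  len <- max(e1 - s1, e2 - s2)
  len > 0 && ov >= min_ro * len
}

build_merged <- function(pooled, comp) {
  clusters <- split(seq_len(nrow(pooled)), comp)
  rows <- lapply(clusters, function(ix) {
    mem <- pooled[ix, , drop = FALSE]
    ord <- order(-mem$pe_support, mem$start, mem$id)
    rep <- mem[ord[1], , drop = FALSE]
    rep$callers <- paste(sort(unique(mem$caller)), collapse = ",")
    rep$n_members <- nrow(mem)
    rep$sample_id <- NULL
    rep$members <- I(list(mem[order(mem$sample_id, mem$caller, mem$id), ,
                              drop = FALSE]))
    rep
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("merged_calls", "data.frame")
  out
}

empty_merged <- function() {
  out <- as.data.frame(sv_records())
  out$callers <- character(0)
  out$n_members <- integer(0)
  out$members <- I(list())
  class(out) <- c("merged_calls", "data.frame")
  out
}

#' Build an SV frequency database from a sample cohort
#'
#' Clusters calls across samples with the [merge_callers()] criteria and
#' records, per cluster, the number of distinct samples contributing — the
#' role played by population and laboratory-internal SV frequency
#' databases in a WGS-first workflow.
#'
#' @param per_sample List of [caller_output()] objects, or of
#'   `list(sample_id =, records =)` pairs holding already-merged records.
#' @param n_samples Total samples indexed; defaults to the number of
#'   distinct sample ids supplied.
#' @param bp_tol,min_reciprocal_overlap Merge criteria.
#' @return A `frequency_db`: list with `clusters` (merged_calls plus
#'   `count`) and `n_samples`.
#' @export
build_frequency_db <- function(per_sample, n_samples = NULL,
                               bp_tol = 200, min_reciprocal_overlap = 0.7) {
  norm <- lapply(per_sample, function(o) {
    if (inherits(o, "caller_output")) {
      list(sample_id = o$sample_id, records = o$records)
    } else if (is.list(o) && !is.null(o$sample_id) && !is.null(o$records)) {
      o
    } else stop("unrecognised per-sample element", call. = FALSE)
  })
  ids <- vapply(norm, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(norm, function(o) {
    r <- as.data.frame(o$records)
    r$sample_id <- if (nrow(r) > 0) o$sample_id else character(0)
    r
  }))
  if (is.null(n_samples)) n_samples <- length(ids)
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(structure(list(clusters = empty_merged(), n_samples = n_samples),
                     class = "frequency_db"))
  }
  comp <- sv_link_components(pooled, bp_tol, min_reciprocal_overlap)
  merged <- build_merged(pooled, comp)
  merged$count <- vapply(merged$members, function(m) {
    length(unique(m$sample_id))
  }, integer(1))
  stopifnot(all(merged$count <= n_samples))
  structure(list(clusters = merged, n_samples = n_samples,
                 bp_tol = bp_tol, min_reciprocal_overlap = min_reciprocal_overlap),
            class = "frequency_db")
}

#' Query the allele frequency of an SV in a frequency database
#'
#' Matches the record against database clusters under the same criteria
#' used to build the database and returns `count / n_samples` of the
#' best-matching cluster (largest overlap, then nearest breakpoints), or 0
#' when no cluster matches.
#'
#' @param record One-row [sv_records()] table (or a row of one).
#' @param db A [build_frequency_db()] result.
#' @return Allele frequency in \[0, 1\].
#' @export
query_af <- function(record, db) {
  stopifnot(inherits(db, "frequency_db"))
  if (db$n_samples == 0) stop("frequency database indexes zero samples", call. = FALSE)
  cl <- db$clusters
  if (nrow(cl) == 0L) return(0)
  bp_tol <- db$bp_tol %||% 200
  min_ro <- db$min_reciprocal_overlap %||% 0.7
  cand <- which(cl$chrom == record$chrom & cl$sv_type == record$sv_type)
  if (length(cand) == 0L) return(0)
  ok <- vapply(cand, function(i) {
    sv_pair_match(record$start, record$end, cl$start[i], cl$end[i],
                  bp_tol, min_ro)
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0L) return(0)
  ov <- pmin(record$end, cl$end[cand]) - pmax(record$start, cl$start[cand])
  d <- abs(record$start - cl$start[cand]) + abs(record$end - cl$end[cand])
  best <- cand[order(-ov, d)][1]
  cl$count[best] / db$n_samples
}

#' Filtering cascade configuration
#'
#' Thresholds of the size/quality/frequency/decoy cascade. Defaults encode
#' the clinical WGS-first workflow: intergenic CNVs kept above 10 kb and
#' intragenic above 2 kb; paired-read-only calls need at least 6 discordant
#' pairs; coverage-only calls at least 5 kb; population SV frequency at
#' most 0.5% and internal database frequency below 1%; panel SNVs below 1%
#' minor allele frequency. The frequency operators are deliberately
#' explicit about boundary semantics: population frequency exactly at the
#' bound is retained (`<=`), internal frequency exactly at the bound is
#' removed (`<`).
#'
#' @param min_intergenic_bp,min_intragenic_bp,min_pe_support,min_coverage_call_bp,max_af_population,max_af_internal,decoy_contigs,snv_max_maf
#'   Cascade thresholds; see Details.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_intergenic_bp = 10000,
                          min_intragenic_bp = 2000,
                          min_pe_support = 6,
                          min_coverage_call_bp = 5000,
                          max_af_population = 0.005,
                          max_af_internal = 0.01,
                          decoy_contigs = c("hs37d5", "NC_007605"),
                          snv_max_maf = 0.01) {
  stopifnot(min_intergenic_bp >= 0, min_intragenic_bp >= 0,
            min_pe_support >= 0, min_coverage_call_bp >= 0,
            max_af_population >= 0, max_af_population <= 1,
            max_af_internal >= 0, max_af_internal <= 1,
            snv_max_maf >= 0, snv_max_maf <= 1)
  structure(list(min_intergenic_bp = min_intergenic_bp,
                 min_intragenic_bp = min_intragenic_bp,
                 min_pe_support = min_pe_support,
                 min_coverage_call_bp = min_coverage_call_bp,
                 max_af_population = max_af_population,
                 max_af_internal = max_af_internal,
                 decoy_contigs = decoy_contigs,
                 snv_max_maf = snv_max_maf),
            class = "filter_config")
}

is_decoy <- function(chrom, cfg) {
  !is.na(chrom) & (chrom %in% cfg$decoy_contigs | grepl("decoy", chrom))
}

#' Classify a call as intragenic or intergenic
#'
#' A record is intragenic iff its interval overlaps at least one gene
#' interval of the panel by at least 1 bp.
#'
#' @param record One-row [sv_records()] table.
#' @param genes A [panel()].
#' @return `"intragenic"` or `"intergenic"`; the overlapped gene symbols
#'   are attached as attribute `"genes"`.
#' @export
classify_context <- function(record, genes) {
  hits <- overlapped_genes(record, genes)
  out <- if (nzchar(hits)) "intragenic" else "intergenic"
  attr(out, "genes") <- hits
  out
}

overlapped_genes <- function(records, p) {
  if (nrow(records) == 0L) return(character(0))
  hits <- GenomicRanges::findOverlaps(sv_granges(records), panel_granges(p))
  out <- rep("", nrow(records))
  if (length(hits) > 0) {
    by_rec <- split(p$genes$gene[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    out[as.integer(names(by_rec))] <-
      vapply(by_rec, function(g) paste(sort(unique(g)), collapse = ","),
             character(1))
  }
  out
}

#' Apply the size/quality/frequency/decoy filtering cascade
#'
#' Stages are applied in order; a call is counted in the tally at the first
#' stage that removes it.
#' \enumerate{
#'   \item size — intergenic calls kept iff longer than
#'     `min_intergenic_bp`; intragenic calls iff longer than
#'     `min_intragenic_bp`.
#'   \item quality — calls supported only by the paired-read caller need
#'     `pe_support >= min_pe_support`; calls supported only by the coverage
#'     caller need length `>= min_coverage_call_bp`; calls seen by both
#'     pass.
#'   \item frequency — kept iff population frequency `<=`
#'     `max_af_population` and internal frequency `<` `max_af_internal`
#'     (queried from the databases when supplied, else taken from the
#'     record annotations, missing treated as 0).
#'   \item decoy — any breakend on a decoy contig removes the call.
#' }
#' The filter is idempotent and `sum(tally) + nrow(retained) == nrow(calls)`.
#'
#' @param calls `merged_calls` data frame from [merge_callers()].
#' @param cfg A [filter_config()].
#' @param genes A [panel()] for intragenic/intergenic classification.
#' @param pop_db,int_db Optional [build_frequency_db()] objects.
#' @return `list(retained = merged_calls, tally = named integer vector)`.
#' @export
filter_callset <- function(calls, cfg = filter_config(), genes,
                           pop_db = NULL, int_db = NULL) {
  tally <- c(size = 0L, quality = 0L, frequency = 0L, decoy = 0L)
  if (nrow(calls) == 0L) return(list(retained = calls, tally = tally))
  len <- calls$end - calls$start
  context <- ifelse(nzchar(overlapped_genes(calls, genes)),
                    "intragenic", "intergenic")
  keep_size <- ifelse(context == "intragenic",
                      len > cfg$min_intragenic_bp,
                      len > cfg$min_intergenic_bp)

  callers <- strsplit(calls$callers, ",", fixed = TRUE)
  keep_quality <- vapply(seq_len(nrow(calls)), function(i) {
    cs <- callers[[i]]
    has_pr <- "pairedread" %in% cs
    has_cov <- "coverage" %in% cs
    if (has_pr && has_cov) TRUE
    else if (has_pr) calls$pe_support[i] >= cfg$min_pe_support
    else if (has_cov) len[i] >= cfg$min_coverage_call_bp
    else TRUE  # provenance unknown (e.g. pre-merged input): not penalised
  }, logical(1))

  afp <- call_af(calls, pop_db, calls$af_population)
  afi <- call_af(calls, int_db, calls$af_internal)
  keep_freq <- afp <= cfg$max_af_population & afi < cfg$max_af_internal

  keep_decoy <- !(is_decoy(calls$chrom, cfg) | is_decoy(calls$partner_chrom, cfg))

  first_fail <- rep(NA_character_, nrow(calls))
  first_fail[!keep_size] <- "size"
  first_fail[is.na(first_fail) & !keep_quality] <- "quality"
  first_fail[is.na(first_fail) & !keep_freq] <- "frequency"
  first_fail[is.na(first_fail) & !keep_decoy] <- "decoy"
  tt <- table(factor(first_fail, levels = names(tally)))
  tally[names(tt)] <- as.integer(tt)

  retained <- calls[is.na(first_fail), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, tally = tally)
}

call_af <- function(calls, db, fallback) {
  if (is.null(db)) {
    out <- fallback
    out[is.na(out)] <- 0
    return(out)
  }
  vapply(seq_len(nrow(calls)), function(i) query_af(calls[i, ], db), numeric(1))
}

#' Rescue small panel-gene calls regardless of size
#'
#' Returns calls — before the size filter but after the frequency (and
#' decoy) stages — that have at least one breakpoint junction inside a
#' panel gene interval, whatever their size. The union with
#' [filter_callset()] output is duplicate-free (by record id).
#'
#' @inheritParams filter_callset
#' @param all_calls `merged_calls` data frame (the unfiltered call set).
#' @param panel A [panel()] of rescue genes.
#' @return `merged_calls` subset.
#' @export
panel_rescue <- function(all_calls, panel, cfg = filter_config(),
                         pop_db = NULL, int_db = NULL) {
  stopifnot(nrow(panel$genes) > 0)
  if (nrow(all_calls) == 0L) return(all_calls)
  afp <- call_af(all_calls, pop_db, all_calls$af_population)
  afi <- call_af(all_calls, int_db, all_calls$af_internal)
  keep_freq <- afp <= cfg$max_af_population & afi < cfg$max_af_internal
  keep_decoy <- !(is_decoy(all_calls$chrom, cfg) |
                    is_decoy(all_calls$partner_chrom, cfg))
  bp_in_panel <- vapply(seq_len(nrow(all_calls)), function(i) {
    r <- all_calls[i, ]
    pts <- data.frame(chrom = c(r$chrom, r$chrom, r$partner_chrom),
                      pos = c(r$start, r$end, r$partner_pos))
    pts <- pts[!is.na(pts$chrom) & !is.na(pts$pos), , drop = FALSE]
    any(vapply(seq_len(nrow(pts)), function(k) {
      any(panel$genes$chrom == pts$chrom[k] &
            panel$genes$start <= pts$pos[k] &
            panel$genes$end >= pts$pos[k])
    }, logical(1)))
  }, logical(1))
  out <- all_calls[keep_freq & keep_decoy & bp_in_panel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine filtered and rescued call sets without duplicates
#'
#' @param filtered,rescued `merged_calls` data frames.
#' @return `merged_calls` union, duplicate record ids removed.
#' @export
union_calls <- function(filtered, rescued) {
  out <- rbind(filtered, rescued[!(rescued$id %in% filtered$id), , drop = FALSE])
  out <- out[order(out$chrom, out$start, out$end, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("merged_calls", "data.frame")
  out
}

#' Filter panel SNVs by minor allele frequency
#'
#' Keeps variants with minor allele frequency below the configured bound
#' (missing treated as 0) that fall in a panel gene.
#'
#' @param records Data frame with columns `gene` and `maf_pop`.
#' @param panel A [panel()].
#' @param cfg A [filter_config()].
#' @return Retained subset of `records`.
#' @export
filter_snvs <- function(records, panel, cfg = filter_config()) {
  maf <- records$maf_pop
  maf[is.na(maf)] <- 0
  stopifnot(all(maf >= 0 & maf <= 1))
  keep <- maf < cfg$snv_max_maf & records$gene %in% panel$genes$gene
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
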