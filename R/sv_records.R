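#' Structural-variant record tables
#'
#' SV call sets are stored as a plain data frame (class `sv_records`) with
#' one row per call and the columns
#' \describe{
#'   \item{id}{opaque record identifier}
#'   \item{chrom, start, end}{interval; length is `end - start`}
#'   \item{sv_type}{one of DEL, DUP, INV, INS, BND}
#'   \item{caller}{`coverage`, `pairedread` or `merged`}
#'   \item{pe_support}{discordant read-pair support (0 when unknown)}
#'   \item{copy_number}{integer copy number or NA}
#'   \item{af_population, af_internal}{allele frequencies in \[0, 1\] or NA}
#'   \item{genes}{comma-separated gene symbols ("" when none)}
#'   \item{classification}{five-tier label (benign .. pathogenic) or NA}
#'   \item{partner_chrom, partner_pos, partner_orient}{breakend partner for
#'     BND records; `partner_orient` is two letters, the retained reference
#'     side at the local and partner breakend (`"LR"`, `"LL"`, `"RL"`,
#'     `"RR"`, where L = sequence left of the position is retained)}
#' }
#'
#' @param id,chrom,start,end,sv_type,caller,pe_support,copy_number,af_population,af_internal,genes,classification,partner_chrom,partner_pos,partner_orient
#'   Column vectors, recycled to a common length.
#' @return An `sv_records` data frame.
#' @export
sv_records <- function(id = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       sv_type = character(), caller = "merged",
                       pe_support = 0L, copy_number = NA_integer_,
                       af_population = NA_real_, af_internal = NA_real_,
                       genes = "", classification = NA_character_,
                       partner_chrom = NA_character_,
                       partner_pos = NA_real_,
                       partner_orient = NA_character_) {
  n <- max(length(id), length(chrom), length(start), length(end),
           length(sv_type))
  df <- data.frame(
    id = rep_len(as.character(id), n), chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n), end = rep_len(as.numeric(end), n),
    sv_type = rep_len(as.character(sv_type), n),
    caller = rep_len(as.character(caller), n),
    pe_support = rep_len(as.integer(pe_support), n),
    copy_number = rep_len(as.integer(copy_number), n),
    af_population = rep_len(as.numeric(af_population), n),
    af_internal = rep_len(as.numeric(af_internal), n),
    genes = rep_len(as.character(genes), n),
    classification = rep_len(as.character(classification), n),
    partner_chrom = rep_len(as.character(partner_chrom), n),
    partner_pos = rep_len(as.numeric(partner_pos), n),
    partner_orient = rep_len(as.character(partner_orient), n),
    stringsAsFactors = FALSE
  )
  validate_sv_records(df)
  class(df) <- c("sv_records", "data.frame")
  df
}

SV_TYPES <- c("DEL", "DUP", "INV", "INS", "BND")
SV_CALLERS <- c("coverage", "pairedread", "merged")
SV_TIERS <- c("benign", "likely benign", "VUS", "likely pathogenic", "pathogenic")

validate_sv_records <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  stopifnot(all(df$sv_type %in% SV_TYPES))
  stopifnot(all(df$caller %in% SV_CALLERS))
  if (any(df$end < df$start)) {
    stop("sv_records: end < start in record(s) ",
         paste(df$id[df$end < df$start], collapse = ", "), call. = FALSE)
  }
  stopifnot(all(df$pe_support >= 0L))
  af <- c(df$af_population, df$af_internal)
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("sv_records: allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  bad <- !is.na(df$classification) & !(df$classification %in% SV_TIERS)
  if (any(bad)) {
    stop("sv_records: unknown classification tier: ",
         paste(unique(df$classification[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' @export
rbind.sv_records <- function(...) {
  out <- do.call(rbind.data.frame, lapply(list(...), as.data.frame))
  class(out) <- c("sv_records", "data.frame")
  out
}

sv_granges <- function(df) {
  # CNV-style ranges; zero-length records widened to 1 bp for overlap math
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1, end = pmax(df$end, df$start + 1))
  )
}

#' Gene panel
#'
#' A named set of gene intervals (gene bodies or exons), the unit used for
#' intragenic/intergenic classification, panel rescue and SNV panel
#' filtering.
#'
#' @param name Panel label.
#' @param genes Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @return A `panel` object.
#' @export
panel <- function(name, genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$end < genes$start)) stop("panel: end < start", call. = FALSE)
  genes$gene <- as.character(genes$gene)
  structure(list(name = name, genes = genes), class = "panel")
}

#' Read a gene panel from BED
#'
#' Expects 4+ column BED (chrom, start, end, gene symbol). Multiple rows per
#' symbol (exons) are allowed.
#'
#' @param path BED file path.
#' @param name Panel label (defaults to the file name).
#' @return A [panel()] object.
#' @export
read_panel_bed <- function(path, name = basename(path)) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("panel BED needs 4 columns (chrom, start, end, gene)")
  panel(name, data.frame(gene = bed[[4]], chrom = bed[[1]],
                         start = bed[[2]], end = bed[[3]],
                         stringsAsFactors = FALSE))
}

panel_granges <- function(p) {
  GenomicRanges::GRanges(
    p$genes$chrom,
    IRanges::IRanges(start = p$genes$start + 1, end = pmax(p$genes$end, p$genes$start + 1))
  )
}
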