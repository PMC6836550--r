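#' Parse a genomic region string
#'
#' Parses coordinate strings of the form `"chr2:166050817-166679227"` as
#' printed in clinical CNV tables. Comma thousand-separators are tolerated
#' (`"chr3:159,243,721-159,420,409"`).
#'
#' Coordinates are stored as printed; interval length is defined as
#' `end - start` throughout the package (the convention under which the
#' printed sizes of clinical CNV tables are self-consistent), so a
#' degenerate region `chr1:100-100` has length 0.
#'
#' @param text A single region string `"chr<label>:<start>-<end>"`.
#' @return A `genomic_interval`: list with `chrom`, `start`, `end` and a
#'   `length()`-compatible size accessor via [interval_length()].
#' @examples
#' gi <- parse_region("chr2:166050817-166679227")
#' interval_length(gi) # 628410
#' @seealso [parse_iscn()], [format_size()]
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub(",", "", trimws(text))
  m <- regexec("^(chr)?([0-9XYMT]+):([0-9]+)-([0-9]+)$", txt)
  parts <- regmatches(txt, m)[[1]]
  if (length(parts) == 0L) {
    stop("malformed region string: '", text, "'", call. = FALSE)
  }
  start <- as.numeric(parts[4])
  end <- as.numeric(parts[5])
  if (end < start) {
    stop("end < start in region string: '", text, "'", call. = FALSE)
  }
  genomic_interval(paste0("chr", parts[3]), start, end)
}

#' Construct a genomic interval
#'
#' @param chrom Contig label.
#' @param start,end Base coordinates, `end >= start >= 0`.
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(start >= 0, end >= start)
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' Interval length (end - start)
#'
#' @param x A `genomic_interval`.
#' @return Numeric length in bp.
#' @export
interval_length <- function(x) {
  x$end - x$start
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom,
          format(x$start, scientific = FALSE),
          format(x$end, scientific = FALSE))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(format(x), sprintf("(%s)\n", format_size(interval_length(x), "auto")))
  invisible(x)
}

#' Parse an ISCN microarray nomenclature string
#'
#' Parses strings such as
#' `"arr[GRCh37] 2p21p22.1(39053852_42501893)x3 dn"` into a structured
#' record. Multi-segment entries separated by commas yield multiple
#' segments; both `_` and `-` are accepted as coordinate separators. Band
#' tokens are kept verbatim as labels and not interpreted.
#'
#' @param text ISCN array string beginning with `"arr["`.
#' @return An `iscn_record`: list with `build`, `segments` (data frame with
#'   `band`, `chrom`, `start`, `end`, `copy_number`, `inheritance`).
#' @examples
#' r <- parse_iscn("arr[GRCh37] 2p21p22.1(39053852_42501893)x3 dn")
#' r$segments$end - r$segments$start # 3448041
#' @export
parse_iscn <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  mb <- regexec("^arr\\[([^]]+)\\]\\s*(.*)$", txt)
  parts <- regmatches(txt, mb)[[1]]
  if (length(parts) == 0L) {
    stop("ISCN string must begin with 'arr[<build>]': '", text, "'",
         call. = FALSE)
  }
  build <- parts[2]
  body <- parts[3]
  if (!nzchar(body)) {
    stop("ISCN string contains no segments: '", text, "'", call. = FALSE)
  }
  toks <- trimws(strsplit(body, ",")[[1]])
  seg_re <- "^([0-9XY]+)([pq][0-9pqter.]*)\\(([0-9]+)[-_]([0-9]+)\\)x([0-9]+)\\s*(.*)$"
  segs <- lapply(toks, function(tok) {
    m <- regmatches(tok, regexec(seg_re, tok))[[1]]
    if (length(m) == 0L) {
      stop("unparseable ISCN segment: '", tok, "'", call. = FALSE)
    }
    inh <- trimws(m[7])
    inh <- sub("\\(.*\\)$", "", inh)  # drop trailing free-text parentheticals
    inh <- trimws(inh)
    if (!nzchar(inh)) inh <- "unknown"
    if (inh == "not paternal") inh <- "not-paternal"
    if (inh == "not maternal") inh <- "not-maternal"
    data.frame(
      band = paste0(m[2], m[3]),
      chrom = paste0("chr", m[2]),
      start = as.numeric(m[4]),
      end = as.numeric(m[5]),
      copy_number = as.integer(m[6]),
      inheritance = inh,
      stringsAsFactors = FALSE
    )
  })
  segments <- do.call(rbind, segs)
  if (any(segments$end < segments$start)) {
    stop("ISCN segment has end < start: '", text, "'", call. = FALSE)
  }
  structure(list(build = build, segments = segments), class = "iscn_record")
}

#' Format a base-pair length for display
#'
#' Renders sizes in the style of clinical CNV tables: three significant
#' figures for kb and Mb (`"3.45 Mb"`, `"502 kb"`), thousands separators
#' for bp (`"628,410 bp"`). `unit = "auto"` selects bp below 10 kb, kb
#' below 1 Mb, and Mb above.
#'
#' @param length_bp Non-negative length in bp.
#' @param unit One of `"bp"`, `"kb"`, `"Mb"`, `"auto"`.
#' @return Display string.
#' @examples
#' format_size(3448041, "Mb") # "3.45 Mb"
#' format_size(501752, "kb")  # "502 kb"
#' @export
format_size <- function(length_bp, unit = c("auto", "bp", "kb", "Mb")) {
  unit <- match.arg(unit)
  if (is.na(length_bp) || length_bp < 0) {
    stop("length_bp must be a non-negative number", call. = FALSE)
  }
  if (unit == "auto") {
    unit <- if (length_bp < 1e4) "bp" else if (length_bp < 1e6) "kb" else "Mb"
  }
  if (unit == "bp") {
    return(paste(formatC(length_bp, format = "d", big.mark = ","), "bp"))
  }
  div <- if (unit == "kb") 1e3 else 1e6
  val <- signif(length_bp / div, 3)
  # drop trailing zeros ("15 Mb", not "15.0 Mb")
  paste(format(val, trim = TRUE, drop0trailing = TRUE, scientific = FALSE), unit)
}
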