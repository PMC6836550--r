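#' Write structural variants as VCF 4.2
#'
#' Serialises an [sv_records()] table as a VCF 4.2 file. Interval records
#' carry `SVTYPE`, `END` and `SVLEN` (defined as `END - POS`, matching the
#' package-wide length convention); breakend (BND) records use breakend ALT
#' syntax derived from the partner columns. Caller provenance and
#' read-pair support travel in the `CALLER` and `PE` INFO keys, allele
#' frequencies in `AF_POP`/`AF_INT` (6 decimals), copy number in `CN`,
#' gene symbols in `GENES` and the five-tier label in `CLASS` (spaces
#' encoded as underscores). All keys are declared in the header.
#'
#' @param records An [sv_records()] data frame.
#' @param path Output file path.
#' @param genome Optional named vector of contig lengths for `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @seealso [sv_vcf_read()]
#' @export
sv_vcf_write <- function(records, path, genome = NULL) {
  validate_sv_records(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cytowgs",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", names(genome), as.integer(genome))
    },
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End coordinate (length = END - POS)">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Variant length END - POS">',
    '##INFO=<ID=CALLER,Number=1,Type=String,Description="Originating caller (coverage/pairedread/merged)">',
    '##INFO=<ID=PE,Number=1,Type=Integer,Description="Discordant read pair support">',
    '##INFO=<ID=CN,Number=1,Type=Integer,Description="Copy number">',
    '##INFO=<ID=AF_POP,Number=1,Type=Float,Description="Population SV database allele frequency">',
    '##INFO=<ID=AF_INT,Number=1,Type=Float,Description="Internal SV database allele frequency">',
    '##INFO=<ID=GENES,Number=.,Type=String,Description="Overlapped gene symbols">',
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="Five-tier classification, spaces as underscores">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=INV,Description="Inversion">',
    '##ALT=<ID=INS,Description="Insertion">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    info <- c(sprintf("SVTYPE=%s", r$sv_type))
    if (r$sv_type == "BND") {
      alt <- bnd_alt(r)
    } else {
      alt <- sprintf("<%s>", r$sv_type)
      info <- c(info,
                sprintf("END=%d", as.integer(r$end)),
                sprintf("SVLEN=%d", as.integer(r$end - r$start)))
    }
    info <- c(info,
              sprintf("CALLER=%s", r$caller),
              sprintf("PE=%d", r$pe_support),
              if (!is.na(r$copy_number)) sprintf("CN=%d", r$copy_number),
              if (!is.na(r$af_population)) sprintf("AF_POP=%.6f", r$af_population),
              if (!is.na(r$af_internal)) sprintf("AF_INT=%.6f", r$af_internal),
              if (nzchar(r$genes)) sprintf("GENES=%s", r$genes),
              if (!is.na(r$classification)) {
                sprintf("CLASS=%s", gsub(" ", "_", r$classification))
              })
    paste(r$chrom, format(r$start, scientific = FALSE), r$id, "N", alt, ".",
          ".", paste(info, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# breakend ALT string from partner columns; partner_orient is two letters,
# the retained side at the local then partner breakend.
bnd_alt <- function(r) {
  if (is.na(r$partner_chrom) || is.na(r$partner_pos) || is.na(r$partner_orient)) {
    stop("BND record '", r$id, "' lacks partner fields", call. = FALSE)
  }
  p <- sprintf("%s:%s", r$partner_chrom, format(r$partner_pos, scientific = FALSE))
  switch(r$partner_orient,
         LR = sprintf("N[%s[", p),
         LL = sprintf("N]%s]", p),
         RL = sprintf("]%s]N", p),
         RR = sprintf("[%s[N", p),
         stop("unknown partner_orient '", r$partner_orient, "'", call. = FALSE))
}

parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec(
    "^([ACGTN]*)(\\[|\\])([^:]+):([0-9]+)(\\[|\\])([ACGTN]*)$", alt))[[1]]
  if (length(m) == 0L) stop("unparseable breakend ALT '", alt, "'", call. = FALSE)
  t_first <- nzchar(m[2])
  bracket <- m[3]
  orient <- if (t_first && bracket == "[") "LR"
  else if (t_first && bracket == "]") "LL"
  else if (!t_first && bracket == "]") "RL"
  else "RR"
  list(partner_chrom = m[4], partner_pos = as.numeric(m[5]),
       partner_orient = orient)
}

#' Read structural variants from VCF
#'
#' Reads a VCF 4.2 SV file (as written by [sv_vcf_write()] or any caller
#' using `SVTYPE`/`END`/`SVLEN` conventions) into an [sv_records()] table.
#' Records missing `SVTYPE`, or whose `END`/`SVLEN` are mutually
#' inconsistent, raise an error naming the offending data line.
#'
#' @param path VCF file path.
#' @return An [sv_records()] data frame.
#' @export
sv_vcf_read <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(sv_records())
  info_get <- function(key) vcfR::extract.info(v, element = key)
  svtype <- info_get("SVTYPE")
  pos <- as.numeric(fix[, "POS"])
  bad <- which(is.na(svtype) | !nzchar(svtype))
  if (length(bad)) {
    stop("record(s) without SVTYPE at data line(s) ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  end <- suppressWarnings(as.numeric(info_get("END")))
  svlen <- suppressWarnings(as.numeric(info_get("SVLEN")))
  inconsistent <- which(!is.na(end) & !is.na(svlen) & (end - pos) != svlen)
  if (length(inconsistent)) {
    stop("inconsistent END/SVLEN at data line(s) ",
         paste(inconsistent, collapse = ", "), " of ", path, call. = FALSE)
  }
  end[is.na(end) & !is.na(svlen)] <- pos[is.na(end) & !is.na(svlen)] +
    svlen[is.na(end) & !is.na(svlen)]
  bad_end <- which(svtype != "BND" & (is.na(end) | end < pos))
  if (length(bad_end)) {
    stop("missing END/SVLEN or END < POS at data line(s) ",
         paste(bad_end, collapse = ", "), " of ", path, call. = FALSE)
  }
  end[svtype == "BND"] <- pos[svtype == "BND"]

  pe <- suppressWarnings(as.integer(info_get("PE")))
  cn <- suppressWarnings(as.integer(info_get("CN")))
  afp <- suppressWarnings(as.numeric(info_get("AF_POP")))
  afi <- suppressWarnings(as.numeric(info_get("AF_INT")))
  caller <- info_get("CALLER")
  caller[is.na(caller) | !nzchar(caller)] <- "merged"
  genes <- info_get("GENES")
  genes[is.na(genes)] <- ""
  cls <- info_get("CLASS")
  cls <- ifelse(is.na(cls), NA_character_, gsub("_", " ", cls))

  pc <- rep(NA_character_, n); pp <- rep(NA_real_, n); po <- rep(NA_character_, n)
  is_bnd <- svtype == "BND"
  if (any(is_bnd)) {
    parsed <- lapply(fix[is_bnd, "ALT"], parse_bnd_alt)
    pc[is_bnd] <- vapply(parsed, `[[`, character(1), "partner_chrom")
    pp[is_bnd] <- vapply(parsed, `[[`, numeric(1), "partner_pos")
    po[is_bnd] <- vapply(parsed, `[[`, character(1), "partner_orient")
  }

  sv_records(
    id = fix[, "ID"], chrom = fix[, "CHROM"], start = pos, end = end,
    sv_type = svtype, caller = caller,
    pe_support = ifelse(is.na(pe), 0L, pe), copy_number = cn,
    af_population = afp, af_internal = afi, genes = genes,
    classification = cls, partner_chrom = pc, partner_pos = pp,
    partner_orient = po
  )
}
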