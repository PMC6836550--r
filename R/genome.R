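#' Genome model
#'
#' Container describing the reference the simulators and reconstruction
#' operate on: contig lengths, repeat regions prone to non-allelic
#' homologous recombination (where the paired-read pseudo-caller is blind),
#' and optionally a gene panel.
#'
#' @param contigs Named numeric vector of contig lengths.
#' @param repeat_regions Data frame with `chrom`, `start`, `end` (may be
#'   empty).
#' @param gene_models Optional [panel()] of gene models.
#' @return A `genome_model` object.
#' @export
genome_model <- function(contigs = hg19_contigs(),
                         repeat_regions = NULL,
                         gene_models = NULL) {
  stopifnot(is.numeric(contigs), !is.null(names(contigs)))
  if (is.null(repeat_regions)) {
    repeat_regions <- data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), stringsAsFactors = FALSE)
  }
  bad <- !(repeat_regions$chrom %in% names(contigs)) |
    repeat_regions$end > contigs[repeat_regions$chrom]
  if (any(bad)) stop("repeat region outside contig bounds", call. = FALSE)
  structure(list(contigs = contigs, repeat_regions = repeat_regions,
                 gene_models = gene_models), class = "genome_model")
}

#' GRCh37 contig lengths
#'
#' Chromosome lengths of the GRCh37/hg19 primary assembly, used as the
#' default genome model for the simulators.
#'
#' @return Named numeric vector chr1..chr22, chrX, chrY.
#' @export
hg19_contigs <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

in_regions <- function(chrom, pos, regions) {
  if (nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(regions$chrom == chrom[i] & regions$start <= pos[i] &
          regions$end >= pos[i])
  }, logical(1))
}
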