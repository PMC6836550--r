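# Internal helpers shared across modules.

# Disjoint-set (union-find) over 1..n with path compression.
uf_new <- function(n) seq_len(n)

uf_find <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i)
  rj <- uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

uf_components <- function(uf) {
  roots <- vapply(seq_along(uf), function(i) uf_find(uf, i), integer(1))
  match(roots, unique(roots))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Length of the longest common prefix of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1] - 1L
}

# Longest common suffix.
common_suffix_len <- function(a, b) {
  common_prefix_len(reverse_string(a), reverse_string(b))
}

reverse_string <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_missing_num <- function(x) is.null(x) || length(x) == 0L || is.na(x)
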