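# Independent brute-force oracles and small fixture builders used across
# the test files.

# O(n^2) single-linkage clustering oracle over the written merge rule:
# same type, and breakpoints within tol or reciprocal overlap >= ro.
oracle_single_linkage <- function(df, bp_tol, min_ro) {
  n <- nrow(df)
  comp <- seq_len(n)
  pair_ok <- function(a, b) {
    if (df$sv_type[a] != df$sv_type[b] || df$chrom[a] != df$chrom[b]) {
      return(FALSE)
    }
    if (abs(df$start[a] - df$start[b]) <= bp_tol &&
        abs(df$end[a] - df$end[b]) <= bp_tol) {
      return(TRUE)
    }
    ov <- min(df$end[a], df$end[b]) - max(df$start[a], df$start[b])
    len <- max(df$end[a] - df$start[a], df$end[b] - df$start[b])
    len > 0 && ov >= min_ro * len
  }
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a < b && pair_ok(a, b) && comp[a] != comp[b]) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# canonical cluster signature: sorted member-id sets
cluster_signature <- function(merged) {
  sig <- vapply(merged$members, function(m) {
    paste(sort(m$id), collapse = "+")
  }, character(1))
  sort(sig)
}

random_caller_output <- function(sample_id, caller, n, seed,
                                 chroms = c("chr1", "chr2")) {
  set.seed(seed)
  start <- round(runif(n, 1e5, 5e5))
  sv_records(
    id = sprintf("%s_%s_%d", sample_id, caller, seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + round(runif(n, 1e3, 2e5)),
    sv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
    caller = caller,
    pe_support = rpois(n, 10)
  ) |> (\(r) caller_output(sample_id, caller, r))()
}

small_genome <- c(chrA = 1e6, chrB = 8e5)

# reduced genome for fast mosaic property tests: hg19 proportions at 1/20
scaled_genome <- function(factor = 20) {
  genome_model(contigs = round(hg19_contigs() / factor))
}

test_panel <- function() {
  panel("test-panel", data.frame(
    gene = c("GENE1", "GENE2", "GENE3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(200000, 600000, 100000),
    end = c(250000, 610000, 180000)
  ))
}
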