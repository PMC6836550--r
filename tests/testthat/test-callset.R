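test_that("identical calls from both callers merge into one cluster", {
  cov <- caller_output("S1", "coverage", sv_records(
    id = "c1", chrom = "chr1", start = 1e5, end = 2e5, sv_type = "DEL",
    caller = "coverage"))
  pr <- caller_output("S1", "pairedread", sv_records(
    id = "p1", chrom = "chr1", start = 1e5, end = 2e5, sv_type = "DEL",
    caller = "pairedread", pe_support = 9L))
  m <- merge_callers(list(cov, pr))
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "coverage,pairedread")
  expect_equal(m$n_members, 2L)
  # representative is the highest-PE member
  expect_equal(m$id, "p1")
})

test_that("calls on different contigs never merge", {
  pr <- caller_output("S1", "pairedread", sv_records(
    id = c("p1", "p2"), chrom = c("chr1", "chr2"), start = 1e5, end = 2e5,
    sv_type = "DEL", caller = "pairedread"))
  expect_equal(nrow(merge_callers(list(pr))), 2)
  expect_equal(nrow(merge_callers(list())), 0)
})

test_that("merging matches the pairwise single-linkage oracle and is
           permutation-invariant and idempotent", {
  for (seed in 1:5) {
    cov <- random_caller_output("S1", "coverage", 10, seed)
    pr <- random_caller_output("S1", "pairedread", 10, seed + 100)
    m <- merge_callers(list(cov, pr), bp_tol = 200,
                       min_reciprocal_overlap = 0.7)
    pooled <- rbind(as.data.frame(cov$records), as.data.frame(pr$records))
    comp <- oracle_single_linkage(pooled, 200, 0.7)
    oracle_sig <- sort(vapply(split(pooled$id, comp), function(ids) {
      paste(sort(ids), collapse = "+")
    }, character(1)))
    expect_equal(cluster_signature(m), unname(oracle_sig))

    # permutation invariance: reversed inputs, shuffled records
    cov2 <- caller_output("S1", "coverage",
                          cov$records[rev(seq_len(nrow(cov$records))), ])
    m2 <- merge_callers(list(pr, cov2), bp_tol = 200,
                        min_reciprocal_overlap = 0.7)
    expect_equal(cluster_signature(m2), cluster_signature(m))

    # idempotence: re-merging the representatives changes nothing
    reps <- as.data.frame(m)[names(as.data.frame(sv_records()))]
    by_caller <- split(reps, reps$caller)
    outs <- lapply(names(by_caller), function(cl) {
      r <- by_caller[[cl]]
      class(r) <- c("sv_records", "data.frame")
      caller_output("S1", cl, r)
    })
    m3 <- merge_callers(outs, bp_tol = 200, min_reciprocal_overlap = 0.7)
    expect_equal(nrow(m3), nrow(m))
    expect_equal(m3[, c("chrom", "start", "end", "sv_type")],
                 m[, c("chrom", "start", "end", "sv_type")])
  }
})

test_that("frequency database counts distinct carrier samples", {
  carriers <- lapply(1:4, function(i) {
    list(sample_id = sprintf("s%d", i),
         records = sv_records(id = sprintf("s%d_v", i), chrom = "chr2",
                              start = 1e6, end = 2e6, sv_type = "DEL"))
  })
  others <- lapply(5:8, function(i) {
    list(sample_id = sprintf("s%d", i), records = sv_records())
  })
  db <- build_frequency_db(c(carriers, others), n_samples = 400)
  q <- sv_records(id = "q", chrom = "chr2", start = 1e6, end = 2e6,
                  sv_type = "DEL")
  expect_equal(query_af(q[1, ], db), 4 / 400)
  # jittered breakpoints within tolerance still match
  qj <- sv_records(id = "qj", chrom = "chr2", start = 1e6 + 150,
                   end = 2e6 - 150, sv_type = "DEL")
  expect_equal(query_af(qj[1, ], db), 0.01)
  # absent variant
  q0 <- sv_records(id = "q0", chrom = "chr9", start = 1e6, end = 2e6,
                   sv_type = "DEL")
  expect_equal(query_af(q0[1, ], db), 0)
  expect_error(build_frequency_db(list(carriers[[1]], carriers[[1]])),
               "duplicate sample_id")
  empty_db <- build_frequency_db(list(), n_samples = 0)
  expect_error(query_af(q[1, ], empty_db), "zero samples")
})

test_that("planted cohort frequencies equal the generator truth", {
  set.seed(99)
  common <- c(1e6, 1.5e6)   # planted in 30 of 50 samples
  private_owner <- "s07"
  cohort <- lapply(1:50, function(i) {
    sid <- sprintf("s%02d", i)
    recs <- sv_records()
    if (i <= 30) {
      recs <- sv_records(id = paste0(sid, "_common"), chrom = "chr3",
                         start = common[1] + round(runif(1, -100, 100)),
                         end = common[2] + round(runif(1, -100, 100)),
                         sv_type = "DUP")
    }
    if (sid == private_owner) {
      recs <- rbind(recs, sv_records(id = "private", chrom = "chr4",
                                     start = 5e6, end = 5.2e6,
                                     sv_type = "DEL"))
    }
    list(sample_id = sid, records = recs)
  })
  db <- build_frequency_db(cohort)
  expect_equal(db$n_samples, 50)
  qc <- sv_records(id = "qc", chrom = "chr3", start = common[1],
                   end = common[2], sv_type = "DUP")
  expect_equal(query_af(qc[1, ], db), 30 / 50)
  qp <- sv_records(id = "qp", chrom = "chr4", start = 5e6, end = 5.2e6,
                   sv_type = "DEL")
  expect_equal(query_af(qp[1, ], db), 1 / 50)
})

test_that("intragenic context requires >= 1 bp of gene overlap", {
  pan <- test_panel()
  inside <- sv_records(id = "a", chrom = "chr1", start = 210000,
                       end = 240000, sv_type = "DEL")
  expect_equal(as.character(classify_context(inside[1, ], pan)), "intragenic")
  desert <- sv_records(id = "b", chrom = "chr1", start = 400000,
                       end = 450000, sv_type = "DEL")
  expect_equal(as.character(classify_context(desert[1, ], pan)), "intergenic")
  # brute-force per-base check around a gene boundary (gene1: 200000-250000)
  for (endpos in c(199999, 200000, 200001, 200002)) {
    rec <- sv_records(id = "c", chrom = "chr1", start = 150000, end = endpos,
                      sv_type = "DEL")
    overlap_bp <- length(intersect(seq(150000 + 1, endpos),
                                   seq(200000 + 1, 250000)))
    expect_equal(as.character(classify_context(rec[1, ], pan)),
                 if (overlap_bp >= 1) "intragenic" else "intergenic",
                 info = paste("end =", endpos))
  }
})

make_call <- function(id, len, chrom = "chr1", start = 4e5,
                      callers = "coverage,pairedread", pe = 10L,
                      afp = 0, afi = 0, partner_chrom = NA) {
  r <- as.data.frame(sv_records(
    id = id, chrom = chrom, start = start, end = start + len,
    sv_type = "DEL", pe_support = pe, af_population = afp,
    af_internal = afi, partner_chrom = partner_chrom))
  r$callers <- callers
  r$n_members <- 1L
  r$members <- I(list(r[1, seq_len(15)]))
  class(r) <- c("merged_calls", "data.frame")
  r
}

test_that("the filtering cascade applies its stages in order", {
  pan <- test_panel()
  calls <- rbind(
    make_call("small_intergenic", 9000),            # size: 9 kb intergenic
    make_call("big_intergenic", 50000),
    make_call("small_intragenic", 2500, start = 210000),  # > 2 kb in gene
    make_call("weak_pe", 50000, callers = "pairedread", pe = 5L),
    make_call("ok_pe", 50000, callers = "pairedread", pe = 6L),
    make_call("small_coverage", 4500, start = 210000, callers = "coverage"),
    make_call("common_pop", 50000, afp = 0.006),
    make_call("boundary_pop", 50000, afp = 0.005),  # retained: <= bound
    make_call("common_int", 50000, afi = 0.01),     # removed: < bound fails
    make_call("decoy", 50000, partner_chrom = "hs37d5"))
  class(calls) <- c("merged_calls", "data.frame")
  fc <- filter_callset(calls, filter_config(), pan)
  expect_setequal(fc$retained$id,
                  c("big_intergenic", "small_intragenic", "ok_pe",
                    "boundary_pop"))
  expect_equal(sum(fc$tally) + nrow(fc$retained), nrow(calls))
  # each removal is charged to its first failing stage
  expect_equal(fc$tally[["size"]], 1L)
  expect_equal(fc$tally[["quality"]], 2L)
  expect_equal(fc$tally[["frequency"]], 2L)
  expect_equal(fc$tally[["decoy"]], 1L)

  # idempotence
  fc2 <- filter_callset(fc$retained, filter_config(), pan)
  expect_equal(as.data.frame(fc2$retained), as.data.frame(fc$retained))
  expect_true(all(fc2$tally == 0))
})

test_that("retention equals a record-by-record restatement of the rules", {
  pan <- test_panel()
  set.seed(5)
  for (seed in 1:3) {
    cov <- random_caller_output("S1", "coverage", 12, seed * 7)
    pr <- random_caller_output("S1", "pairedread", 12, seed * 7 + 1)
    m <- merge_callers(list(cov, pr))
    m$af_population <- round(runif(nrow(m), 0, 0.01), 4)
    m$af_internal <- round(runif(nrow(m), 0, 0.02), 4)
    fc <- filter_callset(m, filter_config(), pan)
    cfg <- filter_config()
    keep_expected <- vapply(seq_len(nrow(m)), function(i) {
      r <- m[i, ]
      len <- r$end - r$start
      intragenic <- any(pan$genes$chrom == r$chrom &
                          pmin(r$end, pan$genes$end) -
                            pmax(r$start, pan$genes$start) >= 1)
      size_ok <- if (intragenic) len > cfg$min_intragenic_bp
      else len > cfg$min_intergenic_bp
      cs <- strsplit(r$callers, ",")[[1]]
      qual_ok <- if (setequal(cs, "pairedread")) {
        r$pe_support >= cfg$min_pe_support
      } else if (setequal(cs, "coverage")) {
        len >= cfg$min_coverage_call_bp
      } else TRUE
      freq_ok <- r$af_population <= cfg$max_af_population &&
        r$af_internal < cfg$max_af_internal
      size_ok && qual_ok && freq_ok
    }, logical(1))
    expect_setequal(fc$retained$id, m$id[keep_expected])
    expect_equal(sum(fc$tally) + nrow(fc$retained), nrow(m))
  }
})

test_that("panel rescue keeps small in-panel calls without duplicates", {
  pan <- test_panel()
  calls <- rbind(
    make_call("exonic_500bp", 500, start = 210000),   # inside GENE1
    make_call("outside_500bp", 500, start = 4e5),
    make_call("big_in_gene", 50000, start = 210000),
    make_call("common_exonic", 500, start = 210000, afi = 0.05))
  class(calls) <- c("merged_calls", "data.frame")
  rescued <- panel_rescue(calls, pan)
  expect_setequal(rescued$id, c("exonic_500bp", "big_in_gene"))
  fc <- filter_callset(calls, filter_config(), pan)
  u <- union_calls(fc$retained, rescued)
  expect_equal(anyDuplicated(u$id), 0L)
  expect_true(all(c("exonic_500bp", "big_in_gene") %in% u$id))
})

test_that("panel SNVs filter on MAF below 1% and panel membership", {
  pan <- test_panel()
  snvs <- data.frame(gene = c("GENE1", "GENE1", "GENE9", "GENE2"),
                     maf_pop = c(0.009, 0.02, 0.001, NA))
  kept <- filter_snvs(snvs, pan)
  expect_setequal(paste(kept$gene, kept$maf_pop),
                  c("GENE1 0.009", "GENE2 NA"))
})
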