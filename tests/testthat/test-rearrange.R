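del_inv_del <- function() {
  # two deletions flanking an inverted normal-copy segment, printed-style
  # adjacent coordinates
  sv_records(id = c("del1", "inv", "del2"), chrom = "chr2",
             start = c(166050817, 166679228, 166818453),
             end = c(166679227, 166818452, 166939516),
             sv_type = c("DEL", "INV", "DEL"))
}

ring18 <- function() {
  L <- hg19_contigs()[["chr18"]]
  sv_records(id = c("delp", "delq", "fusion"), chrom = "chr18",
             start = c(0, 62984563, 62984563),
             end = c(1652788, L, 62984563),
             sv_type = c("DEL", "DEL", "BND"),
             partner_chrom = c(NA, NA, "chr18"),
             partner_pos = c(NA, NA, 1652788),
             partner_orient = c(NA, NA, "LR"))
}

test_that("records cluster by proximity and breakend linkage", {
  recs <- del_inv_del()
  cl <- cluster_rearrangements(recs)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$records), 3)

  solo <- sv_records(id = "d", chrom = "chr7", start = 1e6, end = 1.05e6,
                     sv_type = "DEL")
  expect_length(cluster_rearrangements(rbind(recs, solo)), 2)

  # duplication on chr3 joined to chr13 through mate breakends
  cross <- sv_records(
    id = c("dup3", "bnd"), chrom = c("chr3", "chr13"),
    start = c(158567751, 79000000), end = c(160802139, 79000000),
    sv_type = c("DUP", "BND"),
    partner_chrom = c(NA, "chr3"), partner_pos = c(NA, 158567751),
    partner_orient = c(NA, "LR"))
  cl2 <- cluster_rearrangements(cross)
  expect_length(cl2, 1)
  expect_setequal(cl2[[1]]$records$chrom, c("chr3", "chr13"))
})

test_that("DEL-INV-DEL reconstructs with the middle segment inverted and
           the deleted segments absent", {
  recs <- del_inv_del()
  st <- reconstruct_derivative(recs, hg19_contigs())
  expect_length(st, 1)
  segs <- st[[1]]$segments
  expect_false(st[[1]]$circular)
  expect_false(st[[1]]$incomplete)
  inverted <- segs[segs$orient == "-", ]
  expect_equal(nrow(inverted), 1)
  expect_equal(inverted$start, 166679228)
  expect_equal(inverted$end, 166818452)
  # deleted material is absent
  mid <- function(s, e) segs$start < e & segs$end > s
  expect_false(any(mid(166050817 + 1, 166679227 - 1)))
  expect_false(any(mid(166818453 + 1, 166939516 - 1)))
  # flanks retained in reference orientation
  expect_equal(segs$orient[1], "+")
  expect_equal(segs$orient[nrow(segs)], "+")
  expect_equal(classify_structure(st, recs), "DEL-INV-DEL")
})

test_that("terminal deletions with a p-q fusion reconstruct as a ring", {
  recs <- ring18()
  st <- reconstruct_derivative(recs, hg19_contigs())
  circ <- Filter(function(s) s$circular, st)
  expect_length(circ, 1)
  expect_equal(circ[[1]]$segments$start, 1652788)
  expect_equal(circ[[1]]$segments$end, 62984563)
  expect_false(circ[[1]]$incomplete)
  expect_equal(classify_structure(st, recs), "ring")
})

test_that("a simple deletion yields a two-segment linear derivative", {
  recs <- sv_records(id = "d", chrom = "chr2", start = 71740967,
                     end = 71749805, sv_type = "DEL")
  st <- reconstruct_derivative(recs, hg19_contigs())
  expect_length(st, 1)
  expect_equal(nrow(st[[1]]$segments), 2)
  expect_equal(st[[1]]$segments$end[1], 71740967)
  expect_equal(st[[1]]$segments$start[2], 71749805)
  expect_equal(classify_structure(st, recs), "simple-DEL")
})

test_that("reconstruction conserves reference bases at their copy number", {
  cases <- list(
    del_inv_del(),
    ring18(),
    sv_records(id = "dup", chrom = "chr3", start = 9453917, end = 12015126,
               sv_type = "DUP"),
    sv_records(id = c("u1", "u2"), chrom = "chr5", start = c(1e7, 2e7),
               end = c(1.2e7, 2.1e7), sv_type = c("DUP", "DUP")),
    sv_records(id = c("d1", "d2"), chrom = "chr5", start = c(1e7, 2e7),
               end = c(1.2e7, 2.1e7), sv_type = c("DEL", "DEL")))
  genome <- hg19_contigs()
  for (recs in cases) {
    st <- reconstruct_derivative(recs, genome)
    # expected multiplicity per fine segment
    juncs <- cytowgs:::derive_junctions(recs, genome = genome)
    segs <- cytowgs:::derive_segments(recs, juncs, genome)
    observed <- rep(0, nrow(segs))
    for (s in st) {
      if (is.null(s$segments)) next
      for (k in seq_len(nrow(s$segments))) {
        covered <- segs$chrom == s$segments$chrom[k] &
          segs$start >= min(s$segments$start[k], s$segments$end[k]) &
          segs$end <= max(s$segments$start[k], s$segments$end[k])
        observed[covered] <- observed[covered] + 1
      }
    }
    expect_equal(observed, segs$copies,
                 info = paste(recs$id, collapse = ","))
  }
})

test_that("topology labels follow the rule table", {
  genome <- hg19_contigs()
  # reciprocal translocation with deletion: 9.3-Mb 4q loss, two 4;7 junctions
  recs <- sv_records(
    id = c("del4", "j1", "j2"), chrom = "chr4",
    start = c(176500000, 176500000, 185800000),
    end = c(185800000, 176500000, 185800000),
    sv_type = c("DEL", "BND", "BND"),
    partner_chrom = c(NA, "chr7", "chr7"),
    partner_pos = c(NA, 8200000, 8200000),
    partner_orient = c(NA, "LR", "RL"))
  st <- reconstruct_derivative(recs, genome)
  expect_equal(classify_structure(st, recs), "reciprocal-translocation")
  expect_length(Filter(function(s) !is.null(s$segments) &&
                         length(unique(s$segments$chrom)) == 2, st), 2)

  # insertional translocation: chr3 segment into chr13 with inverted
  # 69.6-kb acceptor segment
  s3 <- 158567751; e3 <- 160802139; p1 <- 79000000; p2 <- 79069600
  ins <- sv_records(
    id = c("dup3", "j1", "j2", "j3"),
    chrom = c("chr3", "chr13", "chr3", "chr13"),
    start = c(s3, p1, e3, p1), end = c(e3, p1, e3, p1),
    sv_type = c("DUP", "BND", "BND", "BND"),
    partner_chrom = c(NA, "chr3", "chr13", "chr13"),
    partner_pos = c(NA, s3, p2, p2),
    partner_orient = c(NA, "LR", "LL", "RR"))
  st_ins <- reconstruct_derivative(ins, genome)
  expect_equal(classify_structure(st_ins, ins), "insertional-translocation")
  der13 <- Filter(function(s) !is.null(s$segments) &&
                    "chr3" %in% s$segments$chrom &&
                    "chr13" %in% s$segments$chrom, st_ins)
  expect_length(der13, 1)
  expect_true(any(der13[[1]]$segments$orient == "-"))  # inverted acceptor

  # unbalanced translocation: terminal 4q gain replacing terminal 2p loss
  unb <- sv_records(
    id = c("dup4", "del2", "j"), chrom = c("chr4", "chr2", "chr4"),
    start = c(110000000, 0, 110000000),
    end = c(hg19_contigs()[["chr4"]], 27000, 110000000),
    sv_type = c("DUP", "DEL", "BND"),
    partner_chrom = c(NA, NA, "chr2"), partner_pos = c(NA, NA, 27000),
    partner_orient = c(NA, NA, "RR"))
  st_unb <- reconstruct_derivative(unb, genome)
  expect_equal(classify_structure(st_unb, unb), "unbalanced-translocation")

  # synthetic head-to-tail junction: tandem duplication
  td <- sv_records(
    id = c("dup", "j"), chrom = "chr6", start = c(129655050, 129670080),
    end = c(129670080, 129670080), sv_type = c("DUP", "BND"),
    partner_chrom = c(NA, "chr6"), partner_pos = c(NA, 129655050),
    partner_orient = c(NA, "LR"))
  expect_equal(classify_structure(reconstruct_derivative(td, genome), td),
               "tandem-DUP")

  two_dels <- sv_records(id = c("d1", "d2"), chrom = "chr5",
                         start = c(1e7, 2e7), end = c(1.2e7, 2.1e7),
                         sv_type = c("DEL", "DEL"))
  expect_equal(classify_structure(reconstruct_derivative(two_dels, genome),
                                  two_dels), "DEL-NML-DEL")
})

test_that("classification is invariant to record order and mate
           presentation", {
  genome <- hg19_contigs()
  recs <- sv_records(
    id = c("del4", "j1", "j2"), chrom = "chr4",
    start = c(176500000, 176500000, 185800000),
    end = c(185800000, 176500000, 185800000),
    sv_type = c("DEL", "BND", "BND"),
    partner_chrom = c(NA, "chr7", "chr7"),
    partner_pos = c(NA, 8200000, 8200000),
    partner_orient = c(NA, "LR", "RL"))
  lab <- classify_structure(reconstruct_derivative(recs, genome), recs)
  for (perm in list(c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))) {
    r2 <- recs[perm, ]
    expect_equal(classify_structure(reconstruct_derivative(r2, genome), r2),
                 lab)
  }
  # breakends presented from the mate side (swapped loci, mirrored sides)
  mate <- recs
  mate[2, c("chrom", "start", "end", "partner_chrom", "partner_pos",
            "partner_orient")] <-
    list("chr7", 8200000, 8200000, "chr4", 176500000, "RL")
  expect_equal(classify_structure(reconstruct_derivative(mate, genome), mate),
               lab)
})

test_that("duplication topology is read from breakend evidence", {
  dup <- sv_records(id = "dup", chrom = "chr6", start = 129655050,
                    end = 129670080, sv_type = "DUP")
  # head-to-tail self-junction
  tandem_j <- sv_records(id = "j", chrom = "chr6", start = 129670080,
                         end = 129670080, sv_type = "BND",
                         partner_chrom = "chr6", partner_pos = 129655050,
                         partner_orient = "LR")
  expect_equal(duplication_topology(dup[1, ], tandem_j), "tandem")
  # mates on another chromosome
  ins_j <- sv_records(id = "j", chrom = "chr6", start = 129655050,
                      end = 129655050, sv_type = "BND",
                      partner_chrom = "chr13", partner_pos = 79000000,
                      partner_orient = "RL")
  expect_equal(duplication_topology(dup[1, ], ins_j), "inserted")
  # coverage-only call: no junction evidence
  expect_equal(duplication_topology(dup[1, ], sv_records()), "unknown")
})
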