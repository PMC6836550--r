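test_that("parse_region reproduces printed interval sizes", {
  expect_equal(interval_length(parse_region("chr2:166050817-166679227")), 628410)
  expect_equal(interval_length(parse_region("chrX:32493944-33021034")), 527090)
  expect_equal(interval_length(parse_region("chr1:100-100")), 0)
  # thousand separators tolerated
  expect_equal(interval_length(parse_region("chr3:159,243,721-159,420,409")),
               176688)
  expect_error(parse_region("chr1:200-100"), "end < start")
  expect_error(parse_region("banana"), "malformed")
})

test_that("parse_region after formatting is the identity", {
  set.seed(41)
  for (i in 1:25) {
    gi <- genomic_interval(sample(c("chr1", "chr17", "chrX"), 1),
                           s <- sample.int(1e8, 1), s + sample.int(1e6, 1))
    back <- parse_region(format(gi))
    expect_equal(back[c("chrom", "start", "end")],
                 gi[c("chrom", "start", "end")])
  }
})

test_that("parse_iscn handles single and multi-segment strings", {
  r <- parse_iscn("arr[GRCh37] 2p21p22.1(39053852_42501893)x3 dn")
  expect_equal(r$build, "GRCh37")
  expect_equal(nrow(r$segments), 1)
  expect_equal(r$segments$copy_number, 3L)
  expect_equal(r$segments$inheritance, "dn")
  expect_equal(r$segments$end - r$segments$start, 3448041)

  # both "-" and "_" coordinate separators, two segments
  r2 <- parse_iscn(paste0("arr[GRCh37]18p11.32pter(12774-1652788)x1 dn,",
                          "18q22.1qter(62984563_78015117)x1 dn"))
  expect_equal(nrow(r2$segments), 2)
  expect_equal(r2$segments$copy_number, c(1L, 1L))
  expect_equal(r2$segments$chrom, c("chr18", "chr18"))

  r3 <- parse_iscn("arr[GRCh37] 12q24.31(123736705_123740392)x0 (exon 2)")
  expect_equal(r3$segments$copy_number, 0L)

  expect_error(parse_iscn("arr[GRCh37]"), "no segments")
  expect_error(parse_iscn("arr[GRCh37] 2p21(100_200)"), "unparseable")
  expect_error(parse_iscn("not an iscn string"), "arr")
})

test_that("format_size matches clinical table style", {
  expect_equal(format_size(3448041, "Mb"), "3.45 Mb")
  expect_equal(format_size(501752, "kb"), "502 kb")
  expect_equal(format_size(0, "auto"), "0 bp")
  expect_equal(format_size(628410, "bp"), "628,410 bp")
  expect_equal(format_size(2650083, "Mb"), "2.65 Mb")
  # auto unit selection: bp below 10 kb, kb below 1 Mb, Mb above
  expect_equal(format_size(9999), "9,999 bp")
  expect_equal(format_size(10000), "10 kb")
  expect_equal(format_size(999999), "1000 kb")
  expect_equal(format_size(1e6), "1 Mb")
  expect_error(format_size(-5), "non-negative")
})

test_that("SV VCF writing and reading round-trips mixed records", {
  recs <- sv_records(
    id = c("a", "b", "c"), chrom = c("chr1", "chr2", "chr3"),
    start = c(1000, 5000, 9000), end = c(2000, 8000, 9000),
    sv_type = c("DEL", "DUP", "BND"),
    caller = c("coverage", "pairedread", "pairedread"),
    pe_support = c(0L, 12L, 8L), copy_number = c(1L, 3L, NA),
    af_population = c(0.001234, NA, 0.5), af_internal = c(NA, 0.01, NA),
    genes = c("GENE1,GENE2", "", ""),
    classification = c("pathogenic", NA, "VUS"),
    partner_chrom = c(NA, NA, "chr18"), partner_pos = c(NA, NA, 123456),
    partner_orient = c(NA, NA, "RL"))
  f <- withr::local_tempfile(fileext = ".vcf")
  sv_vcf_write(recs, f)
  back <- sv_vcf_read(f)
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 1e-9)
  # write(read(write(x))) is stable
  f2 <- withr::local_tempfile(fileext = ".vcf")
  sv_vcf_write(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a large simulated record set round-trips with frequencies", {
  set.seed(11)
  n <- 1000
  start <- sample.int(1e8, n)
  orient <- sample(c("LR", "LL", "RL", "RR"), n, replace = TRUE)
  types <- sample(c("DEL", "DUP", "INV", "BND"), n, replace = TRUE)
  recs <- sv_records(
    id = sprintf("v%04d", seq_len(n)),
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    start = start,
    end = ifelse(types == "BND", start, start + sample.int(1e6, n)),
    sv_type = types,
    caller = sample(c("coverage", "pairedread"), n, replace = TRUE),
    pe_support = rpois(n, 8),
    af_population = round(runif(n), 6),
    af_internal = round(runif(n), 6),
    partner_chrom = ifelse(types == "BND", "chr9", NA),
    partner_pos = ifelse(types == "BND", sample.int(1e8, n), NA),
    partner_orient = ifelse(types == "BND", orient, NA))
  f <- withr::local_tempfile(fileext = ".vcf")
  sv_vcf_write(recs, f)
  back <- sv_vcf_read(f)
  expect_equal(back$af_population, recs$af_population, tolerance = 1e-6)
  expect_equal(back$af_internal, recs$af_internal, tolerance = 1e-6)
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 1e-6)
})

test_that("malformed SV VCFs raise per-record errors", {
  expect_error(
    sv_records(id = "x", chrom = "chr1", start = 500, end = 100,
               sv_type = "DEL"),
    "end < start")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chr1\t1000\tx\tN\t<DEL>\t.\t.\tEND=2000"), f)
  expect_error(sv_vcf_read(f), "SVTYPE")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chr1\t1000\tx\tN\t<DEL>\t.\t.\tSVTYPE=DEL;END=2000;SVLEN=99"), f)
  expect_error(sv_vcf_read(f), "inconsistent END/SVLEN")
})

test_that("CGH export emits baseline probes and call-proportional log2", {
  g <- c(chrA = 100000, chrB = 45000)
  recs <- sv_records(id = c("d", "u"), chrom = "chrA",
                     start = c(30000, 70000), end = c(60000, 90000),
                     sv_type = c("DEL", "DUP"),
                     copy_number = c(1L, 3L))
  f <- withr::local_tempfile(fileext = ".xml")
  res <- write_cgh(recs, g, spacing = 10000, path = f)
  expect_equal(res$n_probes, floor(100000 / 10000) + floor(45000 / 10000))
  ps <- read_probe_series(f)
  expect_equal(nrow(ps), res$n_probes)
  inside_del <- ps$chrom == "chrA" & ps$pos > 30000 & ps$pos <= 60000
  inside_dup <- ps$chrom == "chrA" & ps$pos > 70000 & ps$pos <= 90000
  expect_true(all(ps$log2[inside_del] == -1))
  expect_equal(ps$log2[inside_dup], rep(log2(3 / 2), sum(inside_dup)),
               tolerance = 1e-6)
  expect_true(all(ps$log2[!inside_del & !inside_dup] == 0))

  # homozygous loss floored at -3; probe count independent of records
  recs0 <- sv_records(id = "h", chrom = "chrB", start = 10000, end = 30000,
                      sv_type = "DEL", copy_number = 0L)
  res0 <- write_cgh(recs0, g, spacing = 10000, path = f)
  expect_equal(res0$n_probes, res$n_probes)
  ps0 <- read_probe_series(f)
  expect_true(all(ps0$log2[ps0$chrom == "chrB" & ps0$pos > 10000 &
                             ps0$pos <= 30000] == -3))

  # empty record list: all-baseline document
  res_empty <- write_cgh(sv_records(), g, spacing = 10000, path = f)
  expect_equal(res_empty$n_probes, res$n_probes)
  expect_true(all(read_probe_series(f)$log2 == 0))

  # record with neither DEL/DUP type nor copy number is skipped, counted
  bad <- sv_records(id = "i", chrom = "chrA", start = 1000, end = 1000,
                    sv_type = "INS")
  expect_warning(res_skip <- write_cgh(bad, g, spacing = 10000, path = f),
                 "skipped")
  expect_equal(res_skip$n_skipped, 1L)

  # document is bit-stable for fixed input
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_cgh(recs, g, spacing = 10000, path = f)
  write_cgh(recs, g, spacing = 10000, path = f2)
  expect_identical(readLines(f), readLines(f2))
  # and is well-formed XML
  expect_silent(xml2::read_xml(f))
})
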