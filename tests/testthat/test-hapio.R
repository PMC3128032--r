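# File formats, window selection and round trips.

test_that("hap-matrix reader returns a structurally sound panel", {
  path <- write_lines_tmp(c(
    "#chrom=chr1",
    "sample_ids s1 s2",
    "rs1 100 A A G A",
    "rs2 200 C C C T",
    "rs3 300 T G G G"))
  panel <- read_haplotypes(path)
  expect_s3_class(panel, "HaplotypePanel")
  expect_equal(nrow(panel$alleles), 4L)    # 2 rows per individual
  expect_equal(length(panel$snp_ids), 3L)
  expect_equal(panel$chrom, "chr1")
  # major allele recoded to 0 at every SNP
  expect_equal(unname(panel$alleles[, 1L]), c(0L, 0L, 1L, 0L))
  expect_equal(unname(panel$alleles[, 3L]), c(1L, 0L, 0L, 0L))
  expect_true(all(panel$alleles %in% 0:1))
})

test_that("hap-matrix reader rejects malformed input with line numbers", {
  expect_error(read_haplotypes(write_lines_tmp(character())), "empty")
  # odd allele-row count: 3 allele columns for 2 declared... wrong field count
  bad <- write_lines_tmp(c("sample_ids s1 s2", "rs1 100 0 1 0"))
  expect_error(read_haplotypes(bad), "line 2")
  # non-increasing positions
  bad2 <- write_lines_tmp(c("sample_ids s1", "rs1 200 0 1", "rs2 100 1 0"))
  expect_error(read_haplotypes(bad2), "strictly increasing")
  # three symbols at one SNP
  bad3 <- write_lines_tmp(c("sample_ids s1 s2", "rs1 100 A C G A"))
  expect_error(read_haplotypes(bad3), "two allele symbols")
})

test_that("VCF reader keeps phased biallelic records and logs skips", {
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "9001", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0|1", "1|1", sep = "\t"),
    paste("chr1", "9002", "rs2", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1|1", sep = "\t"),                       # unphased
    paste("chr1", "9003", "rs3", "A", "G", ".", "PASS", ".", "GT",
          "0|0", "1|0", sep = "\t"),
    paste("chr1", "9004", "rs4", "A", "G", ".", "PASS", ".", "GT",
          "1|1", "0|0", sep = "\t"),
    paste("chr1", "9005", "rs5", "A", "G", ".", "PASS", ".", "GT",
          "0|1", "0|1", sep = "\t")), ext = ".vcf")
  expect_message(panel <- read_haplotypes(vcf, format = "vcf"), "skipped 1")
  expect_equal(length(panel$snp_ids), 4L)
  expect_equal(panel$sample_ids, c("s1", "s2"))
  # VCF POS is 1-based; panel stores 0-based
  expect_equal(panel$positions, c(9000L, 9002L, 9003L, 9004L))
  expect_equal(unname(panel$alleles[, 1L]), c(0L, 1L, 1L, 1L))
})

test_that("CNV table reader parses totals and flags missing/invalid cells", {
  path <- write_lines_tmp(c("cnv_id\tchrom\tstart\tend\ts1\ts2",
                            "cnv1\tchr1\t100\t200\t2\t3",
                            "cnv2\tchr1\t300\t400\t.\t1"))
  cnvs <- read_cnv_table(path)
  expect_equal(cnvs$cnv1$totals, c(s1 = 2L, s2 = 3L))
  expect_true(is.na(cnvs$cnv2$totals[["s1"]]))
  expect_error(read_cnv_table(write_lines_tmp(
    c("cnv_id\tchrom\tstart\tend\ts1", "cnv1\tchr1\t1\t2\t2.5"))),
    "non-integer")
  expect_error(read_cnv_table(write_lines_tmp(
    c("cnv_id\tchrom\tstart\tend\ts1", "cnv1\tchr1\t1\t2\t-1"))),
    "negative")
})

test_that("window selection follows the extension rule and is monotone", {
  panel <- tiny_panel()
  cnv <- tiny_cnv()
  loc1 <- select_window(panel, cnv, 1.0)
  # CNV [10000, 12000), L = 2000 -> window [8000, 14000): spans 3x the CNV
  expect_equal(unname(loc1$window), c(8000, 14000))
  expect_equal(diff(unname(loc1$window)), 3 * (cnv$end - cnv$start))
  expect_equal(loc1$n_snps, 3L)
  loc0 <- select_window(panel, cnv, 0)
  expect_equal(loc0$snp_ids, "rs2")        # only the SNP inside the CNV
  # monotone: smaller extension never adds SNPs
  fs <- c(0, 0.3, 0.5, 1, 2)
  sets <- lapply(fs, function(f) select_window(panel, cnv, f)$snp_ids)
  for (i in seq_len(length(fs) - 1L)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
  }
  # empty window signalled through n_snps = 0
  far <- cnv_record("cnv9", "chr1", 100000L, 100100L, c(s1 = 2L, s2 = 2L))
  expect_equal(select_window(panel, far, 1.0)$n_snps, 0L)
  expect_error(select_window(panel, cnv, -1), "extension_factor")
})

test_that("reader/writer pairs round-trip", {
  panel <- tiny_panel()
  p1 <- tempfile(fileext = ".hap")
  write_haplotypes(panel, p1)
  back <- read_haplotypes(p1)
  expect_equal(back$alleles, panel$alleles)
  expect_equal(back$positions, panel$positions)
  expect_equal(back$chrom, panel$chrom)

  cnvs <- list(tiny_cnv(), cnv_record("cnv2", "chr1", 500L, 900L,
                                      c(s1 = NA, s2 = 4L)))
  p2 <- tempfile(fileext = ".tsv")
  write_cnv_table(cnvs, p2)
  back2 <- read_cnv_table(p2)
  expect_equal(back2$cnv1$totals, cnvs[[1]]$totals)
  expect_equal(back2$cnv2$totals, cnvs[[2]]$totals)

  calls <- data.frame(cnv_id = "cnv1", sample_id = c("s1", "s2", "s3"),
                      copy_hapA = c(1L, 0L, -1L), copy_hapB = c(1L, 2L, -1L),
                      total = c(2L, 2L, 2L),
                      satisfied = c(TRUE, TRUE, FALSE), k = 3L)
  p3 <- tempfile(fileext = ".tsv")
  expect_warning(write_calls(calls, p3), "NA")
  expect_equal(read_calls(p3), calls)
})

test_that("pedigree reader validates structure", {
  ok <- write_lines_tmp(c("child\tfather\tmother", "c1\tf1\tm1"))
  ped <- read_pedigree(ok)
  expect_equal(ped$child, "c1")
  expect_error(read_pedigree(ok, sample_ids = c("c1", "f1")), "not present")
  bad <- write_lines_tmp(c("child\tfather\tmother", "c1\tc1\tm1"))
  expect_error(read_pedigree(bad), "own parent")
})
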