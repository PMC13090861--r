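# Reading and writing of the tabular dialects, with row-level validation.

test_that("variant table round trip preserves fields and handles headers-only files", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  v <- simulate_variant_table(3, 2, seed = 11)
  write_variant_table(v, tmp)
  back <- read_variant_table(tmp)
  expect_equal(nrow(back), 5L)
  for (col in c("sample_id", "chrom", "ref", "alt", "variant_classification",
                "caller_evidence", "effect_class")) {
    expect_identical(back[[col]], v[[col]])
  }
  expect_equal(back$pos, v$pos)
  expect_equal(back$depth, v$depth)
  expect_equal(back$alt_count, v$alt_count)
  expect_equal(back$vaf, v$vaf, tolerance = 1e-9)

  empty <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v[0, ], empty)
  expect_equal(nrow(read_variant_table(empty)), 0L)
})

test_that("invalid variant rows are rejected with their line numbers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "G1\ts1\t1\t100\tA\tT\tMissense_Mutation\tNA\tmutect:KEEP;strelka:PASS\t50\t10",
    "G2\ts1\t2\t200\tC\tG\tSilent\tNA\tmutect:KEEP;strelka:PASS\t30\t40",   # alt > depth
    "G3\ts1\t3\t300\tG\tA\tMissense_Mutation\tNA\tmutect:KEEP\t60\t12"
  )
  write_tiny_variant_file(tmp, rows)
  expect_error(read_variant_table(tmp), "line 3.*alt_count > depth")

  # drop mode keeps the audit trail: read + rejected = input rows
  out <- suppressMessages(read_variant_table(tmp, on_invalid = "drop"))
  rej <- attr(out, "rejected")
  expect_equal(nrow(out) + nrow(rej), 3L)
  expect_equal(rej$line, 3L)
})

test_that("comment lines are skipped but line numbers stay file-accurate", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  header <- paste("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2",
                  "Variant_Classification", "caller_evidence",
                  "t_depth", "t_alt_count", sep = "\t")
  writeLines(c("# generated for testing", header,
               "# interior comment",
               "s1\t1\t100\tA\tT\tMissense_Mutation\tmutect:KEEP;strelka:PASS\t30\t40"),
             tmp)
  expect_error(read_variant_table(tmp), "line 4")
})

test_that("missing mandatory columns are named in the error", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chromosome\tStart_Position", "1\t100"), tmp)
  expect_error(read_variant_table(tmp), "Tumor_Sample_Barcode")
})

test_that("segments read sorted, overlaps are a named validation error", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_copy_number",
               "s1\t1\t200\t300\t4",
               "s1\t1\t1\t100\t2"), tmp)
  seg <- read_segments(tmp)
  expect_equal(seg$start, c(1, 200))
  expect_identical(seg$is_altered, c(FALSE, TRUE))

  writeLines(c("sample\tchrom\tstart\tend\ttotal_copy_number",
               "s1\t1\t1\t100\t3",
               "s1\t1\t50\t150\t1"), tmp)
  expect_error(read_segments(tmp), "\\[1,100\\] and \\[50,150\\]")

  writeLines("sample\tchrom\tstart\tend\ttotal_copy_number", tmp)
  expect_equal(nrow(read_segments(tmp)), 0L)
})

test_that("segment round trip is exact", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  seg <- simulate_segments(1e6, 0.4, 12, seed = 5)
  write_segments(seg, tmp)
  back <- read_segments(tmp)
  expect_equal(back$start, seg$start)
  expect_equal(back$end, seg$end)
  expect_equal(back$total_copy_number, seg$total_copy_number)
  expect_identical(back$is_altered, seg$is_altered)
})

test_that("loci table: vaf from counts, CP clipping tolerance, duplicates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutation_id\tsample_id\tcluster_id\tcellular_prevalence\tref_count\talt_count",
               "m1\ts1\t1\t0.5\t60\t40",
               "m2\ts1\t1\t1.0000000001\t50\t50"), tmp)
  expect_warning(loci <- read_loci_table(tmp), "clipped")
  expect_equal(loci$vaf, c(0.4, 0.5))
  expect_equal(loci$cellular_prevalence, c(0.5, 1))

  writeLines(c("mutation_id\tsample_id\tcellular_prevalence\tref_count\talt_count",
               "m1\ts1\t1.5\t60\t40"), tmp)
  expect_error(read_loci_table(tmp), "outside \\[0,1\\]")

  writeLines(c("mutation_id\tsample_id\tcellular_prevalence\tref_count\talt_count",
               "m1\ts1\t0.5\t60\t40",
               "m1\ts1\t0.6\t70\t30"), tmp)
  expect_error(read_loci_table(tmp), "duplicate mutation_id")
})

test_that("loci round trip preserves values to near machine precision", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  sim <- simulate_subclonal_tumor(c(0.9, 0.3), c(10, 10), seed = 2)
  write_loci_table(sim$loci, tmp)
  back <- read_loci_table(tmp)
  expect_identical(back$mutation_id, sim$loci$mutation_id)
  expect_equal(back$cellular_prevalence, sim$loci$cellular_prevalence,
               tolerance = 1e-9)
  expect_equal(back$vaf, sim$loci$vaf, tolerance = 1e-9)
  expect_equal(back$alt_count, sim$loci$alt_count)
})

test_that("gene intervals: BED half-open coordinates convert at the boundary", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t0\t100\tGENE1", "2\t999\t2000\tGENE2"), tmp)
  g <- read_gene_intervals(tmp, format = "bed")
  expect_equal(g$start, c(1, 1000))
  expect_equal(g$end, c(100, 2000))
  expect_equal(g$end - g$start + 1, c(100, 1001))
})

test_that("cohort table validates unique sample ids and purity range", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thistotype\tpurity\tith",
               "s1\tosteosarcoma\t0.7\t0.5",
               "s2\tewing\t\t0.2"), tmp)
  tbl <- read_cohort_table(tmp)
  expect_equal(tbl$purity, c(0.7, NA))
  expect_equal(tbl$ith, c(0.5, 0.2))

  writeLines(c("sample_id\tpurity", "s1\t1.2"), tmp)
  expect_error(read_cohort_table(tmp), "purity")
  writeLines(c("sample_id\tpurity", "s1\t0.5", "s1\t0.6"), tmp)
  expect_error(read_cohort_table(tmp), "duplicate")
})

test_that("chromosome comparison strips the chr prefix", {
  expect_equal(normalize_chrom(c("chr1", "1", "chrX")), c("1", "1", "X"))
})
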