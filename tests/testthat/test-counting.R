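fixture_fes <- function() sim_fixture()$fes

write_sam <- function(path, records, chrom = "chrS", genome_length = 20000L) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, genome_length),
               records), path)
  path
}

sam_rec <- function(qname, flag, pos, cigar, mapq = 60, chrom = "chrS",
                    rnext = "*", pnext = 0L) {
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, 0L, "*", "*",
        sep = "\t")
}

test_that("a read fully inside one promoter region is counted once", {
  fes <- fixture_fes()  # P1 1001-1600, P2 3001-3600, P3 5001-5600
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(path, sam_rec("r1", 0, 1100, "150M"))
  fc <- count_first_exon_reads(path, fes, alignment_policy())
  expect_equal(unname(fc$counts), c(1L, 0L, 0L))
  expect_equal(fc$library_size, 1L)
})

test_that("a spliced read is assigned by its aligned blocks only", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  # 50M block inside P2 (3001-3600), 1000N gap, 100M in a shared exon region
  write_sam(path, sam_rec("r1", 0, 3500, "50M1000N100M"))
  fc <- count_first_exon_reads(path, fes, alignment_policy(min_overlap = 10))
  expect_equal(unname(fc$counts), c(0L, 1L, 0L))
  # oracle agreement on the same file
  orc <- oracle_count_sam(path, fes, alignment_policy(min_overlap = 10))
  expect_equal(fc$counts, orc$counts)
})

test_that("N, D and S operations contribute no aligned bases", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(path, c(
    sam_rec("r1", 0, 2996, "5M10D30M"),   # M blocks 2996-3000 and 3011-3040
    sam_rec("r2", 0, 2981, "20S20M")))    # M block 2981-3000, S ignored
  fc <- count_first_exon_reads(path, fes,
                               alignment_policy(min_overlap = 30, min_mapq = 0))
  # r1 overlaps P2 (3001-3600) by 30 aligned bases (3011-3040), r2 by none
  expect_equal(unname(fc$counts), c(0L, 1L, 0L))
})

test_that("secondary, supplementary and unmapped records are ignored", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(path, c(
    sam_rec("r1", 0, 1100, "150M"),
    sam_rec("r2", 256, 1100, "150M"),
    sam_rec("r3", 2048, 1100, "150M"),
    sam_rec("r4", 4, 1100, "*")))
  fc <- count_first_exon_reads(path, fes, alignment_policy())
  expect_equal(unname(fc$counts), c(1L, 0L, 0L))
  expect_equal(fc$library_size, 1L)
})

test_that("counts match the per-base expansion oracle on random SAM files", {
  fes <- fixture_fes()
  policies <- list(
    alignment_policy(min_overlap = 1, min_mapq = 0),
    alignment_policy(min_overlap = 10, min_mapq = 20),
    alignment_policy(min_overlap = 25, min_mapq = 30,
                     include_duplicates = FALSE),
    alignment_policy(min_overlap = 5, min_mapq = 0, strandedness = "forward"),
    alignment_policy(min_overlap = 5, min_mapq = 0, strandedness = "reverse"))
  for (seed in 1:10) {
    path <- withr::local_tempfile(fileext = ".sam")
    write_random_sam(path, fes, n_records = 150, seed = seed)
    pol <- policies[[(seed %% length(policies)) + 1L]]
    got <- count_first_exon_reads(path, fes, pol)
    orc <- oracle_count_sam(path, fes, pol)
    expect_equal(got$counts, orc$counts)
    expect_equal(got$library_size, orc$library_size)
  }
})

test_that("raising min_mapq or min_overlap never increases counts", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  write_random_sam(path, fes, n_records = 200, seed = 99)
  base <- count_first_exon_reads(path, fes,
                                 alignment_policy(min_overlap = 1, min_mapq = 0))
  for (mo in c(5, 20, 60)) {
    tighter <- count_first_exon_reads(
      path, fes, alignment_policy(min_overlap = mo, min_mapq = 0))
    expect_true(all(tighter$counts <= base$counts))
  }
  for (mq in c(10, 30, 60)) {
    tighter <- count_first_exon_reads(
      path, fes, alignment_policy(min_overlap = 1, min_mapq = mq))
    expect_true(all(tighter$counts <= base$counts))
  }
})

test_that("fragment mode counts a qualifying pair once", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(path, c(
    sam_rec("f1", 99, 1100, "150M", rnext = "=", pnext = 1300),   # mate 1 in P1
    sam_rec("f1", 147, 1300, "150M", rnext = "=", pnext = 1100))) # mate 2 in P1
  fc <- count_first_exon_reads(path, fes,
                               alignment_policy(count_unit = "fragment"))
  expect_equal(unname(fc$counts), c(1L, 0L, 0L))
  expect_equal(fc$library_size, 1L)

  # mates voting for different promoters are discarded
  path2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(path2, c(
    sam_rec("f1", 99, 1100, "150M", rnext = "=", pnext = 3100),
    sam_rec("f1", 147, 3100, "150M", rnext = "=", pnext = 1100)))
  fc2 <- count_first_exon_reads(path2, fes,
                                alignment_policy(count_unit = "fragment"))
  expect_equal(sum(fc2$counts), 0L)
  expect_equal(fc2$n_discarded, 1L)
})

test_that("RPM normalization follows its definition and is scale invariant", {
  fc <- structure(list(sample_id = "s", gene_id = "g",
                       counts = c(P1 = 100L), library_size = 1000000L,
                       n_discarded = 0L), class = "FirstExonCounts")
  expect_equal(unname(rpm_normalize(fc)$rpm), 100)

  fc$counts <- c(P1 = 0L)
  expect_equal(unname(rpm_normalize(fc)$rpm), 0)

  fc$counts <- c(P1 = 34L, P2 = 16L, P3 = 50L)
  fc$library_size <- 2000000L
  expect_equal(unname(rpm_normalize(fc)$rpm), c(17, 8, 25))

  fc$library_size <- 0L
  expect_error(rpm_normalize(fc), "RPM undefined")
})

test_that("duplicating every record doubles counts and preserves RPM", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  write_random_sam(path, fes, n_records = 120, seed = 5)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body2 <- sub("^r", "s", body)  # same alignments, fresh qnames
  path2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(hdr, sort(c(body, body2))), path2)

  pol <- alignment_policy(min_overlap = 1, min_mapq = 0)
  one <- count_first_exon_reads(path, fes, pol)
  two <- count_first_exon_reads(path2, fes, pol)
  expect_equal(two$counts, one$counts * 2L)
  expect_equal(two$library_size, one$library_size * 2L)
  if (one$library_size > 0 && two$library_size > 0)
    expect_equal(rpm_normalize(two)$rpm, rpm_normalize(one)$rpm)
})

test_that("a file with no passing alignments yields zero counts and a warning", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(path, sam_rec("r1", 4, 1100, "*"))
  expect_warning(fc <- count_first_exon_reads(path, fes, alignment_policy()),
                 "no alignments")
  expect_equal(sum(fc$counts), 0L)
  expect_equal(fc$library_size, 0L)
})

test_that("counts TSV round-trips", {
  fes <- fixture_fes()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(path, c(sam_rec("r1", 0, 1100, "150M"),
                    sam_rec("r2", 0, 3100, "150M")))
  fc <- count_first_exon_reads(path, fes, alignment_policy(), sample_id = "sA")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_first_exon_counts(list(fc), tsv)
  back <- read_first_exon_counts(tsv)[["sA"]]
  expect_equal(back$counts, fc$counts)
  expect_equal(back$library_size, fc$library_size)
})
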