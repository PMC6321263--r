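test_that("parse_gtf maps exon lines to gene and transcript structure", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(path, data.frame(
    chrom = "chr1", start = c(100, 300, 500), end = c(200, 400, 600),
    strand = "+", gene_id = "g1", transcript_id = "t1"))
  genes <- parse_gtf(path)
  expect_length(genes, 1L)
  expect_equal(genes[["g1"]]$gene_id, "g1")
  tx <- genes[["g1"]]$transcripts[["t1"]]
  expect_equal(nrow(tx$exons), 3L)
  expect_equal(tx$exons$start, c(100, 300, 500))
})

test_that("minus-strand exons are stored in transcription order", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(path, data.frame(
    chrom = "chr1", start = c(100, 300), end = c(200, 400),
    strand = "-", gene_id = "g1", transcript_id = "t1"))
  tx <- parse_gtf(path)[["g1"]]$transcripts[["t1"]]
  expect_equal(unlist(tx$exons[1, ]), c(start = 300, end = 400))
})

test_that("parse_gtf rejects malformed lines with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_exon_line("chr1", 1, 50, "+", "g1", "t1"),
    "chr1\tonly\tthree"), path)
  expect_error(parse_gtf(path), "line 2")

  writeLines(c(
    gtf_exon_line("chr1", 1, 50, "+", "g1", "t1"),
    "chr1\tx\texon\t10\t5\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t2\";"),
    path)
  expect_error(parse_gtf(path), "line 2")
})

test_that("transcripts declared without exons are rejected by id", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_exon_line("chr1", 1, 50, "+", "g1", "t1"),
    "chr1\tx\ttranscript\t100\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t_empty\";"),
    path)
  expect_error(parse_gtf(path), "t_empty")
})

test_that("synthetic GTF round-trips through parse_gtf identically", {
  for (strand in c("+", "-")) {
    cfg <- sim_config(strand = strand)
    model <- simulate_gene_model(cfg)
    path <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(model, path)
    reparsed <- parse_gtf(path)[[model$gene_id]]
    for (tid in names(model$transcripts)) {
      expect_equal(reparsed$transcripts[[tid]]$exons,
                   model$transcripts[[tid]]$exons)
      expect_equal(reparsed$transcripts[[tid]]$strand, strand)
    }
  }
})

test_that("non-overlapping first exons are returned untrimmed", {
  fx <- sim_fixture()
  fes <- fx$fes
  expect_named(fes$regions, c("P1", "P2", "P3"))
  for (i in 1:3) {
    fe <- fx$model$transcripts[[i]]$exons[1, ]
    expect_equal(fes$regions[[paste0("P", i)]],
                 data.frame(start = fe$start, end = fe$end))
  }
})

test_that("first exon overlapped by another isoform's exon is trimmed", {
  # first exon of t1 spans 100-250; t2 has an internal exon 200-260
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(path, rbind(
    data.frame(chrom = "chr1", start = c(100, 500), end = c(250, 600),
               strand = "+", gene_id = "g1", transcript_id = "t1"),
    data.frame(chrom = "chr1", start = c(20, 200, 500), end = c(60, 260, 600),
               strand = "+", gene_id = "g1", transcript_id = "t2")))
  gene <- parse_gtf(path)[["g1"]]
  fes <- derive_first_exons(gene, min_unique_length = 25)
  # per-base subtraction oracle
  oracle <- first_exon_unique_bases_oracle(gene, 25)
  expect_equal(fes$regions[[2]], data.frame(start = 100, end = 199))
  got_bases <- unlist(lapply(seq_len(nrow(fes$regions[[2]])), function(i)
    fes$regions[[2]]$start[i]:fes$regions[[2]]$end[i]))
  expect_equal(got_bases, oracle[["100 250"]])
})

test_that("byte-identical first exons collapse to one promoter", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(path, rbind(
    data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600),
               strand = "+", gene_id = "g1", transcript_id = "t1"),
    data.frame(chrom = "chr1", start = c(100, 800), end = c(200, 900),
               strand = "+", gene_id = "g1", transcript_id = "t2"),
    data.frame(chrom = "chr1", start = c(1200, 1500), end = c(1300, 1600),
               strand = "+", gene_id = "g1", transcript_id = "t3")))
  fes <- derive_first_exons(parse_gtf(path)[["g1"]])
  expect_setequal(fes$promoter_transcripts[["P1"]], c("t1", "t2"))
  expect_length(fes$regions, 2L)
})

test_that("unusably short unique residues are excluded with a warning", {
  # t1's first exon 100-250 is covered by t2's exon except 10 bases
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(path, rbind(
    data.frame(chrom = "chr1", start = c(100, 900), end = c(250, 1000),
               strand = "+", gene_id = "g1", transcript_id = "t1"),
    data.frame(chrom = "chr1", start = c(110, 900), end = c(350, 1000),
               strand = "+", gene_id = "g1", transcript_id = "t2"),
    data.frame(chrom = "chr1", start = c(500, 900), end = c(600, 1000),
               strand = "+", gene_id = "g1", transcript_id = "t3")))
  expect_warning(fes <- derive_first_exons(parse_gtf(path)[["g1"]],
                                           min_unique_length = 25),
                 "excluded")
  expect_length(fes$regions, 2L)

  # with only two isoforms the exclusion leaves < 2 usable promoters
  path2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_fixture(path2, rbind(
    data.frame(chrom = "chr1", start = c(100, 900), end = c(250, 1000),
               strand = "+", gene_id = "g1", transcript_id = "t1"),
    data.frame(chrom = "chr1", start = c(110, 900), end = c(260, 1000),
               strand = "+", gene_id = "g1", transcript_id = "t2")))
  expect_error(
    suppressWarnings(derive_first_exons(parse_gtf(path2)[["g1"]],
                                        min_unique_length = 25)),
    "fewer than 2")
})

test_that("unique regions are disjoint and no larger than the first exon", {
  for (seed in 1:100) {
    path <- withr::local_tempfile(fileext = ".gtf")
    random_gene_gtf(path, seed)
    gene <- parse_gtf(path)[["GENE1"]]
    fes <- tryCatch(
      suppressWarnings(derive_first_exons(gene, min_unique_length = 10)),
      error = function(e) NULL)
    if (is.null(fes)) next  # < 2 usable promoters in this draw
    base_sets <- lapply(fes$regions, function(r)
      unlist(lapply(seq_len(nrow(r)), function(i) r$start[i]:r$end[i])))
    # pairwise disjoint (per-base intersection oracle)
    if (length(base_sets) > 1) {
      pairs <- utils::combn(length(base_sets), 2)
      for (j in seq_len(ncol(pairs)))
        expect_length(intersect(base_sets[[pairs[1, j]]],
                                base_sets[[pairs[2, j]]]), 0L)
    }
    # each region no larger than the raw first exon, and matches the
    # per-base subtraction oracle
    oracle <- first_exon_unique_bases_oracle(gene, 10)
    for (pid in names(fes$regions)) {
      tid <- fes$promoter_transcripts[[pid]][1]
      fe <- gene$transcripts[[tid]]$exons[1, ]
      expect_lte(length(base_sets[[pid]]), fe$end - fe$start + 1)
      key <- paste(fe$start, fe$end)
      expect_equal(sort(base_sets[[pid]]), oracle[[key]])
    }
  }
})

test_that("reflecting the genome reflects the first-exon set", {
  fx <- sim_fixture()
  L <- attr(fx$model, "genome_length")
  refl <- reflect_gene_model(fx$model, L)
  fes_r <- derive_first_exons(refl)
  expect_equal(fes_r$strand, "-")
  # P1 stays the 5'-most promoter in transcription direction
  for (pid in names(fx$fes$regions)) {
    orig <- fx$fes$regions[[pid]]
    got <- fes_r$regions[[pid]]
    expect_equal(got$start, rev(L - orig$end + 1))
    expect_equal(got$end, rev(L - orig$start + 1))
  }
})

test_that("BED export uses 0-based half-open coordinates", {
  fx <- sim_fixture()
  path <- withr::local_tempfile(fileext = ".bed")
  write_first_exons_bed(fx$fes, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, vapply(fx$fes$regions, function(r) r$start[1] - 1,
                              numeric(1), USE.NAMES = FALSE))
  expect_equal(bed$V3, vapply(fx$fes$regions, function(r) r$end[1],
                              numeric(1), USE.NAMES = FALSE))
  expect_equal(bed$V4[1], "SIMG1|P1")
  expect_equal(unique(bed$V6), "+")
})
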