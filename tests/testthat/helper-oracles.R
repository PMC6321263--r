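# Independent brute-force oracles and fixture builders used across tests.
# Everything here is deliberately written against the file formats and the
# definitions, never through the package's own code paths.

# ---- GTF fixture builders ---------------------------------------------------

gtf_exon_line <- function(chrom, start, end, strand, gene_id, transcript_id) {
  paste(chrom, "test", "exon", start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";', gene_id, transcript_id),
        sep = "\t")
}

write_gtf_fixture <- function(path, exons) {
  # exons: data.frame chrom,start,end,strand,gene_id,transcript_id
  writeLines(mapply(gtf_exon_line, exons$chrom, exons$start, exons$end,
                    exons$strand, exons$gene_id, exons$transcript_id),
             path)
  path
}

# random multi-isoform gene model as a GTF: 2-4 transcripts, each with a
# random chain of non-overlapping exons; first exons may collide with other
# isoforms' exons arbitrarily
random_gene_gtf <- function(path, seed) {
  set.seed(seed)
  n_tx <- sample(2:4, 1)
  strand <- sample(c("+", "-"), 1)
  rows <- list()
  for (t in seq_len(n_tx)) {
    n_ex <- sample(2:4, 1)
    pos <- sample(500:2000, 1)
    ex <- list()
    for (e in seq_len(n_ex)) {
      len <- sample(30:300, 1)
      ex[[e]] <- c(pos, pos + len - 1)
      pos <- pos + len + sample(50:400, 1)
    }
    ex <- do.call(rbind, ex)
    rows[[t]] <- data.frame(chrom = "chrT", start = ex[, 1], end = ex[, 2],
                            strand = strand, gene_id = "GENE1",
                            transcript_id = paste0("tx", t))
  }
  write_gtf_fixture(path, do.call(rbind, rows))
}

# per-base oracle for first-exon trimming: unique bases of each first exon
first_exon_unique_bases_oracle <- function(model, min_unique_length = 1L) {
  txs <- model$transcripts
  fe_key <- vapply(txs, function(tx) paste(tx$exons$start[1], tx$exons$end[1]),
                   character(1))
  out <- list()
  for (k in unique(fe_key)) {
    members <- names(txs)[fe_key == k]
    r <- as.integer(strsplit(k, " ")[[1]])
    fe_bases <- r[1]:r[2]
    other <- unlist(lapply(txs[setdiff(names(txs), members)], function(tx) {
      unlist(lapply(seq_len(nrow(tx$exons)),
                    function(i) tx$exons$start[i]:tx$exons$end[i]))
    }))
    uniq <- sort(setdiff(fe_bases, other))
    # contiguous runs, drop runs shorter than min_unique_length
    if (length(uniq) > 0) {
      run_id <- cumsum(c(1L, diff(uniq) != 1L))
      runs <- split(uniq, run_id)
      uniq <- sort(unname(unlist(runs[vapply(runs, length, integer(1)) >=
                                        min_unique_length])))
    }
    out[[k]] <- uniq
  }
  out
}

# ---- SAM counting oracle ----------------------------------------------------

# expand a CIGAR into 1-based aligned reference positions (M/=/X only)
cigar_ref_positions <- function(pos, cigar) {
  if (cigar == "*") return(integer(0))
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ref <- pos
  out <- integer(0)
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]", "", op))
    o <- sub("[0-9]+", "", op)
    if (o %in% c("M", "=", "X")) {
      out <- c(out, ref:(ref + n - 1L)); ref <- ref + n
    } else if (o %in% c("D", "N")) {
      ref <- ref + n
    } # I, S, H, P consume no reference
  }
  out
}

# full per-base reimplementation of the counting contract on SAM text
oracle_count_sam <- function(sam_path, fes, policy) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  proms <- names(fes$regions)
  region_bases <- lapply(fes$regions, function(r)
    unlist(lapply(seq_len(nrow(r)), function(i) r$start[i]:r$end[i])))

  recs <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  keep <- vapply(recs, function(f) {
    flag <- as.integer(f[2]); mapq <- as.integer(f[5])
    if (bitwAnd(flag, 4L) != 0L) return(FALSE)       # unmapped
    if (bitwAnd(flag, 256L) != 0L) return(FALSE)     # secondary
    if (bitwAnd(flag, 2048L) != 0L) return(FALSE)    # supplementary
    if (!policy$include_duplicates && bitwAnd(flag, 1024L) != 0L) return(FALSE)
    mapq >= policy$min_mapq
  }, logical(1))
  recs <- recs[keep]
  qnames <- vapply(recs, `[`, character(1), 1L)
  library_size <- if (policy$count_unit == "fragment")
    length(unique(qnames)) else length(recs)

  assign_of <- vapply(recs, function(f) {
    flag <- as.integer(f[2])
    read_strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    if (policy$strandedness == "forward" && read_strand != fes$strand)
      return(NA_character_)
    if (policy$strandedness == "reverse" && read_strand == fes$strand)
      return(NA_character_)
    bases <- cigar_ref_positions(as.integer(f[4]), f[6])
    ov <- vapply(region_bases, function(rb) length(intersect(bases, rb)),
                 integer(1))
    ov[ov < policy$min_overlap] <- 0L
    if (all(ov == 0L)) return(NA_character_)
    best <- which(ov == max(ov))
    if (length(best) > 1L) return("TIE")
    proms[best]
  }, character(1))

  ok <- !is.na(assign_of) & assign_of != "TIE"
  if (policy$count_unit == "fragment") {
    votes <- split(assign_of[ok], qnames[ok])
    v <- vapply(votes, function(x) if (length(unique(x)) == 1L) x[1]
                else "CONFLICT", character(1))
    v <- v[v != "CONFLICT"]
    counts <- table(factor(v, levels = proms))
  } else {
    counts <- table(factor(assign_of[ok], levels = proms))
  }
  list(counts = stats::setNames(as.integer(counts), proms),
       library_size = library_size)
}

# random small SAM over a FirstExonSet's neighborhood with random CIGARs
# drawn from {M, I, D, N, S}; includes secondary/supplementary/duplicate/
# unmapped records and random MAPQ
write_random_sam <- function(path, fes, n_records, seed,
                             genome_length = 20000L) {
  set.seed(seed)
  lo <- max(1L, min(unlist(lapply(fes$regions, `[[`, "start"))) - 500L)
  hi <- max(unlist(lapply(fes$regions, `[[`, "end"))) + 500L
  mk_cigar <- function() {
    n_m <- sample(1:3, 1)
    parts <- character(0)
    if (stats::runif(1) < 0.25) parts <- paste0(sample(1:20, 1), "S")
    for (i in seq_len(n_m)) {
      parts <- c(parts, paste0(sample(5:120, 1), "M"))
      if (i < n_m)
        parts <- c(parts, paste0(sample(1:800, 1),
                                 sample(c("N", "D", "I"), 1)))
    }
    if (stats::runif(1) < 0.25) parts <- c(parts, paste0(sample(1:20, 1), "S"))
    paste(parts, collapse = "")
  }
  recs <- character(n_records)
  for (i in seq_len(n_records)) {
    flag <- 0L
    r <- stats::runif(1)
    if (r < 0.05) flag <- 4L                # unmapped
    else {
      if (stats::runif(1) < 0.5) flag <- flag + 16L
      if (stats::runif(1) < 0.08) flag <- flag + 256L
      if (stats::runif(1) < 0.08) flag <- flag + 2048L
      if (stats::runif(1) < 0.10) flag <- flag + 1024L
    }
    pos <- sample(lo:hi, 1)
    cig <- if (flag == 4L) "*" else mk_cigar()
    mapq <- sample(0:60, 1)
    recs[i] <- paste(sprintf("r%04d", i), flag, fes$chrom, pos, mapq, cig,
                     "*", 0L, 0L, "*", "*", sep = "\t")
  }
  pos <- as.integer(vapply(strsplit(recs, "\t", fixed = TRUE), `[`,
                           character(1), 4L))
  recs <- recs[order(pos)]
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", fes$chrom, genome_length)),
             path)
  cat(recs, file = path, sep = "\n", append = TRUE)
  path
}

# ---- statistics oracles -----------------------------------------------------

welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

hyper_upper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

median_of_ratios_oracle <- function(m) {
  gm <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  use <- gm > 0
  vapply(seq_len(ncol(m)), function(j)
    stats::median(m[use, j] / gm[use]), numeric(1))
}

# default three-promoter fixture shared by several test files
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config()
      model <- simulate_gene_model(cfg)
      cache <<- list(cfg = cfg, model = model,
                     fes = derive_first_exons(model))
    }
    cache
  }
})
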