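#' Synthetic data with machine-readable truth
#'
#' Generates every input the pipeline consumes: a multi-promoter gene model
#' (GTF), spliced paired-end alignments drawn from a known isoform mixture
#' (SAM, with per-read truth labels), negative-binomial count matrices with
#' planted fold-changes, and term annotations with one planted enriched
#' term.  Reads are emitted as already-aligned SAM records — the pipeline's
#' scope starts at alignments, so no sequence/aligner step is simulated.
#'
#' The default geometry emulates a three-promoter adipogenesis master
#' regulator: three isoforms with distinct equal-length first exons and
#' shared downstream exons, sequenced as 150-nt read pairs with three
#' biological replicates per group.  The default group mixtures reproduce
#' the usage contrast between an obese-breed group (`Min`, first promoter
#' dominant at ~34%) and a lean-breed group (`DL`, first promoter ~19%,
#' second ~31%).  Because the default first exons have equal length and all
#' transcripts share the same total length, the molar isoform mixture
#' equals the expected first-exon read share exactly.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_isoforms number of promoters/isoforms (default 3).
#' @param first_exon_lengths length in bases of each isoform's first exon.
#' @param first_exon_gap intronic gap between consecutive first exons.
#' @param shared_exon_lengths lengths of the downstream exons shared by all
#'   isoforms.
#' @param shared_exon_gaps intronic gap preceding each shared exon.
#' @param chrom,strand,origin placement of the gene on the synthetic genome.
#' @param mixtures named list of per-group isoform molar proportion vectors,
#'   each summing to 1.
#' @param reads_per_sample fragments simulated per sample (default 1e5).
#' @param samples_per_group biological replicates per group (default 3).
#' @param read_length read length in bases (default 150).
#' @param paired paired-end sequencing (default TRUE).
#' @param fragment_mean,fragment_sd fragment-length distribution (bases);
#'   lengths are drawn from the discretized normal truncated to
#'   `[read_length, fragment_mean + 4 * fragment_sd]` (and to the transcript
#'   length).
#' @param soft_clip_max maximum uniform soft-clip at read ends (0 disables;
#'   used only to exercise CIGAR handling).
#' @param seed base random seed; each sample's stream is keyed by
#'   (seed, sample_id).
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_isoforms = 3L,
                       first_exon_lengths = rep(600L, n_isoforms),
                       first_exon_gap = 1400L,
                       shared_exon_lengths = c(1000L, 900L, 1000L),
                       shared_exon_gaps = c(2000L, 1500L, 1500L),
                       chrom = "chrS", strand = "+", origin = 1001L,
                       mixtures = list(Min = c(0.3403, 0.1615, 0.4982),
                                       DL = c(0.1869, 0.3111, 0.5020)),
                       reads_per_sample = 100000L,
                       samples_per_group = 3L,
                       read_length = 150L,
                       paired = TRUE,
                       fragment_mean = 300, fragment_sd = 30,
                       soft_clip_max = 0L,
                       seed = 1L) {
  stopifnot(n_isoforms >= 2L,
            length(first_exon_lengths) == n_isoforms,
            all(first_exon_lengths >= 1L), first_exon_gap >= 1L,
            all(shared_exon_lengths >= 1L), all(shared_exon_gaps >= 1L),
            length(shared_exon_gaps) == length(shared_exon_lengths),
            strand %in% c("+", "-"), reads_per_sample > 0L,
            samples_per_group >= 1L, read_length >= 1L,
            fragment_mean >= read_length, fragment_sd > 0,
            soft_clip_max >= 0L, soft_clip_max <= 5L)
  for (g in names(mixtures)) {
    mx <- mixtures[[g]]
    if (length(mx) != n_isoforms || abs(sum(mx) - 1) > 1e-9 || any(mx < 0))
      stop("mixture for group '", g, "' must be ", n_isoforms,
           " nonnegative proportions summing to 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "SimConfig")
}

# deterministic per-sample RNG key, kept below 2^31
sample_seed <- function(seed, sample_id) {
  h <- sum(utf8ToInt(sample_id) * seq_along(utf8ToInt(sample_id)))
  as.integer((as.numeric(seed) * 10007 + h * 131) %% 2147483647)
}

reflect_interval <- function(start, end, genome_length) {
  data.frame(start = genome_length - end + 1L, end = genome_length - start + 1L)
}

#' Reflect a gene model about its genome
#'
#' Maps position p to `genome_length - p + 1` and flips the strand; used for
#' strand-symmetry checks and to lay out minus-strand genes.
#'
#' @param model a `GeneModel` with a `genome_length` attribute (or supply one).
#' @param genome_length total length of the synthetic genome.
#' @return the reflected `GeneModel`.
#' @export
reflect_gene_model <- function(model, genome_length = attr(model, "genome_length")) {
  stopifnot(inherits(model, "GeneModel"), !is.null(genome_length))
  txs <- lapply(model$transcripts, function(tx) {
    ex <- reflect_interval(tx$exons$start, tx$exons$end, genome_length)
    new_transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                         if (tx$strand == "+") "-" else "+", ex)
  })
  out <- new_gene_model(model$gene_id, txs)
  attr(out, "genome_length") <- genome_length
  out
}

#' Simulate a multi-promoter gene model
#'
#' One gene with `n_isoforms` transcripts: isoform i owns first exon i
#' (mutually non-overlapping) and all isoforms share the same downstream
#' exons, so usage differences are attributable to promoters only.
#'
#' @param cfg a `SimConfig`.
#' @param gtf_path optional path; when given, the model is also serialized
#'   as Ensembl-dialect GTF.
#' @return a `GeneModel` (attribute `genome_length` records the synthetic
#'   genome size).
#' @export
simulate_gene_model <- function(cfg = sim_config(), gtf_path = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  pos <- cfg$origin
  fe <- vector("list", cfg$n_isoforms)
  for (i in seq_len(cfg$n_isoforms)) {
    fe[[i]] <- c(pos, pos + cfg$first_exon_lengths[i] - 1L)
    pos <- fe[[i]][2] + cfg$first_exon_gap + 1L
  }
  pos <- fe[[cfg$n_isoforms]][2]
  shared <- vector("list", length(cfg$shared_exon_lengths))
  for (j in seq_along(cfg$shared_exon_lengths)) {
    s <- pos + cfg$shared_exon_gaps[j] + 1L
    shared[[j]] <- c(s, s + cfg$shared_exon_lengths[j] - 1L)
    pos <- shared[[j]][2]
  }
  genome_length <- pos + 1000L
  gene_id <- "SIMG1"
  txs <- lapply(seq_len(cfg$n_isoforms), function(i) {
    ex <- do.call(rbind, c(fe[i], shared))
    new_transcript_model(sprintf("%s.t%d", gene_id, i), gene_id, cfg$chrom,
                         "+", data.frame(start = ex[, 1], end = ex[, 2]))
  })
  model <- new_gene_model(gene_id, txs)
  attr(model, "genome_length") <- genome_length
  if (cfg$strand == "-") model <- reflect_gene_model(model, genome_length)
  if (!is.null(gtf_path)) write_gtf(model, gtf_path)
  model
}

#' Serialize a GeneModel as Ensembl-dialect GTF
#'
#' Emits one `exon` feature line per exon (ascending coordinates within a
#' transcript) with `gene_id`/`transcript_id` attributes.
#'
#' @param model a `GeneModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(model, path) {
  stopifnot(inherits(model, "GeneModel"))
  lines <- character(0)
  for (tx in model$transcripts) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    lines <- c(lines, paste(
      tx$chrom, "promusage_sim", "exon", ex$start, ex$end, ".", tx$strand, ".",
      sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id, tx$transcript_id),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# cumulative transcript-coordinate map of a transcript (transcription order)
tx_map <- function(tx) {
  w <- tx$exons$end - tx$exons$start + 1L
  data.frame(g_start = tx$exons$start, g_end = tx$exons$end,
             t_start = cumsum(c(1L, w[-length(w)])), t_end = cumsum(w))
}

# exon table in genomic-ascending order with transcript-coordinate spans
tx_map_ascending <- function(tx) {
  map <- tx_map(tx)
  map <- map[order(map$g_start), , drop = FALSE]
  rownames(map) <- NULL
  map
}

# Vectorized projection of transcript intervals [a, b] to genomic blocks.
# Returns pos (leftmost), end (rightmost) and a spliced CIGAR per interval.
project_intervals <- function(tx, a, b) {
  map <- tx_map_ascending(tx)
  E <- nrow(map)
  n <- length(a)
  GS <- GE <- matrix(NA_integer_, n, E)
  for (j in seq_len(E)) {
    lo <- pmax(a, map$t_start[j]); hi <- pmin(b, map$t_end[j])
    ok <- lo <= hi
    if (tx$strand == "+") {
      GS[ok, j] <- map$g_start[j] + (lo[ok] - map$t_start[j])
      GE[ok, j] <- map$g_start[j] + (hi[ok] - map$t_start[j])
    } else {
      GS[ok, j] <- map$g_end[j] - (hi[ok] - map$t_start[j])
      GE[ok, j] <- map$g_end[j] - (lo[ok] - map$t_start[j])
    }
  }
  gaps <- if (E > 1L) map$g_start[-1L] - map$g_end[-E] - 1L else integer(0)
  pieces <- matrix("", n, E)
  for (j in seq_len(E)) {
    ok <- !is.na(GS[, j])
    w <- GE[ok, j] - GS[ok, j] + 1L
    lead_n <- if (j > 1L) {
      prev_ok <- !is.na(GS[ok, j - 1L, drop = TRUE])
      ifelse(prev_ok, paste0(gaps[j - 1L], "N"), "")
    } else ""
    pieces[ok, j] <- paste0(lead_n, w, "M")
  }
  cig <- do.call(paste0, asplit(pieces, 2L))
  list(pos = suppressWarnings(apply(GS, 1L, min, na.rm = TRUE)),
       end = suppressWarnings(apply(GE, 1L, max, na.rm = TRUE)),
       cigar = cig)
}

# map a transcript-coordinate interval [a, b] to ascending genomic blocks
tx_interval_to_genome <- function(map, strand, a, b) {
  hit <- map[map$t_end >= a & map$t_start <= b, , drop = FALSE]
  lo <- pmax(a, hit$t_start); hi <- pmin(b, hit$t_end)
  if (strand == "+") {
    gs <- hit$g_start + (lo - hit$t_start); ge <- hit$g_start + (hi - hit$t_start)
  } else {
    ge <- hit$g_end - (lo - hit$t_start); gs <- hit$g_end - (hi - hit$t_start)
  }
  out <- data.frame(start = gs, end = ge)
  out[order(out$start), , drop = FALSE]
}

# map a genomic interval (inside one exon) to transcript coordinates
genome_interval_to_tx <- function(map, strand, gs, ge) {
  hit <- map[map$g_start <= gs & map$g_end >= ge, , drop = FALSE]
  stopifnot(nrow(hit) == 1L)
  if (strand == "+") c(hit$t_start + (gs - hit$g_start), hit$t_start + (ge - hit$g_start))
  else c(hit$t_start + (hit$g_end - ge), hit$t_start + (hit$g_end - gs))
}

cigar_from_blocks <- function(blocks) {
  w <- blocks$end - blocks$start + 1L
  if (nrow(blocks) == 1L) return(paste0(w, "M"))
  gaps <- blocks$start[-1L] - blocks$end[-nrow(blocks)] - 1L
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
         w[length(w)], "M")
}

# discretized truncated-normal fragment-length pmf
fragment_pmf <- function(cfg, tx_len) {
  if (!cfg$paired)
    return(data.frame(len = cfg$read_length, w = 1))
  lo <- max(cfg$read_length, floor(cfg$fragment_mean - 4 * cfg$fragment_sd))
  hi <- min(tx_len, ceiling(cfg$fragment_mean + 4 * cfg$fragment_sd))
  if (lo > hi) stop("fragments longer than the transcript; shorten fragment_mean",
                    call. = FALSE)
  len <- lo:hi
  w <- stats::pnorm(len + 0.5, cfg$fragment_mean, cfg$fragment_sd) -
       stats::pnorm(len - 0.5, cfg$fragment_mean, cfg$fragment_sd)
  data.frame(len = len, w = w / sum(w))
}

# unique first-exon region(s) of each isoform, in transcript coordinates
unique_regions_tx <- function(model, fes) {
  lapply(names(model$transcripts), function(tid) {
    tx <- model$transcripts[[tid]]
    pid <- NULL
    for (p in names(fes$promoter_transcripts))
      if (tid %in% fes$promoter_transcripts[[p]]) pid <- p
    if (is.null(pid)) return(NULL)
    map <- tx_map(tx)
    r <- fes$regions[[pid]]
    tcoords <- t(vapply(seq_len(nrow(r)), function(i)
      genome_interval_to_tx(map, tx$strand, r$start[i], r$end[i]),
      numeric(2)))
    list(promoter_id = pid,
         regions = data.frame(start = tcoords[, 1], end = tcoords[, 2]))
  })
}

#' Expected first-exon read shares of an isoform mixture
#'
#' The probability that a simulated fragment of isoform i has at least one
#' aligned base in isoform i's unique first-exon region, combined with the
#' molar mixture and renormalized: the "read-mass" truth against which the
#' counting estimator is validated.  Computed exactly from the geometry and
#' the discretized fragment-length distribution.
#'
#' @param model a `GeneModel`.
#' @param mixture molar isoform proportions (sums to 1).
#' @param cfg a `SimConfig`.
#' @return named numeric vector of expected read shares per promoter.
#' @export
expected_read_shares <- function(model, mixture, cfg = sim_config()) {
  fes <- derive_first_exons(model, min_unique_length = 1L)
  ur <- unique_regions_tx(model, fes)
  rl <- cfg$read_length
  q <- numeric(length(model$transcripts))
  pid <- character(length(model$transcripts))
  for (i in seq_along(model$transcripts)) {
    tx <- model$transcripts[[i]]
    L <- transcript_length(tx)
    pmf <- fragment_pmf(cfg, L)
    reg <- ur[[i]]$regions
    pid[i] <- ur[[i]]$promoter_id
    qi <- 0
    for (r in seq_len(nrow(pmf))) {
      fl <- pmf$len[r]
      n_start <- L - fl + 1L
      # starts s whose mate1 [s, s+rl-1] or mate2 [s+fl-rl, s+fl-1]
      # touches a unique-region interval
      lo <- pmax(1L, reg$start - rl + 1L)
      hi <- reg$end
      if (cfg$paired) {
        lo2 <- pmax(1L, reg$start - fl + 1L)
        hi2 <- reg$end - fl + rl
        keep <- hi2 >= lo2
        lo <- c(lo, lo2[keep]); hi <- c(hi, hi2[keep])
      }
      hi <- pmin(hi, n_start)
      keep <- hi >= lo
      lo <- lo[keep]; hi <- hi[keep]
      if (length(lo) == 0L) next
      ord <- order(lo)
      lo <- lo[ord]; hi <- hi[ord]
      # union length of sorted intervals
      tot <- 0L; cur_lo <- lo[1]; cur_hi <- hi[1]
      if (length(lo) > 1L) for (j in 2:length(lo)) {
        if (lo[j] > cur_hi + 1L) {
          tot <- tot + (cur_hi - cur_lo + 1L); cur_lo <- lo[j]; cur_hi <- hi[j]
        } else cur_hi <- max(cur_hi, hi[j])
      }
      tot <- tot + (cur_hi - cur_lo + 1L)
      qi <- qi + pmf$w[r] * tot / n_start
    }
    q[i] <- qi
  }
  share <- mixture * q
  stats::setNames(share / sum(share), pid)
}

#' Molar mixture achieving target first-exon read shares
#'
#' Inverts [expected_read_shares()]: returns the molar isoform mixture whose
#' expected first-exon read shares equal `shares` under the given geometry.
#'
#' @param model a `GeneModel`.
#' @param shares target read shares (one per promoter, ordered P1, P2, ...;
#'   sums to 1).
#' @param cfg a `SimConfig`.
#' @return molar proportion vector.
#' @export
mixture_for_shares <- function(model, shares, cfg = sim_config()) {
  stopifnot(abs(sum(shares) - 1) < 1e-9)
  q <- expected_read_shares(model, rep(1 / length(shares), length(shares)), cfg)
  # q above is share under uniform mixture ~ proportional to per-isoform
  # overlap probability; invert
  mx <- shares / q
  unname(mx / sum(mx))
}

#' Simulate spliced alignments from an isoform mixture
#'
#' Each fragment picks an isoform from the molar mixture, a fragment length
#' from the discretized truncated-normal distribution and a uniform start on
#' the transcript; mate intervals are projected through the exon structure
#' to genomic blocks, producing spliced CIGARs (`M` blocks separated by `N`
#' gaps).  Records are valid, coordinate-sorted SAM with a header.  The
#' truth labels a fragment as supporting its promoter iff its aligned bases
#' overlap the isoform's unique first-exon region by at least one base.
#'
#' @param model a `GeneModel` from [simulate_gene_model()].
#' @param mixture molar isoform proportions (sums to 1).
#' @param n_reads number of fragments (read pairs when paired).
#' @param cfg a `SimConfig`.
#' @param sample_id sample label; also keys the RNG stream together with
#'   `cfg$seed`.
#' @param path output SAM path.
#' @return list: `sam` (path), `truth` (list with `per_read` data.frame of
#'   qname/isoform/promoter, truth `counts` per promoter, the `molar`
#'   mixture and exact expected `read_share`).
#' @export
simulate_alignments <- function(model, mixture, n_reads, cfg = sim_config(),
                                sample_id = "S1", path = tempfile(fileext = ".sam")) {
  stopifnot(inherits(model, "GeneModel"),
            abs(sum(mixture) - 1) < 1e-9, n_reads > 0L)
  genome_length <- attr(model, "genome_length")
  if (is.null(genome_length))
    genome_length <- max(vapply(model$transcripts,
                                function(tx) max(tx$exons$end), numeric(1))) + 1000L
  set.seed(sample_seed(cfg$seed, sample_id))

  txs <- model$transcripts
  n_iso <- length(txs)
  maps <- lapply(txs, tx_map)
  lens <- vapply(txs, transcript_length, numeric(1))
  rl <- cfg$read_length
  fes <- derive_first_exons(model, min_unique_length = 1L)
  ur <- unique_regions_tx(model, fes)

  iso <- sample.int(n_iso, n_reads, replace = TRUE, prob = mixture)
  fl <- integer(n_reads)
  for (i in seq_len(n_iso)) {
    sel <- iso == i
    if (!any(sel)) next
    pmf <- fragment_pmf(cfg, lens[i])
    fl[sel] <- if (nrow(pmf) == 1L) pmf$len else
      sample(pmf$len, sum(sel), replace = TRUE, prob = pmf$w)
  }
  if (any(fl > lens[iso]))
    stop("fragment longer than transcript", call. = FALSE)
  s <- 1L + floor(stats::runif(n_reads) * (lens[iso] - fl + 1L))

  # truth: does the fragment touch its isoform's unique region?
  labeled <- rep(NA_character_, n_reads)
  for (i in seq_len(n_iso)) {
    sel <- which(iso == i)
    if (length(sel) == 0L) next
    reg <- ur[[i]]$regions
    hit <- rep(FALSE, length(sel))
    for (j in seq_len(nrow(reg))) {
      ra <- reg$start[j]; rb <- reg$end[j]
      m1 <- s[sel] <= rb & (s[sel] + rl - 1L) >= ra
      hit <- hit | m1
      if (cfg$paired) {
        m2s <- s[sel] + fl[sel] - rl
        hit <- hit | (m2s <= rb & (m2s + rl - 1L) >= ra)
      }
    }
    labeled[sel][hit] <- ur[[i]]$promoter_id
  }

  qname <- sprintf("%s.F%07d", sample_id, seq_len(n_reads))
  sc <- if (cfg$soft_clip_max > 0L)
    matrix(sample.int(cfg$soft_clip_max + 1L, 2L * n_reads, replace = TRUE) - 1L,
           ncol = 2L) else matrix(0L, n_reads, 2L)

  lines <- character(0)
  all_pos <- integer(0)
  for (i in seq_len(n_iso)) {
    sel <- which(iso == i)
    if (length(sel) == 0L) next
    tx <- txs[[i]]
    chrom <- tx$chrom
    if (cfg$paired) {
      a1 <- s[sel] + sc[sel, 1]; b1e <- s[sel] + rl - 1L
      a2 <- s[sel] + fl[sel] - rl; b2e <- s[sel] + fl[sel] - 1L - sc[sel, 2]
      pr1 <- project_intervals(tx, a1, b1e)
      pr2 <- project_intervals(tx, a2, b2e)
      c1 <- pr1$cigar; c2 <- pr2$cigar
      clip1 <- sc[sel, 1] > 0L; clip2 <- sc[sel, 2] > 0L
      if (tx$strand == "+") {
        c1[clip1] <- paste0(sc[sel, 1][clip1], "S", c1[clip1])
        c2[clip2] <- paste0(c2[clip2], sc[sel, 2][clip2], "S")
        f1 <- 99L; f2 <- 147L
      } else {
        c1[clip1] <- paste0(c1[clip1], sc[sel, 1][clip1], "S")
        c2[clip2] <- paste0(sc[sel, 2][clip2], "S", c2[clip2])
        f1 <- 83L; f2 <- 163L
      }
      span <- pmax(pr1$end, pr2$end) - pmin(pr1$pos, pr2$pos) + 1L
      t1 <- ifelse(pr1$pos <= pr2$pos, span, -span)
      l1 <- paste(qname[sel], f1, chrom, pr1$pos, 60L, c1, "=", pr2$pos, t1,
                  "*", "*", sep = "\t")
      l2 <- paste(qname[sel], f2, chrom, pr2$pos, 60L, c2, "=", pr1$pos, -t1,
                  "*", "*", sep = "\t")
      lines <- c(lines, l1, l2)
      all_pos <- c(all_pos, pr1$pos, pr2$pos)
    } else {
      pr1 <- project_intervals(tx, s[sel], s[sel] + rl - 1L)
      flag <- if (tx$strand == "+") 0L else 16L
      lines <- c(lines,
                 paste(qname[sel], flag, chrom, pr1$pos, 60L, pr1$cigar,
                       "*", 0L, 0L, "*", "*", sep = "\t"))
      all_pos <- c(all_pos, pr1$pos)
    }
  }
  lines <- lines[order(all_pos, lines, method = "radix")]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", txs[[1]]$chrom, genome_length))
  writeLines(c(header, lines), path)

  truth_counts <- table(factor(labeled, levels = names(fes$regions)))
  list(sam = path,
       truth = list(
         per_read = data.frame(qname = qname, isoform = names(txs)[iso],
                               promoter = labeled),
         counts = stats::setNames(as.integer(truth_counts),
                                  names(truth_counts)),
         molar = mixture,
         read_share = expected_read_shares(model, mixture, cfg)))
}

#' Multinomial first-exon counts (count-level fast path)
#'
#' Draws per-sample first-exon read counts directly from the truth read
#' shares — the exact sampling distribution of the counts that full
#' alignment simulation plus truth-faithful counting yields.  Used where
#' many replicates are needed (test calibration, convergence studies).
#'
#' @param shares first-exon read shares (named per promoter; sums to 1).
#' @param n_reads first-exon reads per sample.
#' @param n_samples samples to draw.
#' @param seed RNG seed.
#' @param sample_prefix prefix for sample ids.
#' @return list of `FirstExonCounts` (library_size = n_reads).
#' @export
simulate_usage_counts <- function(shares, n_reads, n_samples, seed = 1L,
                                  sample_prefix = "S") {
  stopifnot(abs(sum(shares) - 1) < 1e-9, n_reads > 0L, n_samples >= 1L)
  if (is.null(names(shares))) names(shares) <- paste0("P", seq_along(shares))
  set.seed(as.integer(seed))
  m <- stats::rmultinom(n_samples, n_reads, shares)
  lapply(seq_len(n_samples), function(j) {
    structure(list(sample_id = paste0(sample_prefix, j), gene_id = "SIMG1",
                   counts = stats::setNames(as.integer(m[, j]), names(shares)),
                   library_size = as.integer(n_reads), n_discarded = 0L),
              class = "FirstExonCounts")
  })
}

#' Simulate a count matrix with planted fold-changes
#'
#' Gene means are log-normal across genes; counts are negative binomial
#' (`nb_dispersion = 0` gives the Poisson limit).  A planted fraction of
#' genes has its group-B mean multiplied by `2^(+/- effect_log2fc)` with
#' random sign.
#'
#' @param n_genes number of genes.
#' @param groups named integer vector of samples per group (exactly two
#'   groups), default `c(A = 3, B = 3)`.
#' @param frac_de fraction of genes with a planted effect, in [0, 1].
#' @param effect_log2fc absolute planted log2 fold-change.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be >= 0.
#' @param seed RNG seed.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   gene-mean distribution.
#' @return list: `counts` (gene x sample integer matrix), `lengths` (named
#'   gene lengths, bases), `groups` (sample_id -> group), `truth`
#'   (data.frame gene_id, true_log2fc, is_de).
#' @export
simulate_count_matrix <- function(n_genes = 5000L, groups = c(A = 3L, B = 3L),
                                  frac_de = 0.1, effect_log2fc = 2,
                                  nb_dispersion = 0.05, seed = 1L,
                                  baseline_meanlog = log(100),
                                  baseline_sdlog = 1) {
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]", call. = FALSE)
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  stopifnot(length(groups) == 2L, all(groups >= 1L), !is.null(names(groups)))
  set.seed(as.integer(seed))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  mu <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  n_de <- round(frac_de * n_genes)
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
  sign <- rep(0, n_genes)
  if (n_de > 0) sign[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)
  mu_b <- mu * 2^(sign * effect_log2fc)

  draw <- function(mu_vec, n_samp) {
    m <- matrix(0L, n_genes, n_samp)
    for (j in seq_len(n_samp)) {
      m[, j] <- if (nb_dispersion == 0) stats::rpois(n_genes, mu_vec)
                else stats::rnbinom(n_genes, mu = mu_vec, size = 1 / nb_dispersion)
    }
    m
  }
  counts <- cbind(draw(mu, groups[[1]]), draw(mu_b, groups[[2]]))
  sample_ids <- c(sprintf("%s%d", names(groups)[1], seq_len(groups[[1]])),
                  sprintf("%s%d", names(groups)[2], seq_len(groups[[2]])))
  dimnames(counts) <- list(gene_ids, sample_ids)
  lengths <- stats::setNames(round(stats::runif(n_genes, 500, 5000)), gene_ids)
  group_of <- stats::setNames(rep(names(groups), groups), sample_ids)
  list(counts = counts, lengths = lengths, groups = group_of,
       truth = data.frame(gene_id = gene_ids,
                          true_log2fc = sign * effect_log2fc,
                          is_de = sign != 0))
}

#' Simulate a term annotation with one planted enriched term
#'
#' Random terms draw genes uniformly from the background; the planted term
#' preferentially contains genes from `selected_pool` (defaults to a fresh
#' random selection), so that a query with that pool is enriched for it.
#'
#' @param background character vector of background gene ids, or an integer
#'   size (ids are generated).
#' @param n_terms number of random terms besides the planted one.
#' @param term_size_range min/max size of random terms.
#' @param planted_term_size background genes in the planted term.
#' @param selected_size size of the selected (query) gene set returned.
#' @param planted_overlap selected genes drawn from the planted term.
#' @param selected_pool optional pool (e.g. true DEGs) that the planted term
#'   and the selected set are built from; drawn at random when NULL.
#' @param seed RNG seed.
#' @return list: `annotation` (AnnotationMap), `gene_set` (selected genes),
#'   `truth` (planted term id).
#' @export
simulate_annotation <- function(background = 2000L, n_terms = 50L,
                                term_size_range = c(10L, 100L),
                                planted_term_size = 40L,
                                selected_size = 100L,
                                planted_overlap = 20L,
                                selected_pool = NULL,
                                seed = 1L) {
  set.seed(as.integer(seed))
  if (is.numeric(background) && length(background) == 1L)
    background <- sprintf("G%05d", seq_len(background))
  stopifnot(planted_overlap <= planted_term_size,
            planted_overlap <= selected_size,
            planted_term_size <= length(background))
  if (is.null(selected_pool))
    selected_pool <- sample(background, max(selected_size, planted_overlap))
  selected_pool <- intersect(selected_pool, background)

  planted_in <- sample(selected_pool, planted_overlap)
  planted_out <- sample(setdiff(background, selected_pool),
                        planted_term_size - planted_overlap)
  terms <- list(T_planted = c(planted_in, planted_out))
  sizes <- sample(term_size_range[1]:term_size_range[2], n_terms, replace = TRUE)
  for (t in seq_len(n_terms))
    terms[[sprintf("T%04d", t)]] <- sample(background, sizes[t])

  rest <- sample(setdiff(selected_pool, planted_in),
                 min(selected_size - planted_overlap,
                     length(setdiff(selected_pool, planted_in))))
  gene_set <- c(planted_in, rest)
  if (length(gene_set) < selected_size)
    gene_set <- c(gene_set,
                  sample(setdiff(background, gene_set),
                         selected_size - length(gene_set)))
  list(annotation = annotation_map(terms, background),
       gene_set = gene_set,
       truth = list(planted_term = "T_planted"))
}
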