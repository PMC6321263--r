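#' Read counting over first-exon regions
#'
#' Assigns alignments to promoters by overlap of their aligned reference
#' bases with the isoform-unique first-exon regions, then normalizes counts
#' to reads per million (RPM).  Aligned reference bases are those consumed by
#' CIGAR M/=/X operations; N (splice), D (deletion), S (soft clip) and I
#' (insertion) contribute no aligned bases.
#'
#' @name counting
NULL

#' Alignment filtering and assignment policy
#'
#' @param min_overlap minimum aligned-base overlap with a promoter's region
#'   for assignment (bases, default 10).
#' @param min_mapq minimum mapping quality (default 20).
#' @param strandedness `"unstranded"` (default), `"forward"` (read strand
#'   must match the gene strand) or `"reverse"` (must oppose it).
#' @param count_unit `"read"` (default; each record is a unit) or
#'   `"fragment"` (a read pair is one unit; a pair counts once if either mate
#'   qualifies, and pairs whose mates vote for different promoters are
#'   discarded).
#' @param include_duplicates keep records flagged as PCR/optical duplicates
#'   (default `TRUE`; the upstream protocol rarely marks them).
#' @return an `AlignmentPolicy` list.
#' @export
alignment_policy <- function(min_overlap = 10L, min_mapq = 20L,
                             strandedness = c("unstranded", "forward", "reverse"),
                             count_unit = c("read", "fragment"),
                             include_duplicates = TRUE) {
  strandedness <- match.arg(strandedness)
  count_unit <- match.arg(count_unit)
  stopifnot(min_overlap >= 1L, min_mapq >= 0L)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_mapq = as.integer(min_mapq),
                 strandedness = strandedness,
                 count_unit = count_unit,
                 include_duplicates = isTRUE(include_duplicates)),
            class = "AlignmentPolicy")
}

# Accept a SAM (text) or BAM path; return a BAM path, converting if needed.
as_bam_path <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  con <- file(path, "rb"); magic <- readBin(con, "raw", 4L); close(con)
  is_bgzf <- length(magic) >= 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  if (is_bgzf) return(path)
  # whole-file streaming: no index needed, so unsorted SAM is acceptable
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

#' Count reads supporting each promoter's first exon
#'
#' Streams primary, non-supplementary, mapped alignments passing the MAPQ
#' filter, expands each record's CIGAR to its aligned reference blocks, and
#' assigns a unit to the promoter whose unique first-exon regions it overlaps
#' by at least `policy$min_overlap` aligned bases.  A unit bridging two
#' promoters' regions is assigned to the larger overlap; exact ties are
#' discarded (and tallied).  `library_size` is the number of primary,
#' non-supplementary mapped units in the whole file passing the MAPQ filter
#' — the denominator of "reads per million reads".
#'
#' @param alignments path to a SAM or BAM file (SAM is converted on the fly).
#' @param fes a `FirstExonSet` (regions disjoint across promoters).
#' @param policy an `AlignmentPolicy`; see [alignment_policy()].
#' @param sample_id sample label for the result (default: file base name).
#' @return a `FirstExonCounts`: named integer `counts` per promoter,
#'   `library_size`, and the number of tie/conflict discards.
#' @export
count_first_exon_reads <- function(alignments, fes,
                                   policy = alignment_policy(),
                                   sample_id = NULL) {
  stopifnot(inherits(fes, "FirstExonSet"), inherits(policy, "AlignmentPolicy"))
  if (is.null(sample_id))
    sample_id <- sub("\\.(sam|bam)$", "", basename(alignments))
  bam <- as_bam_path(alignments)

  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (policy$include_duplicates) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = policy$min_mapq,
                                   what = c("qname", "flag"))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  promoters <- names(fes$regions)
  empty <- structure(list(sample_id = sample_id, gene_id = fes$gene_id,
                          counts = stats::setNames(integer(length(promoters)), promoters),
                          library_size = 0L, n_discarded = 0L),
                     class = "FirstExonCounts")
  if (length(gal) == 0L) {
    warning("no alignments pass filters in ", alignments, call. = FALSE)
    return(empty)
  }

  qname <- S4Vectors::mcols(gal)$qname
  if (policy$count_unit == "fragment") {
    library_size <- length(unique(qname))
  } else {
    library_size <- length(gal)
  }

  region_gr <- first_exon_granges(fes)
  # aligned reference blocks: M/=/X only (N splits, D dropped)
  blocks <- GenomicAlignments::grglist(gal, drop.D.ranges = TRUE)
  bl <- unlist(blocks, use.names = FALSE)
  ridx <- rep(seq_along(blocks), S4Vectors::elementNROWS(blocks))
  hits <- GenomicRanges::findOverlaps(bl, region_gr, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    empty$library_size <- library_size
    return(empty)
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov_w <- GenomicRanges::width(GenomicRanges::pintersect(bl[qh], region_gr[sh],
                                                         ignore.strand = TRUE))
  read_i <- ridx[qh]
  prom_i <- S4Vectors::mcols(region_gr)$promoter_id[sh]

  # strand compatibility
  if (policy$strandedness != "unstranded") {
    read_strand <- as.character(GenomicAlignments::strand(gal))[read_i]
    ok <- if (policy$strandedness == "forward") read_strand == fes$strand
          else read_strand != fes$strand
    ov_w <- ov_w[ok]; read_i <- read_i[ok]; prom_i <- prom_i[ok]
  }
  if (length(ov_w) == 0L) { empty$library_size <- library_size; return(empty) }

  # total overlap per (read, promoter)
  key <- paste(read_i, prom_i, sep = "\r")
  tot <- rowsum(ov_w, key)
  kk <- strsplit(rownames(tot), "\r", fixed = TRUE)
  r_of <- as.integer(vapply(kk, `[`, character(1), 1L))
  p_of <- vapply(kk, `[`, character(1), 2L)
  w_of <- as.numeric(tot[, 1])

  # per read: best promoter, ties discarded, overlap >= min_overlap
  assign_unit <- function(prom, w) {
    w_ok <- w >= policy$min_overlap
    prom <- prom[w_ok]; w <- w[w_ok]
    if (length(w) == 0L) return(NA_character_)
    mx <- max(w)
    best <- prom[w == mx]
    if (length(best) > 1L) return("TIE")
    best
  }
  sp <- split(seq_along(r_of), r_of)
  read_assign <- vapply(sp, function(ii) assign_unit(p_of[ii], w_of[ii]),
                        character(1))
  read_ids <- as.integer(names(sp))

  n_discarded <- sum(read_assign == "TIE", na.rm = TRUE)
  keep <- !is.na(read_assign) & read_assign != "TIE"
  read_assign <- read_assign[keep]; read_ids <- read_ids[keep]

  if (policy$count_unit == "fragment") {
    # one vote per fragment; conflicting mates discarded
    frag <- qname[read_ids]
    votes <- split(read_assign, frag)
    uniq_votes <- vapply(votes, function(v) {
      u <- unique(v)
      if (length(u) == 1L) u else "CONFLICT"
    }, character(1))
    n_discarded <- n_discarded + sum(uniq_votes == "CONFLICT")
    uniq_votes <- uniq_votes[uniq_votes != "CONFLICT"]
    tab <- table(factor(uniq_votes, levels = promoters))
  } else {
    tab <- table(factor(read_assign, levels = promoters))
  }

  counts <- stats::setNames(as.integer(tab), promoters)
  structure(list(sample_id = sample_id, gene_id = fes$gene_id,
                 counts = counts, library_size = as.integer(library_size),
                 n_discarded = as.integer(n_discarded)),
            class = "FirstExonCounts")
}

#' @export
print.FirstExonCounts <- function(x, ...) {
  cat("FirstExonCounts ", x$sample_id, " (gene ", x$gene_id, "): ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "; library ", x$library_size, sep = "")
  if (x$n_discarded > 0L) cat("; ", x$n_discarded, " tie/conflict discard(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' Normalize first-exon counts to reads per million
#'
#' `rpm[i] = counts[i] * 1e6 / library_size`.
#'
#' @param counts a `FirstExonCounts` with `library_size > 0`.
#' @return an `RpmVector` (named numeric `rpm` per promoter).
#' @export
rpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "FirstExonCounts"))
  if (counts$library_size <= 0L)
    stop("library_size is 0 for sample '", counts$sample_id,
         "': RPM undefined", call. = FALSE)
  structure(list(sample_id = counts$sample_id, gene_id = counts$gene_id,
                 rpm = counts$counts * 1e6 / counts$library_size),
            class = "RpmVector")
}

#' Write per-sample counts and RPM as TSV
#'
#' Columns: sample_id, gene_id, promoter_id, count, library_size, rpm.
#'
#' @param counts_list list of `FirstExonCounts`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_first_exon_counts <- function(counts_list, path) {
  if (inherits(counts_list, "FirstExonCounts")) counts_list <- list(counts_list)
  rows <- do.call(rbind, lapply(counts_list, function(fc) {
    rpm <- if (fc$library_size > 0L) fc$counts * 1e6 / fc$library_size
           else rep(NA_real_, length(fc$counts))
    data.frame(sample_id = fc$sample_id, gene_id = fc$gene_id,
               promoter_id = names(fc$counts),
               count = as.integer(fc$counts),
               library_size = fc$library_size, rpm = rpm)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV back into FirstExonCounts objects
#'
#' Inverse of [write_first_exon_counts()].
#'
#' @param path TSV path.
#' @return list of `FirstExonCounts`, one per sample.
#' @export
read_first_exon_counts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  lapply(split(d, d$sample_id)[unique(d$sample_id)], function(s) {
    structure(list(sample_id = s$sample_id[1], gene_id = s$gene_id[1],
                   counts = stats::setNames(as.integer(s$count), s$promoter_id),
                   library_size = as.integer(s$library_size[1]),
                   n_discarded = NA_integer_),
              class = "FirstExonCounts")
  })
}
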