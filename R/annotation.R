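#' Gene-model containers and first-exon (promoter proxy) derivation
#'
#' A gene transcribed from several alternative promoters produces isoforms
#' whose first exons differ while downstream exons are largely shared.  The
#' portion of each first exon not overlapped by any exon of any other isoform
#' is an isoform-discriminating interval: a read overlapping it can only come
#' from that promoter's transcript.  These unique first-exon regions are the
#' promoter proxies that the counting stage quantifies.
#'
#' Coordinates are 1-based inclusive throughout (GTF convention); BED export
#' converts to 0-based half-open at the boundary.
#'
#' @name annotation
NULL

new_transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) == 0L)
    stop("transcript '", transcript_id, "' has zero exons", call. = FALSE)
  if (any(exons$start < 1L) || any(exons$end < exons$start))
    stop("transcript '", transcript_id, "' has invalid exon coordinates", call. = FALSE)
  # transcription order: ascending on +, descending on -
  ord <- order(exons$start, decreasing = (strand == "-"))
  exons <- exons[ord, c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  gen <- exons[order(exons$start), , drop = FALSE]
  if (nrow(gen) > 1L && any(gen$start[-1L] <= gen$end[-nrow(gen)] + 1L))
    stop("transcript '", transcript_id,
         "' has overlapping or abutting exons (no intronic gap)", call. = FALSE)
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = chrom, strand = strand, exons = exons),
    class = "TranscriptModel"
  )
}

new_gene_model <- function(gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  gids <- vapply(transcripts, `[[`, character(1), "gene_id")
  if (!all(gids == gene_id))
    stop("all transcripts must share gene_id '", gene_id, "'", call. = FALSE)
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "transcript_id")
  structure(list(gene_id = gene_id, transcripts = transcripts),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel", x$gene_id, "with", length(x$transcripts), "transcript(s)\n")
  for (tx in x$transcripts) {
    cat("  ", tx$transcript_id, " [", tx$strand, "] ",
        nrow(tx$exons), " exon(s), first exon ",
        tx$exons$start[1], "-", tx$exons$end[1], "\n", sep = "")
  }
  invisible(x)
}

transcript_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

first_exon <- function(tx) tx$exons[1L, , drop = FALSE]

#' Parse gene models from a GTF file
#'
#' Reads an Ensembl-dialect GTF (9 tab-separated columns, attributes holding
#' `gene_id "..."` and `transcript_id "..."`), groups exon features by
#' transcript and transcripts by gene.  Exons are stored in transcription
#' order: ascending coordinates on the plus strand, descending on the minus
#' strand.  Non-exon features are used only to detect transcripts declared
#' without any exon, which are rejected.
#'
#' @param path path to a GTF file.
#' @return a named list of `GeneModel` objects, one per `gene_id`.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)

  tx_exons <- list()   # transcript_id -> list of rows
  tx_meta  <- list()   # transcript_id -> c(gene_id, chrom, strand)
  declared <- character(0)  # transcript ids seen on any feature line

  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f), call. = FALSE)
    attrs <- f[9]
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", attrs)
    tid <- sub('.*transcript_id "([^"]+)".*', "\\1", attrs)
    if (identical(gid, attrs))
      stop("malformed GTF line ", i, ": missing gene_id attribute", call. = FALSE)
    if (identical(tid, attrs)) {
      if (f[3] == "exon")
        stop("malformed GTF line ", i, ": missing transcript_id attribute",
             call. = FALSE)
      next  # gene-level feature line
    }
    declared <- c(declared, tid)
    if (f[3] != "exon") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1L || end < start)
      stop("malformed GTF line ", i, ": invalid coordinates '", f[4], "'-'",
           f[5], "'", call. = FALSE)
    if (!f[7] %in% c("+", "-"))
      stop("malformed GTF line ", i, ": strand must be '+' or '-', got '",
           f[7], "'", call. = FALSE)
    tx_exons[[tid]] <- c(tx_exons[[tid]], list(c(start, end)))
    tx_meta[[tid]] <- c(gene_id = gid, chrom = f[1], strand = f[7])
  }

  empty <- setdiff(unique(declared), names(tx_exons))
  if (length(empty) > 0L)
    stop("transcript(s) with zero exons rejected: ",
         paste(empty, collapse = ", "), call. = FALSE)

  transcripts <- lapply(names(tx_exons), function(tid) {
    m <- tx_meta[[tid]]
    ex <- do.call(rbind, tx_exons[[tid]])
    new_transcript_model(tid, m[["gene_id"]], m[["chrom"]], m[["strand"]],
                         data.frame(start = ex[, 1], end = ex[, 2]))
  })
  gids <- vapply(transcripts, `[[`, character(1), "gene_id")
  genes <- lapply(split(transcripts, gids), function(txs) {
    new_gene_model(txs[[1]]$gene_id, txs)
  })
  genes[unique(gids)]
}

#' Derive isoform-discriminating first-exon regions
#'
#' For each distinct first exon of the gene's isoforms, subtracts every base
#' overlapped by any exon of any other isoform, leaving the unique portion
#' that unambiguously identifies the promoter.  Transcripts sharing a
#' byte-identical first exon collapse to a single promoter.  Promoters whose
#' unique residue cannot anchor a read (all fragments shorter than
#' `min_unique_length`) are flagged unusable and excluded with a warning;
#' fewer than two usable promoters is an error because usage proportions are
#' then undefined.
#'
#' Promoter ids are `P1`, `P2`, ... ordered 5' to 3' along the direction of
#' transcription.
#'
#' @param gene a `GeneModel` with at least two transcripts.
#' @param min_unique_length minimum retained fragment length in bases
#'   (default 25): shorter unique residues cannot anchor a read reliably.
#' @return a `FirstExonSet`: promoter regions (disjoint across promoters),
#'   the transcripts backing each promoter, and any excluded promoters.
#' @export
derive_first_exons <- function(gene, min_unique_length = 25L) {
  stopifnot(inherits(gene, "GeneModel"))
  txs <- gene$transcripts
  if (length(txs) < 2L)
    stop("gene '", gene$gene_id,
         "' needs >= 2 transcripts for promoter-usage analysis", call. = FALSE)
  chrom <- txs[[1]]$chrom
  strand <- txs[[1]]$strand

  fe <- t(vapply(txs, function(tx) unlist(first_exon(tx)), numeric(2)))
  key <- paste(fe[, 1], fe[, 2], sep = "-")
  groups <- split(names(txs), key)

  # order promoters 5'->3' in transcription direction
  tss <- vapply(unique(key), function(k) {
    r <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    if (strand == "+") r[1] else -r[2]
  }, numeric(1))
  ordered_keys <- unique(key)[order(tss)]

  all_regions <- list(); all_tx <- list(); excluded <- character(0)
  pn <- 0L
  for (k in ordered_keys) {
    members <- groups[[k]]
    r <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    fe_rng <- IRanges::IRanges(start = r[1], end = r[2])
    other_tx <- txs[setdiff(names(txs), members)]
    other_ex <- do.call(rbind, lapply(other_tx, `[[`, "exons"))
    other_rng <- IRanges::reduce(IRanges::IRanges(start = other_ex$start,
                                                  end = other_ex$end))
    uniq <- IRanges::setdiff(fe_rng, other_rng)
    uniq <- uniq[IRanges::width(uniq) >= min_unique_length]
    label <- paste0("first exon ", r[1], "-", r[2])
    if (length(uniq) == 0L) {
      excluded <- c(excluded, label)
      warning("gene '", gene$gene_id, "': promoter at ", label,
              " has no unique residue >= ", min_unique_length,
              " bases; excluded as unobservable", call. = FALSE)
      next
    }
    pn <- pn + 1L
    pid <- paste0("P", pn)
    all_regions[[pid]] <- data.frame(start = IRanges::start(uniq),
                                     end = IRanges::end(uniq))
    all_tx[[pid]] <- members
  }
  if (length(all_regions) < 2L)
    stop("gene '", gene$gene_id, "': fewer than 2 usable promoters (",
         length(all_regions), " usable, ", length(excluded), " excluded)",
         call. = FALSE)

  structure(
    list(gene_id = gene$gene_id, chrom = chrom, strand = strand,
         regions = all_regions, promoter_transcripts = all_tx,
         min_unique_length = as.integer(min_unique_length),
         excluded = excluded),
    class = "FirstExonSet"
  )
}

#' @export
print.FirstExonSet <- function(x, ...) {
  cat("FirstExonSet for gene", x$gene_id, "on", x$chrom, x$strand, "\n")
  for (pid in names(x$regions)) {
    r <- x$regions[[pid]]
    cat("  ", pid, ": ", paste0(r$start, "-", r$end, collapse = ", "),
        " (", sum(r$end - r$start + 1L), " bp; transcripts: ",
        paste(x$promoter_transcripts[[pid]], collapse = ","), ")\n", sep = "")
  }
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = "; "), "\n")
  invisible(x)
}

#' Regions of a FirstExonSet as a GRanges
#'
#' One range per unique-region fragment; `promoter_id` metadata column.
#' @param fes a `FirstExonSet`.
#' @return a `GRanges`.
#' @export
first_exon_granges <- function(fes) {
  stopifnot(inherits(fes, "FirstExonSet"))
  pid <- rep(names(fes$regions),
             vapply(fes$regions, nrow, integer(1)))
  r <- do.call(rbind, fes$regions)
  gr <- GenomicRanges::GRanges(
    seqnames = fes$chrom,
    ranges = IRanges::IRanges(start = r$start, end = r$end),
    strand = fes$strand
  )
  S4Vectors::mcols(gr)$promoter_id <- pid
  gr
}

#' Export a FirstExonSet as BED6
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open
#' convention.  Name is `gene_id|promoter_id`, score 0.
#'
#' @param fes a `FirstExonSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_first_exons_bed <- function(fes, path) {
  stopifnot(inherits(fes, "FirstExonSet"))
  rows <- character(0)
  for (pid in names(fes$regions)) {
    r <- fes$regions[[pid]]
    rows <- c(rows, paste(fes$chrom, r$start - 1L, r$end,
                          paste0(fes$gene_id, "|", pid), 0L, fes$strand,
                          sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
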