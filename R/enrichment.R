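#' Hypergeometric term enrichment with BH correction and richness factors
#'
#' Over-representation testing of a gene set against a term-to-gene
#' annotation: for a term annotating K of N background genes, with a
#' selected set of n genes of which k fall in the term, the p-value is the
#' hypergeometric upper tail P(X >= k).  Benjamini-Hochberg correction is
#' applied across tested terms; the richness factor k/K is the fraction of a
#' term's genes that are selected.
#'
#' @name enrichment
NULL

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n genes without
#' replacement from a background of N of which K carry the term.
#'
#' @param k observed overlap (selected genes in the term).
#' @param K background genes in the term.
#' @param n selected-set size.
#' @param N background size.
#' @return the upper-tail p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: on sorted p-values, `q_(i) = min_{j>=i}(p_(j) *
#' m / j)` clipped at 1, returned in input order.
#'
#' @param p_values numeric vector with all values in (0, 1].
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment of a gene set
#'
#' Tests every term with at least `min_term_size` background genes; genes of
#' the query set absent from the background are dropped with a warning
#' (their number is recorded in the result attributes).
#'
#' @param gene_set character vector of selected gene ids.
#' @param annotation an `AnnotationMap` from [read_annotation_map()] or
#'   [annotation_map()].
#' @param min_term_size smallest testable term (default 5).
#' @return data.frame sorted by ascending p: term_id, k, K, n, N, p_value,
#'   q_value (BH over tested terms), richness_factor = k/K.
#' @export
enrich <- function(gene_set, annotation, min_term_size = 5L) {
  stopifnot(inherits(annotation, "AnnotationMap"))
  gene_set <- unique(gene_set)
  dropped <- setdiff(gene_set, annotation$background)
  if (length(dropped) > 0L) {
    warning(length(dropped),
            " query gene(s) not in background dropped", call. = FALSE)
    gene_set <- intersect(gene_set, annotation$background)
  }
  if (length(gene_set) == 0L)
    stop("gene set empty after intersection with background", call. = FALSE)

  terms <- annotation$terms
  K <- vapply(terms, length, integer(1))
  terms <- terms[K >= min_term_size]
  K <- K[K >= min_term_size]
  N <- length(annotation$background)
  n <- length(gene_set)
  k <- vapply(terms, function(g) length(intersect(g, gene_set)), integer(1))
  p <- hypergeom_upper_tail(k, K, n, N)
  out <- data.frame(term_id = names(terms), k = k, K = K, n = n, N = N,
                    p_value = p, q_value = bh_adjust(p),
                    richness_factor = k / K)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  out
}

#' Construct an annotation map
#'
#' @param terms named list: term_id -> character vector of gene ids.
#' @param background character vector of population gene ids; defaults to
#'   the union of all annotated genes.  Every annotated gene must be in the
#'   background.
#' @return an `AnnotationMap`.
#' @export
annotation_map <- function(terms, background = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  terms <- lapply(terms, unique)
  annotated <- unique(unlist(terms, use.names = FALSE))
  if (is.null(background)) background <- annotated
  background <- unique(background)
  stray <- setdiff(annotated, background)
  if (length(stray) > 0L)
    stop(length(stray), " annotated gene(s) missing from background",
         call. = FALSE)
  structure(list(terms = terms, background = background),
            class = "AnnotationMap")
}

#' Read a long-format annotation TSV (term_id, gene_id)
#'
#' @param path TSV with columns term_id and gene_id.
#' @param background_path optional TSV/one-per-line file of background gene
#'   ids; defaults to the distinct annotated genes.
#' @return an `AnnotationMap`.
#' @export
read_annotation_map <- function(path, background_path = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(d)))
    stop("annotation TSV must have columns term_id and gene_id", call. = FALSE)
  terms <- split(d$gene_id, d$term_id)
  background <- NULL
  if (!is.null(background_path)) {
    background <- scan(background_path, what = character(), quiet = TRUE)
  }
  annotation_map(terms, background)
}

#' Write an annotation map as long-format TSV
#' @param annotation an `AnnotationMap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_map <- function(annotation, path) {
  stopifnot(inherits(annotation, "AnnotationMap"))
  d <- data.frame(
    term_id = rep(names(annotation$terms),
                  vapply(annotation$terms, length, integer(1))),
    gene_id = unlist(annotation$terms, use.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
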