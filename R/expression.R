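#' Gene-level expression: normalization, filtering, DEG calls, set algebra
#'
#' Implements the expression stage surrounding promoter-usage analysis:
#' median-of-ratios size factors, FPKM and TPM, the expressed-gene filter
#' (normalized count above a threshold in at least one sample), a
#' fold-change + Welch-test differential-expression criterion, and overlap
#' summaries between DEG lists.
#'
#' The differential test here is deliberately simple — a two-sided Welch
#' t-test on log2(size-factor-normalized count + pseudocount) — and is
#' labeled as such; it is not a negative-binomial GLM.
#'
#' @name expression
NULL

check_count_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs gene row names and sample column names",
         call. = FALSE)
  if (any(m < 0)) stop("count matrix has negative entries", call. = FALSE)
  invisible(m)
}

#' Median-of-ratios size factors
#'
#' For sample j, `s_j = median_g( count[g,j] / geomean_samples(count[g,.]) )`,
#' the median taken over genes whose geometric mean across samples is
#' positive (i.e. genes with a nonzero count in every sample).
#'
#' @param m gene x sample count matrix (row/col names required).
#' @return named positive numeric vector of size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(m) {
  check_count_matrix(m)
  log_gm <- rowMeans(log(m))            # -Inf for genes with any zero
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no gene has a nonzero count in every sample; size factors undefined",
         call. = FALSE)
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - log_gm[use]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factor(s) computed", call. = FALSE)
  sf
}

#' FPKM / TPM normalization
#'
#' `FPKM[g,j] = count[g,j] * 1e9 / (length_g * total_j)` with `total_j` the
#' column sum of raw counts; `TPM[g,j]` rescales the per-kilobase rates
#' `count/length` to sum to one million per sample, equivalently FPKM
#' renormalized per column.
#'
#' @param m gene x sample count matrix.
#' @param lengths named vector of gene lengths in bases (>= 1), covering all
#'   rows of `m`.
#' @param method `"FPKM"` or `"TPM"`.
#' @return matrix of the same shape; attribute `method` records the unit.
#' @export
normalize_expression <- function(m, lengths, method = c("FPKM", "TPM")) {
  method <- match.arg(method)
  check_count_matrix(m)
  if (!all(rownames(m) %in% names(lengths)))
    stop("gene length missing for: ",
         paste(utils::head(setdiff(rownames(m), names(lengths))), collapse = ", "),
         call. = FALSE)
  len <- lengths[rownames(m)]
  if (any(len < 1)) stop("all gene lengths must be >= 1", call. = FALSE)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("zero column total for sample(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "), call. = FALSE)
  if (method == "FPKM") {
    out <- sweep(m / len, 2, totals, "/") * 1e9
  } else {
    rate <- m / len
    out <- sweep(rate, 2, colSums(rate), "/") * 1e6
  }
  attr(out, "method") <- method
  out
}

#' Expressed-gene filter
#'
#' A gene is called expressed when its size-factor-normalized count exceeds
#' `threshold` in at least one sample.
#'
#' @param m gene x sample count matrix.
#' @param size_factors named vector covering the columns of `m`.
#' @param threshold normalized-count cutoff (default 3).
#' @return character vector of expressed gene ids (row order of `m`).
#' @export
expressed_filter <- function(m, size_factors, threshold = 3) {
  check_count_matrix(m)
  if (!all(colnames(m) %in% names(size_factors)))
    stop("size factor missing for some samples", call. = FALSE)
  norm <- sweep(m, 2, size_factors[colnames(m)], "/")
  rownames(m)[apply(norm > threshold, 1, any)]
}

#' Call differentially expressed genes
#'
#' Fold change is computed from group means of size-factor-normalized counts
#' with a pseudocount: `log2FC = log2((mean_b + pseudocount) /
#' (mean_a + pseudocount))`.  The p-value is a two-sided Welch t-test on
#' `log2(normalized + pseudocount)` per sample.  A gene is a DEG when
#' `|log2FC| > lfc_threshold` and `p < p_threshold` (defaults: fold-change
#' above 2, p below 0.05).
#'
#' @param m gene x sample count matrix.
#' @param size_factors named vector covering the columns of `m`.
#' @param group_a,group_b character vectors of sample ids (>= 2 each).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param pseudocount added before log2 (default 1).
#' @return data.frame: gene_id, mean_a, mean_b, log2_fold_change, p_value,
#'   is_deg.
#' @export
call_degs <- function(m, size_factors, group_a, group_b,
                      lfc_threshold = 1, p_threshold = 0.05, pseudocount = 1) {
  check_count_matrix(m)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 samples (got ", length(group_a), " and ",
         length(group_b), ")", call. = FALSE)
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing))
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  norm <- sweep(m, 2, size_factors[colnames(m)], "/")
  na <- norm[, group_a, drop = FALSE]
  nb <- norm[, group_b, drop = FALSE]
  mean_a <- rowMeans(na); mean_b <- rowMeans(nb)
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  la <- log2(na + pseudocount); lb <- log2(nb + pseudocount)
  p <- vapply(seq_len(nrow(m)),
              function(i) welch_test(la[i, ], lb[i, ])$p, numeric(1))
  out <- data.frame(gene_id = rownames(m), mean_a = mean_a, mean_b = mean_b,
                    log2_fold_change = lfc, p_value = p,
                    is_deg = abs(lfc) > lfc_threshold & p < p_threshold)
  rownames(out) <- NULL
  out
}

#' Overlap summary of named DEG sets
#'
#' Pairwise and global intersections and unions, with the shared fraction
#' reported both against the union and against the total of the two lists
#' (both denominators are in circulation for "percent shared").
#'
#' @param deg_lists named list (>= 2) of character vectors of gene ids.
#' @return list with `pairwise` (data.frame: set_a, set_b, size_a, size_b,
#'   shared, union, pct_shared_of_union, pct_shared_of_total) and `global`
#'   (intersection and union sizes over all sets).
#' @export
deg_set_algebra <- function(deg_lists) {
  stopifnot(is.list(deg_lists), length(deg_lists) >= 2L,
            !is.null(names(deg_lists)))
  sets <- lapply(deg_lists, unique)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- sets[[pairs[1, i]]]; b <- sets[[pairs[2, i]]]
    sh <- length(intersect(a, b)); un <- length(union(a, b))
    data.frame(set_a = pairs[1, i], set_b = pairs[2, i],
               size_a = length(a), size_b = length(b),
               shared = sh, union = un,
               pct_shared_of_union = if (un > 0) 100 * sh / un else NA_real_,
               pct_shared_of_total =
                 if (length(a) + length(b) > 0)
                   100 * sh / (length(a) + length(b)) else NA_real_)
  }))
  rownames(pairwise) <- NULL
  list(pairwise = pairwise,
       global = list(intersection = length(Reduce(intersect, sets)),
                     union = length(Reduce(union, sets))))
}

#' Read a count matrix TSV (first column gene_id, header sample ids)
#' @param path TSV path.
#' @return integer matrix with gene row names and sample column names.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  check_count_matrix(m)
}

#' Write a matrix as TSV with a gene_id first column
#' @param m matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length TSV (gene_id, length)
#' @param path TSV path.
#' @return named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d[[2]]), d[[1]])
}
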