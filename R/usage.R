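#' Promoter usage proportions and group comparison
#'
#' The usage proportion of a promoter in a sample is the number of reads
#' mapped to its first exon divided by the total mapped to all the gene's
#' first exons.  Proportions are computed per sample and compared between
#' groups with a two-sided Welch (unequal-variance) t-test, one promoter at
#' a time.
#'
#' @name usage_stats
NULL

#' Per-sample promoter usage proportions
#'
#' @param counts_list list of `FirstExonCounts`, all covering the same
#'   promoter set.
#' @param sample_groups optional named character vector mapping sample_id to
#'   group_id; unnamed samples get group `NA`.
#' @return a `PromoterUsageTable` data.frame with columns sample_id,
#'   group_id, promoter_id, count, rpm, proportion.  Samples with zero total
#'   first-exon count get `NA` proportions and a warning; they are excluded
#'   from comparisons.
#' @export
usage_proportions <- function(counts_list, sample_groups = NULL) {
  if (inherits(counts_list, "FirstExonCounts")) counts_list <- list(counts_list)
  proms <- names(counts_list[[1]]$counts)
  for (fc in counts_list) {
    if (!identical(sort(names(fc$counts)), sort(proms)))
      stop("sample '", fc$sample_id, "' covers a different promoter set",
           call. = FALSE)
  }
  rows <- lapply(counts_list, function(fc) {
    cc <- fc$counts[proms]
    total <- sum(cc)
    prop <- if (total > 0) cc / total else {
      warning("sample '", fc$sample_id,
              "' has zero first-exon reads; proportions undefined",
              call. = FALSE)
      rep(NA_real_, length(cc))
    }
    rpm <- if (fc$library_size > 0) cc * 1e6 / fc$library_size
           else rep(NA_real_, length(cc))
    gid <- if (!is.null(sample_groups) && fc$sample_id %in% names(sample_groups))
      unname(sample_groups[fc$sample_id]) else NA_character_
    data.frame(sample_id = fc$sample_id, group_id = gid,
               promoter_id = proms, count = as.integer(cc),
               rpm = rpm, proportion = as.numeric(prop))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("PromoterUsageTable", "data.frame")
  out
}

# Welch test returning the degenerate-case contract: both groups constant
# and equal means -> p = 1; constant but different means -> p collapses to
# the smallest representable positive value (infinite evidence).
welch_test <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = .Machine$double.xmin,
                df = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Compare promoter usage between two groups
#'
#' Two-sided Welch t-test on the per-sample usage proportions of one
#' promoter.  An arcsine-square-root variance-stabilizing transform is
#' optional; the default tests raw proportions.
#'
#' @param table a `PromoterUsageTable` with group_id filled in.
#' @param group_a,group_b group ids to compare.
#' @param promoter promoter id.
#' @param transform `"none"` (default) or `"arcsine"` (asin(sqrt(p))).
#' @return a `UsageComparison` list: promoter_id, group ids, mean
#'   proportions (untransformed), t_stat, p_value, n_a, n_b.
#' @export
compare_usage <- function(table, group_a, group_b, promoter,
                          transform = c("none", "arcsine")) {
  transform <- match.arg(transform)
  stopifnot(inherits(table, "PromoterUsageTable"))
  sel <- table$promoter_id == promoter & !is.na(table$proportion)
  a <- table$proportion[sel & table$group_id == group_a]
  b <- table$proportion[sel & table$group_id == group_b]
  if (length(a) < 2L)
    stop("group '", group_a, "' has ", length(a),
         " usable sample(s); >= 2 required", call. = FALSE)
  if (length(b) < 2L)
    stop("group '", group_b, "' has ", length(b),
         " usable sample(s); >= 2 required", call. = FALSE)
  ta <- a; tb <- b
  if (transform == "arcsine") { ta <- asin(sqrt(a)); tb <- asin(sqrt(b)) }
  w <- welch_test(ta, tb)
  structure(list(promoter_id = promoter, group_a = group_a, group_b = group_b,
                 mean_a = mean(a), mean_b = mean(b),
                 t_stat = w$t, p_value = w$p, df = w$df,
                 n_a = length(a), n_b = length(b), transform = transform),
            class = "UsageComparison")
}

#' @export
print.UsageComparison <- function(x, ...) {
  cat(sprintf(
    "UsageComparison %s: %s (mean %.4f, n=%d) vs %s (mean %.4f, n=%d)\n  Welch t = %.4g, p = %.4g%s\n",
    x$promoter_id, x$group_a, x$mean_a, x$n_a, x$group_b, x$mean_b, x$n_b,
    x$t_stat, x$p_value,
    if (x$transform != "none") paste0(" (", x$transform, " transform)") else ""))
  invisible(x)
}

#' Compare every promoter between two groups
#'
#' @inheritParams compare_usage
#' @return data.frame with one row per promoter: promoter_id, group_a,
#'   group_b, mean_a, mean_b, t_stat, p_value, n_a, n_b.  Raw p-values are
#'   reported (no multiplicity correction across the handful of promoters).
#' @export
compare_usage_all <- function(table, group_a, group_b,
                              transform = c("none", "arcsine")) {
  transform <- match.arg(transform)
  proms <- unique(table$promoter_id)
  rows <- lapply(proms, function(p) {
    cmp <- compare_usage(table, group_a, group_b, p, transform)
    data.frame(promoter_id = p, group_a = group_a, group_b = group_b,
               mean_a = cmp$mean_a, mean_b = cmp$mean_b,
               t_stat = cmp$t_stat, p_value = cmp$p_value,
               n_a = cmp$n_a, n_b = cmp$n_b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a usage table or comparison table as TSV
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_usage_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample table TSV (sample_id, group_id)
#' @param path TSV with columns sample_id and group_id.
#' @return named character vector sample_id -> group_id.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group_id") %in% names(d)))
    stop("sample table must have columns sample_id and group_id", call. = FALSE)
  stats::setNames(d$group_id, d$sample_id)
}
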