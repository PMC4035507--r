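# Frequency tables, between-dataset fold enrichment, proportion tests
# and the Pfam -> COG functional-category roll-up.

#' Percentage of a count, half-up rounded
#'
#' @param count Non-negative count (vectorised).
#' @param total Positive total.
#' @param decimals Reporting precision (default 1).
#' @return `100 * count / total`, rounded half-up.
#' @examples
#' frequency(5126, 21823, 1)  # 23.5
#' frequency(44, 7978, 2)     # 0.55
#' @export
frequency <- function(count, total, decimals = 1) {
  if (any(total <= 0)) stop("`total` must be > 0: percentage undefined")
  if (any(count < 0 | count > total)) {
    stop("`count` must lie in [0, total]")
  }
  round_half_up(100 * count / total, decimals)
}

#' Fold enrichment of a feature between two datasets
#'
#' The ratio of the feature's relative frequency in dataset A to that
#' in dataset B.  A zero count in B gives `Inf` with an `infinite`
#' attribute flag rather than an error.
#'
#' @param count_a,total_a Feature count and dataset size in A.
#' @param count_b,total_b Feature count and dataset size in B.
#' @return The fold ratio (attribute `infinite` = TRUE when
#'   `count_b` is 0).
#' @examples
#' fold_enrichment(499, 7978, 108, 21607)  # ~12.5
#' @export
fold_enrichment <- function(count_a, total_a, count_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("totals must be > 0")
  if (count_b == 0) {
    return(structure(Inf, infinite = TRUE))
  }
  (count_a / total_a) / (count_b / total_b)
}

#' Two-proportion comparison with exact fallback
#'
#' Two-sided two-proportion z-test with pooled variance; when any
#' expected cell under the pooled proportion is below 5 the exact
#' conditional (Fisher) test is used instead.  Identical observed
#' proportions give p = 1 by convention.
#'
#' @param count_a,total_a Successes and size of dataset A.
#' @param count_b,total_b Successes and size of dataset B.
#' @param alpha Significance level (default 0.001).
#' @return List `(p_value, significant, method)`.
#' @export
compare_proportions <- function(count_a, total_a, count_b, total_b,
                                alpha = 0.001) {
  stopifnot(total_a > 0, total_b > 0,
            count_a >= 0, count_a <= total_a,
            count_b >= 0, count_b <= total_b)
  p1 <- count_a / total_a
  p2 <- count_b / total_b
  pool <- (count_a + count_b) / (total_a + total_b)
  expected <- c(pool * total_a, (1 - pool) * total_a,
                pool * total_b, (1 - pool) * total_b)
  if (p1 == p2) {
    p <- 1
    method <- "identical"
  } else if (any(expected < 5)) {
    tab <- matrix(c(count_a, total_a - count_a,
                    count_b, total_b - count_b), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher_exact"
  } else {
    se <- sqrt(pool * (1 - pool) * (1 / total_a + 1 / total_b))
    z <- (p1 - p2) / se
    p <- 2 * stats::pnorm(-abs(z))
    method <- "two_proportion_z"
  }
  list(p_value = p, significant = p <= alpha, method = method)
}

#' Roll Pfam counts up to COG-style functional categories
#'
#' Sums Pfam domain counts per single-letter functional category using
#' a Pfam -> category map; Pfams absent from the map fall into
#' category S (function unknown).  Relative abundances are percentages
#' of the total count.
#'
#' @param pfam_counts data.frame `(pfam, count)` or a named count
#'   vector.
#' @param pfam_to_cog_map data.frame `(pfam, category)`; categories
#'   are the single letters A-Z of the COG functional scheme.
#' @param decimals Reporting precision (default 1).
#' @return data.frame `(category, count, pct)`, categories sorted;
#'   empty input gives an empty table.
#' @export
cog_rollup <- function(pfam_counts, pfam_to_cog_map, decimals = 1) {
  if (!is.data.frame(pfam_counts)) {
    pfam_counts <- data.frame(pfam = names(pfam_counts),
                              count = as.numeric(pfam_counts))
  }
  stopifnot(all(c("pfam", "count") %in% names(pfam_counts)))
  if (nrow(pfam_counts) == 0) {
    return(data.frame(category = character(), count = numeric(),
                      pct = numeric()))
  }
  stopifnot(all(c("pfam", "category") %in% names(pfam_to_cog_map)))
  cat_of <- pfam_to_cog_map$category[
    match(pfam_counts$pfam, pfam_to_cog_map$pfam)]
  cat_of[is.na(cat_of)] <- "S"
  agg <- stats::aggregate(list(count = pfam_counts$count),
                          by = list(category = cat_of), FUN = sum)
  agg <- agg[order(agg$category), , drop = FALSE]
  agg$pct <- frequency(agg$count, sum(agg$count), decimals)
  rownames(agg) <- NULL
  agg
}

#' Build a two-dataset frequency comparison table
#'
#' For each label, the counts and percentages in both datasets, the
#' A-over-B fold enrichment and the proportion-test p-value with its
#' significance flag at `alpha`.
#'
#' @param counts_a,counts_b Named count vectors (or data.frames
#'   `(label, count)`) for the two datasets; labels are unioned,
#'   missing counts are 0.
#' @param alpha Significance level (default 0.001).
#' @param decimals Percentage precision (default 1).
#' @return data.frame `(label, count_a, count_b, pct_a, pct_b, fold,
#'   p_value, significant)`.
#' @export
compare_frequency_tables <- function(counts_a, counts_b, alpha = 0.001,
                                     decimals = 1) {
  to_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$count, x$label) else x
  }
  a <- to_vec(counts_a)
  b <- to_vec(counts_b)
  labels <- sort(union(names(a), names(b)))
  ca <- ifelse(labels %in% names(a), a[labels], 0)
  cb <- ifelse(labels %in% names(b), b[labels], 0)
  ta <- sum(ca)
  tb <- sum(cb)
  if (ta == 0 || tb == 0) stop("each dataset needs a positive total")
  out <- data.frame(label = labels, count_a = as.numeric(ca),
                    count_b = as.numeric(cb),
                    pct_a = frequency(ca, ta, decimals),
                    pct_b = frequency(cb, tb, decimals))
  out$fold <- mapply(function(x, y) {
    if (y == 0) Inf else (x / ta) / (y / tb)
  }, ca, cb)
  tests <- mapply(function(x, y) {
    compare_proportions(x, ta, y, tb, alpha)
  }, ca, cb, SIMPLIFY = FALSE)
  out$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  out$significant <- vapply(tests, `[[`, logical(1), "significant")
  rownames(out) <- NULL
  out
}
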