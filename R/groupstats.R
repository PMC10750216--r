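# Rank-based comparison of per-ROI statistics across disease groups
# (e.g. RLN vs DLBCL vs AITL), implemented from first principles with the
# tie-corrected Kruskal-Wallis H statistic and its chi-square approximation.

#' Grouped per-ROI samples
#'
#' @param values numeric vector of per-ROI statistics (density, pair count,
#'   ratio).
#' @param groups group labels (disease types), same length as `values`.
#' @return an object of class `grouped_samples`.
#' @export
grouped_samples <- function(values, groups) {
  stopifnot(length(values) == length(groups), is.numeric(values))
  groups <- as.character(groups)
  if (anyNA(values) || anyNA(groups)) stop("NA in values or groups")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("every group must be nonempty")
  structure(list(values = values, groups = groups),
            class = "grouped_samples")
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-ranks are assigned to the pooled values;
#' `H = (12 / (N (N + 1))) * sum(R_j^2 / n_j) - 3 (N + 1)` is divided by the
#' tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)` and referred to the
#' chi-square distribution with `k - 1` degrees of freedom. All values
#' identical is degenerate: H = 0, p = 1, flagged.
#'
#' @param samples a [grouped_samples()] object.
#' @param alpha significance level for the flag (default 0.05).
#' @return an object of class `kw_test`: `statistic` (H), `df`, `p_value`,
#'   `significant`, `degenerate`, and `small_groups` (TRUE when any group
#'   has fewer than 5 values, where the chi-square approximation is rough).
#' @export
kruskal_wallis <- function(samples, alpha = 0.05) {
  stopifnot(inherits(samples, "grouped_samples"))
  x <- samples$values
  g <- samples$groups
  k <- length(unique(g))
  N <- length(x)
  if (N < k + 1L) stop("need at least one more observation than groups")
  degenerate <- length(unique(x)) == 1L
  if (degenerate) {
    H <- 0; p <- 1
  } else {
    r <- rank(x)  # mid-ranks for ties
    Rj <- tapply(r, g, sum)
    nj <- tapply(r, g, length)
    H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
    ties <- table(x)
    tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    H <- H / tie_corr
    p <- stats::pchisq(H, df = k - 1L, lower.tail = FALSE)
  }
  structure(
    list(statistic = H, df = k - 1L, p_value = p,
         significant = p < alpha, alpha = alpha,
         degenerate = degenerate,
         small_groups = any(table(g) < 5L)),
    class = "kw_test"
  )
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g%s%s\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) " (significant)" else "",
              if (x$small_groups) " [group n < 5: approximation is rough]"
              else ""))
  invisible(x)
}

#' Boxplot summary of grouped samples
#'
#' Quartiles use the median-of-halves convention: Q1 and Q3 are the medians
#' of the lower and upper halves of the sorted data, the median excluded
#' from both halves when n is odd. Whiskers extend to the most extreme
#' values within 1.5 * IQR of the quartiles; values beyond are outliers.
#'
#' @param samples a [grouped_samples()] object.
#' @return a data.frame with one row per group: `group`, `n`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
summarize_boxplot <- function(samples) {
  stopifnot(inherits(samples, "grouped_samples"))
  halves_quartiles <- function(v) {
    v <- sort(v)
    n <- length(v)
    med <- stats::median(v)
    if (n == 1L) return(c(q1 = v, med = med, q3 = v))
    lower <- v[seq_len(floor(n / 2))]
    upper <- v[(n + 1L - floor(n / 2)):n]
    c(q1 = stats::median(lower), med = med, q3 = stats::median(upper))
  }
  groups <- unique(samples$groups)
  rows <- lapply(groups, function(gr) {
    v <- samples$values[samples$groups == gr]
    q <- halves_quartiles(v)
    iqr <- q[["q3"]] - q[["q1"]]
    lo_fence <- q[["q1"]] - 1.5 * iqr
    hi_fence <- q[["q3"]] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    data.frame(group = gr, n = length(v), median = q[["med"]],
               q1 = q[["q1"]], q3 = q[["q3"]],
               whisker_lo = min(inside), whisker_hi = max(inside),
               n_outliers = sum(v < lo_fence | v > hi_fence))
  })
  do.call(rbind, rows)
}
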