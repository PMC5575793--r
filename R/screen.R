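#' Normalize screen metrics to the same-day control
#'
#' Divides each animal's metric by the mean (or median) of the control
#' group's metric from the same experimental day, removing day-to-day
#' drifts in preparation, age and imaging; control records normalize to
#' mean (median) 1 by construction.
#'
#' @param records `data.frame` with columns `compound`, `day`, and the
#'   metric; controls have `compound == "control"`.
#' @param metric Metric column name (e.g. `"max_dRR"`).
#' @param stat `"mean"` (default) or `"median"` control anchor.
#' @param min_control Minimum number of defined same-day control values
#'   (default 3).
#' @return Numeric vector of normalized values aligned with `records`
#'   (`NA` where the metric is undefined).
#' @export
normalize_to_control <- function(records, metric, stat = c("mean", "median"),
                                 min_control = 3) {
  stat <- match.arg(stat)
  stopifnot(all(c("compound", "day", metric) %in% names(records)))
  anchor <- if (stat == "mean") mean else stats::median
  out <- rep(NA_real_, nrow(records))
  for (d in unique(records$day)) {
    in_day <- records$day == d
    ctrl <- records[[metric]][in_day & records$compound == "control"]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) < min_control) {
      stop(sprintf("day '%s' has %d defined control values for %s (need %d)",
                   d, length(ctrl), metric, min_control))
    }
    out[in_day] <- records[[metric]][in_day] / anchor(ctrl)
  }
  out
}

new_test_result <- function(statistic, p_value, n_per_group, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_per_group = n_per_group, method = method,
                 stars = p_stars(p_value)),
            class = "touch_test")
}

#' @export
print.touch_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g %s (n = %s)\n",
              x$method, x$statistic, x$p_value, x$stars,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

# counts of ways to choose `n` of the ranks 1..N with each possible rank
# sum; index i of the result holds the count for rank sum i - 1
rank_sum_counts <- function(n, N) {
  max_sum <- sum((N - n + 1):N)
  # dp[k + 1, s + 1] = number of k-subsets of the ranks seen so far
  # summing to s
  dp <- matrix(0, n + 1, max_sum + 1)
  dp[1, 1] <- 1
  for (r in seq_len(N)) {
    kmax <- min(r, n)
    for (k in kmax:1) {
      from <- dp[k, seq_len(max_sum + 1 - r)]
      dp[k + 1, (r + 1):(max_sum + 1)] <-
        dp[k + 1, (r + 1):(max_sum + 1)] + from
    }
  }
  dp[n + 1, ]
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank tie handling. The
#' two-sided p-value is exact (from the full null distribution of U)
#' when the pooled sample has at most `exact_max` observations and no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest pooled size for the exact p-value
#'   (default 16).
#' @return A `touch_test` with the U statistic of `x`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact_max = 16) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && N <= exact_max) {
    counts <- rank_sum_counts(n, N)
    # shift from rank sums to U values: U = W - n(n+1)/2
    u_counts <- counts[(n * (n + 1) / 2 + 1):length(counts)]
    total <- sum(u_counts)
    lo <- sum(u_counts[seq_len(U + 1)]) / total        # P(U <= u)
    hi <- sum(u_counts[(U + 1):length(u_counts)]) / total  # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "mann_whitney_exact"
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    mu <- n * m / 2
    sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "mann_whitney_normal"
  }
  new_test_result(U, p, c(n, m), method)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of two or more groups:
#' \deqn{H = \frac{12}{N(N+1)} \sum_i R_i^2 / n_i - 3(N+1)}
#' divided by the tie correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)};
#' p-value from the chi-squared distribution with k-1 degrees of
#' freedom. When every observation is identical the test is flagged
#' degenerate (`NA` statistic and p).
#'
#' @param groups List of numeric samples (>= 2, each nonempty).
#' @return A `touch_test`; `method` is `"kruskal_wallis"` or
#'   `"kruskal_wallis_degenerate"`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("empty group")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  R <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / lengths(groups)) - 3 * (N + 1)
  tie_tab <- table(pooled)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (C <= 0) {
    return(new_test_result(NA_real_, NA_real_, lengths(groups),
                           "kruskal_wallis_degenerate"))
  }
  H <- H / C
  p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  new_test_result(H, p, lengths(groups), "kruskal_wallis")
}

#' Significance stars
#'
#' Strict-inequality tiers: `****` for p < 0.0001, `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, otherwise `ns`.
#'
#' @param p P-value(s) in \[0, 1\] (vectorized; `NA` passes through).
#' @return Character vector of tiers.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    stopifnot(pi >= 0, pi <= 1)
    if (pi < 0.0001) "****"
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Per-compound screen report
#'
#' The full screen analysis: per compound, the responder fraction and
#' the same-day-control-normalized distributions of peak response,
#' delay time and half-life; a Kruskal-Wallis test across all groups
#' per metric; and unadjusted pairwise Mann-Whitney tests of each
#' compound against control per metric with star annotations. Records
#' with undefined half-life are excluded from half-life statistics and
#' counted. A compound is flagged `affected` when any of its three
#' pairwise tests has p below `alpha`.
#'
#' @param records `data.frame` with columns `animal_id`, `compound`,
#'   `day`, `max_dRR`, `delay_time`, `half_life` (may be `NA`),
#'   `responder`.
#' @param normalize_stat Control anchor, `"mean"` or `"median"`.
#' @param alpha Flagging threshold for the pairwise tests.
#' @param p_adjust Multiple-testing correction applied to the pairwise
#'   p-values per metric, a method of [stats::p.adjust()]; `"none"`
#'   (default) matches the presentation with per-comparison stars.
#' @return List with `summary` (per-compound fractions and counts),
#'   `normalized` (records plus `norm_*` columns), `kruskal`
#'   (per-metric across-group tests), `pairwise` (per compound x metric
#'   vs control), and `affected` (named logical).
#' @export
screen_report <- function(records, normalize_stat = c("mean", "median"),
                          alpha = 0.05, p_adjust = "none") {
  normalize_stat <- match.arg(normalize_stat)
  need <- c("animal_id", "compound", "day", "max_dRR", "delay_time",
            "half_life", "responder")
  stopifnot(all(need %in% names(records)))
  if (!"control" %in% records$compound) stop("no control records")
  metrics <- c("max_dRR", "delay_time", "half_life")
  for (m in metrics) {
    records[[paste0("norm_", m)]] <-
      normalize_to_control(records, m, stat = normalize_stat)
  }
  compounds <- setdiff(unique(records$compound), "control")

  summary <- do.call(rbind, lapply(
    unique(records$compound), function(cp) {
      d <- records[records$compound == cp, ]
      data.frame(compound = cp, n = nrow(d),
                 response_fraction = mean(d$responder),
                 n_half_life_defined = sum(!is.na(d$half_life)),
                 n_half_life_excluded = sum(is.na(d$half_life)))
    }))

  if (length(compounds) == 0) {
    return(list(summary = summary, normalized = records,
                kruskal = NULL, pairwise = NULL,
                affected = logical(0)))
  }

  kruskal <- do.call(rbind, lapply(metrics, function(m) {
    col <- paste0("norm_", m)
    grp <- split(records[[col]][!is.na(records[[col]])],
                 records$compound[!is.na(records[[col]])])
    tst <- kruskal_wallis(grp)
    data.frame(metric = m, statistic = tst$statistic,
               p_value = tst$p_value, stars = tst$stars,
               method = tst$method)
  }))

  pairwise <- do.call(rbind, lapply(metrics, function(m) {
    col <- paste0("norm_", m)
    ctrl <- records[[col]][records$compound == "control"]
    ctrl <- ctrl[!is.na(ctrl)]
    rows <- do.call(rbind, lapply(compounds, function(cp) {
      trt <- records[[col]][records$compound == cp]
      trt <- trt[!is.na(trt)]
      if (length(trt) == 0) {
        return(data.frame(metric = m, compound = cp,
                          statistic = NA_real_, p_value = NA_real_,
                          n_treated = 0L, n_control = length(ctrl)))
      }
      tst <- mann_whitney(trt, ctrl)
      data.frame(metric = m, compound = cp, statistic = tst$statistic,
                 p_value = tst$p_value, n_treated = length(trt),
                 n_control = length(ctrl))
    }))
    rows$p_value <- stats::p.adjust(rows$p_value, method = p_adjust)
    rows$stars <- p_stars(rows$p_value)
    rows
  }))

  affected <- vapply(compounds, function(cp) {
    p <- pairwise$p_value[pairwise$compound == cp]
    any(!is.na(p) & p < alpha)
  }, logical(1))

  list(summary = summary, normalized = records, kruskal = kruskal,
       pairwise = pairwise, affected = affected)
}
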