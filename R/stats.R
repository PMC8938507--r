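#' Two-tailed two-sample t-test and mean ± SEM summary
#'
#' Classical Student's t-test (pooled variance) by default; Welch's
#' correction behind `welch = TRUE`. Degenerate inputs (zero variance in
#' both groups) return p = 1 when the means are equal and p = 0, flagged,
#' when they differ.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param welch use the Welch (unequal-variance) test.
#' @return tibble with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
t_test_two_tailed <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    same <- mean(a) == mean(b)
    return(tibble(
      statistic = if (same) 0 else Inf * sign(mean(a) - mean(b)),
      p_value = if (same) 1 else 0,
      df = NA_real_, mean_a = mean(a), mean_b = mean(b), degenerate = TRUE
    ))
  }
  res <- t.test(a, b, var.equal = !welch)
  tibble(
    statistic = unname(res$statistic), p_value = res$p.value,
    df = unname(res$parameter), mean_a = mean(a), mean_b = mean(b),
    degenerate = FALSE
  )
}

#' @rdname t_test_two_tailed
#' @param values numeric vector.
#' @export
summarize_mean_sem <- function(values) {
  tibble(
    mean = mean(values),
    sem = sd(values) / sqrt(length(values)),
    n = length(values)
  )
}

as_grouped_values <- function(values, group) {
  stopifnot(length(values) == length(group))
  split(as.numeric(values), factor(group))
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups the combined two-group sample is midranked and
#' the standardized rank-sum statistic computed with tie-corrected variance
#' (no continuity correction); the familywise p-value refers
#' `|t| * sqrt(2)` to the studentized-range distribution with `k` groups and
#' infinite degrees of freedom. With k = 2 this reduces to the two-sided
#' normal-approximation Wilcoxon test. A pair whose values are all tied gets
#' p = 1.
#'
#' @param values numeric vector of observations.
#' @param group group label per observation (>= 2 groups, each n >= 2).
#' @return tibble of class `pairwise_test`: `group1`, `group2`, `statistic`
#'   (the standardized rank statistic), `p_value`; method and family size as
#'   attributes.
#' @export
steel_dwass <- function(values, group) {
  g <- as_grouped_values(values, group)
  k <- length(g)
  stopifnot(k >= 2, all(lengths(g) >= 2))
  pairs <- utils::combn(names(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    x <- g[[pr[1]]]
    y <- g[[pr[2]]]
    n1 <- length(x)
    n <- n1 + length(y)
    r <- rank(c(x, y)) # midranks
    if (length(unique(c(x, y))) == 1) {
      return(tibble(
        group1 = pr[1], group2 = pr[2], statistic = 0, p_value = 1
      ))
    }
    rsum <- sum(r[seq_len(n1)])
    e <- n1 * (n + 1) / 2
    v <- n1 * (n - n1) / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
    t_stat <- (rsum - e) / sqrt(v)
    tibble(
      group1 = pr[1], group2 = pr[2], statistic = t_stat,
      p_value = 1 - ptukey(abs(t_stat) * sqrt(2), k, Inf)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("pairwise_test", class(out)),
    method = "steel_dwass", k = k
  )
}

#' Tukey-Kramer all-pairs comparison of means
#'
#' Pooled within-group variance from the one-way ANOVA; for each pair the
#' studentized statistic `q = |m_i - m_j| / sqrt(s2/2 (1/n_i + 1/n_j))` is
#' referred to the studentized-range distribution with `k` groups and
#' `N - k` degrees of freedom. With k = 2 the p-value equals the pooled
#' two-sample t-test's. Zero within-group variance is flagged degenerate.
#'
#' @inheritParams steel_dwass
#' @return tibble of class `pairwise_test`: `group1`, `group2`, `statistic`
#'   (q), `p_value`, `mean_diff`, `degenerate`.
#' @export
tukey_kramer <- function(values, group) {
  g <- as_grouped_values(values, group)
  k <- length(g)
  stopifnot(k >= 2, all(lengths(g) >= 2))
  n <- lengths(g)
  N <- sum(n)
  means <- vapply(g, mean, 0)
  s2 <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / (N - k)
  degenerate <- s2 == 0
  pairs <- utils::combn(names(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    diff <- means[pr[1]] - means[pr[2]]
    if (degenerate) {
      q <- if (diff == 0) 0 else Inf
    } else {
      q <- abs(diff) / sqrt(s2 / 2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    }
    tibble(
      group1 = pr[1], group2 = pr[2], statistic = unname(q),
      p_value = unname(1 - ptukey(q, k, N - k)),
      mean_diff = unname(diff), degenerate = degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("pairwise_test", class(out)),
    method = "tukey_kramer", k = k, df = N - k, pooled_var = s2
  )
}

#' @export
print.pairwise_test <- function(x, ...) {
  cat("<pairwise_test> ", attr(x, "method"), ", k = ", attr(x, "k"),
    " groups, ", nrow(x), " pairs\n",
    sep = ""
  )
  NextMethod()
}

#' Fraction of marker-positive crypts per animal
#'
#' A crypt counts as marker-positive when it contains at least `min_cells`
#' marker-positive cells (inclusive threshold); the per-animal fraction of
#' positive crypts is returned. These fractions are the per-animal values
#' fed to [tukey_kramer()] across treatment groups in crypt-scoring
#' experiments.
#'
#' @param crypts data frame with columns `animal`, `positive_cells`
#'   (non-negative integer per crypt) and optionally `group`.
#' @param min_cells positivity threshold (default 3, inclusive).
#' @return tibble with one row per animal: `animal`, `n_crypts`,
#'   `n_positive`, `fraction` (and `group` when present).
#' @export
crypt_positive_fraction <- function(crypts, min_cells = 3) {
  crypts <- as_tibble(crypts)
  stopifnot(
    all(c("animal", "positive_cells") %in% names(crypts)),
    nrow(crypts) >= 1, all(crypts$positive_cells >= 0)
  )
  keys <- intersect(c("group", "animal"), names(crypts))
  crypts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_crypts = dplyr::n(),
      n_positive = sum(.data$positive_cells >= min_cells),
      fraction = .data$n_positive / .data$n_crypts,
      .groups = "drop"
    )
}
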