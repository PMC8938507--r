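test_that("two-sample t-test matches the closed-form textbook case", {
  same <- t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  sep <- t_test_two_tailed(c(1, 2, 3), c(1, 2, 3) + 100)
  expect_lt(sep$p_value, 1e-3)

  res <- t_test_two_tailed(c(2, 4, 6), c(3, 5, 7))
  # pooled variance 4, se = 2 * sqrt(2/3), t = -1 / se
  t_exp <- -1 / (2 * sqrt(2 / 3))
  expect_equal(res$statistic, t_exp, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(t_exp, df = 4), tolerance = 1e-12)

  # degenerate zero-variance inputs
  flat <- t_test_two_tailed(c(2, 2), c(2, 2))
  expect_identical(flat$p_value, 1)
  expect_true(flat$degenerate)
  apart <- t_test_two_tailed(c(2, 2), c(5, 5))
  expect_identical(apart$p_value, 0)
  expect_true(apart$degenerate)

  s <- summarize_mean_sem(c(2, 4, 6))
  expect_identical(s$mean, 4)
  expect_equal(s$sem, sd(c(2, 4, 6)) / sqrt(3), tolerance = 1e-12)
})

test_that("Steel-Dwass reduces to the uncorrected Wilcoxon at k = 2", {
  sd2 <- steel_dwass(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  z <- 4.5 / sqrt(5.25)
  expect_equal(sd2$p_value, 2 * (1 - pnorm(z)), tolerance = 1e-6)
  expect_equal(sd2$p_value, 0.0495, tolerance = 1e-3)
  expect_equal(abs(sd2$statistic), z, tolerance = 1e-12)
})

test_that("identical groups give p = 1 in both all-pairs procedures", {
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  expect_true(all(steel_dwass(v, g)$p_value == 1))
  tk <- tukey_kramer(v, g)
  expect_true(all(tk$p_value > 1 - 1e-10))
})

test_that("all-pairs results are invariant to group order", {
  set.seed(1)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  perm <- sample(30)
  key <- function(x) {
    x <- tidy(x)
    x[order(x$group1, x$group2), c("group1", "group2", "p_value")]
  }
  expect_equal(key(steel_dwass(v, g)), key(steel_dwass(v[perm], g[perm])),
    tolerance = 1e-12
  )
  expect_equal(key(tukey_kramer(v, g)), key(tukey_kramer(v[perm], g[perm])),
    tolerance = 1e-12
  )
})

test_that("Steel-Dwass agrees with an exhaustive permutation oracle", {
  set.seed(7)
  v <- rnorm(12) + rep(c(0, 3, 6), each = 4)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- tidy(steel_dwass(v, g))

  # exhaustive re-partitioning of the 12 values into the 3 groups:
  # null distribution of the familywise max |standardized pair statistic|
  idx <- 1:12
  first <- utils::combn(idx, 4)
  max_stats <- numeric(0)
  for (i in seq_len(ncol(first))) {
    rest <- setdiff(idx, first[, i])
    second <- utils::combn(rest, 4)
    for (j in seq_len(ncol(second))) {
      ga <- v[first[, i]]
      gb <- v[second[, j]]
      gc_ <- v[setdiff(rest, second[, j])]
      m <- max(
        abs(pairwise_rank_stat(ga, gb)),
        abs(pairwise_rank_stat(ga, gc_)),
        abs(pairwise_rank_stat(gb, gc_))
      )
      max_stats <- c(max_stats, m)
    }
  }
  # the asymptotic range-distribution p tracks the exact permutation
  # distribution; at n = 4 the rank statistic is coarse (17 support points),
  # so mid-range p values carry ~0.03-0.08 approximation error while the
  # far tail agrees closely
  for (r in seq_len(nrow(res))) {
    obs <- abs(res$statistic[r])
    p_perm <- mean(max_stats >= obs - 1e-12)
    expect_lt(abs(res$p_value[r] - p_perm), 0.1)
  }
  strong <- which.max(abs(res$statistic))
  p_perm_tail <- mean(max_stats >= abs(res$statistic[strong]) - 1e-12)
  expect_lt(abs(res$p_value[strong] - p_perm_tail), 0.03)
})

test_that("Tukey-Kramer matches the pooled t-test at k = 2", {
  set.seed(2)
  a <- rnorm(8)
  b <- rnorm(10, 0.8)
  tk <- tukey_kramer(c(a, b), rep(c("a", "b"), c(8, 10)))
  tt <- t_test_two_tailed(a, b)
  expect_equal(tk$p_value, tt$p_value, tolerance = 1e-6)
  expect_equal(tk$statistic, abs(tt$statistic) * sqrt(2), tolerance = 1e-10)
})

test_that("Tukey-Kramer p-values match quadrature of the range CDF", {
  set.seed(3)
  v <- rnorm(18, rep(c(0, 0.5, 2), each = 6))
  g <- rep(c("a", "b", "c"), each = 6)
  tk <- tukey_kramer(v, g)
  for (r in 1:3) {
    p_quad <- 1 - prange_df(tk$statistic[r], k = 3, nu = 15)
    expect_lt(abs(tk$p_value[r] - p_quad), 1e-5)
  }
  # and the infinite-df quadrature matches ptukey directly
  expect_lt(abs(prange_inf(2.5, 3) - ptukey(2.5, 3, Inf)), 1e-7)
})

test_that("Steel-Dwass controls the familywise error under the null", {
  rej <- withr::with_seed(11, {
    vapply(1:2000, function(i) {
      v <- rnorm(30)
      g <- rep(c("a", "b", "c"), each = 10)
      min(steel_dwass(v, g)$p_value) < 0.05
    }, TRUE)
  })
  # familywise rejection of any pair stays at or below nominal
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  expect_gte(mean(rej), 0.01)
})

test_that("crypt positivity uses an inclusive threshold", {
  tab <- tibble::tibble(animal = "m1", positive_cells = c(0, 2, 3, 5))
  res <- crypt_positive_fraction(tab)
  expect_identical(res$fraction, 0.5)

  none <- crypt_positive_fraction(
    tibble::tibble(animal = "m1", positive_cells = rep(0, 10))
  )
  expect_identical(none$fraction, 0)

  many <- crypt_positive_fraction(tibble::tibble(
    animal = "m1", positive_cells = c(rep(5, 30), rep(1, 170))
  ))
  expect_identical(many$fraction, 0.15)

  # order-invariant and idempotent
  perm <- tab[sample(4), ]
  expect_identical(crypt_positive_fraction(perm)$fraction, 0.5)
  expect_identical(crypt_positive_fraction(tab, min_cells = 3)$fraction,
                   crypt_positive_fraction(tab[order(tab$positive_cells), ])$fraction)
})

test_that("per-animal crypt fractions feed group comparisons", {
  crypts <- withr::with_seed(21, {
    tidyr::expand_grid(
      group = c("vehicle", "treated"),
      animal = sprintf("m%d", 1:4),
      crypt = 1:200
    ) |>
      dplyr::mutate(
        animal = paste(.data$group, .data$animal),
        positive_cells = rpois(
          dplyr::n(), ifelse(.data$group == "treated", 2.2, 0.4)
        )
      )
  })
  fr <- crypt_positive_fraction(crypts)
  expect_identical(nrow(fr), 8L)
  tk <- tukey_kramer(fr$fraction, fr$group)
  expect_lt(tk$p_value, 0.01)
})
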