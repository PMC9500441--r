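fake_morph <- function(n_per_group = c(UC = 28, CD = 18, "non-IBD" = 22),
                       crypts = 8, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(names(n_per_group), function(g) {
    dplyr::bind_rows(lapply(seq_len(n_per_group[[g]]), function(i) {
      tibble::tibble(
        specimen_id = sprintf("%s-%02d", g, i), group = g,
        crypt_id = seq_len(crypts),
        volume_um3 = rnorm(crypts, 1e6, 2e5),
        ellipticity_prolate = runif(crypts, 0.3, 1),
        tortuosity = 1 + rexp(crypts, 10)
      )
    }))
  }))
}

test_that("crypt sampling reproduces the cohort bookkeeping", {
  tab <- sample_crypts(fake_morph(), n = 5, seed = 3)
  counts <- table(tab$group)
  expect_equal(unname(counts[c("UC", "CD", "non-IBD")]),
               as.integer(c(140, 90, 110)), ignore_attr = TRUE)
  expect_true(all(table(tab$specimen_id) == 5))
  # sampling is without replacement and seeded
  expect_identical(sample_crypts(fake_morph(), 5, seed = 3), tab)

  short <- fake_morph(c(UC = 2), crypts = 3)
  expect_warning(out <- sample_crypts(short, n = 5, seed = 1), "only 3 crypts")
  expect_equal(nrow(out), 6)
})

test_that("exact Mann-Whitney p equals independent pairwise-counting enumeration", {
  # oracle: enumerate all group assignments, computing U by pairwise
  # comparison counts (not rank sums)
  enum_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x); N <- length(pooled)
    U_of <- function(ix) {
      a <- pooled[ix]; b <- pooled[-ix]
      sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    }
    obs <- U_of(seq_len(n))
    mu <- n * (N - n) / 2
    sets <- utils::combn(N, n)
    us <- apply(sets, 2, U_of)
    mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(8)
  for (i in 1:5) {
    x <- sample(1:10, 6, replace = TRUE)   # ties likely
    y <- sample(1:10, 7, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, enum_p(x, y), tolerance = 1e-12)
  }
  # tie-free case agrees with the reference implementation
  x <- rnorm(7); y <- rnorm(8) + 1
  expect_equal(mann_whitney_u(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
})

test_that("the large-sample path uses the tie-corrected normal approximation", {
  set.seed(9)
  x <- round(rnorm(30, 0, 1), 1)
  y <- round(rnorm(35, 0.8, 1), 1)
  mine <- mann_whitney_u(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_match(mine$method, "tie-corrected")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney p is invariant under monotone transformation", {
  set.seed(10)
  x <- rlnorm(12); y <- rlnorm(15, 0.5)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(log(x), log(y))$p_value)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(x^3, y^3)$p_value)
})

test_that("the test ladder selects Student t, Welch t, or Mann-Whitney as specified", {
  set.seed(11)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 1, 1)
  ct <- compare_groups(a, b)
  expect_identical(ct$test, "Student t")
  expect_equal(ct$p_value, t.test(a, b, var.equal = TRUE)$p.value)

  set.seed(12)
  c1 <- rnorm(40, 0, 1); c2 <- rnorm(40, 1, 4)
  ct2 <- compare_groups(c1, c2)
  expect_identical(ct2$test, "Welch t")

  set.seed(13)
  d1 <- rlnorm(40); d2 <- rlnorm(40, 1)
  ct3 <- compare_groups(d1, d2)
  expect_match(ct3$test, "Mann-Whitney")

  expect_error(compare_groups(rep(2, 5), rep(2, 5)), "degenerate")
  expect_error(compare_groups(1:2, 1:5), "length")

  # clearly separated Gaussians are significant at the ** level
  set.seed(14)
  e1 <- rnorm(30, 0, 1); e2 <- rnorm(30, 5, 1)
  expect_lt(compare_groups(e1, e2)$p_value, 0.01)

  td <- tidy(ct)
  expect_identical(td$test, "Student t")
  expect_named(glance(ct),
               c("test", "p_value", "p_normality_x", "p_normality_y",
                 "p_variance", "alpha"))
})

test_that("Spearman rho matches the rank formula and the reference implementation", {
  expect_equal(spearman_correlation(1:8, (1:8) * 2 + 3)$rho, 1.0)
  expect_equal(spearman_correlation(1:8, rev(1:8))$rho, -1.0)

  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 5)
  d <- rank(x) - rank(y)
  n <- length(x)
  expect_equal(spearman_correlation(x, y)$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(spearman_correlation(x, y)$rho, unname(ref$estimate))
  expect_equal(spearman_correlation(x, y)$p_value, ref$p.value, tolerance = 1e-10)

  set.seed(15)
  xl <- rnorm(30); yl <- xl + rnorm(30)
  reft <- suppressWarnings(cor.test(xl, yl, method = "spearman", exact = FALSE))
  mine <- spearman_correlation(xl, yl)
  expect_equal(mine$p_value, reft$p.value, tolerance = 1e-10)
  expect_error(spearman_correlation(rep(1, 6), 1:6), "rank variance")
})

test_that("cohort comparisons and correlations run over generated cohorts", {
  co <- generate_cohort(c(UC = 8, "non-IBD" = 8), seed = 19)
  tab <- sample_crypts(co$truth, n = 5, seed = 19)
  comp <- compare_cohort(tab)
  expect_equal(nrow(comp), 3)  # three variables, one group pair
  vol_row <- comp[comp$variable == "volume_um3", ]
  expect_lt(vol_row$p_value, 0.05)
  corr <- correlate_cohort(tab, co$cell_counts)
  expect_true(all(c("group", "variable", "count", "rho", "p_value") %in% names(corr)))
  expect_true(all(corr$rho >= -1 & corr$rho <= 1))
})
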