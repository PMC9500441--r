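#' Sample crypts per specimen into a cohort table
#'
#' Selects `n` random crypts per specimen (uniform, without replacement,
#' seeded). Specimens with fewer than `n` crypts contribute all their
#' crypts with a warning; specimens with none are excluded with a warning
#' (mirroring the exclusion of specimens whose crypts are destroyed by
#' inflammation).
#'
#' @param morph Per-crypt morphometry tibble (needs `specimen_id`, `group`,
#'   `crypt_id`, `volume_um3`, `ellipticity_prolate`, `tortuosity`).
#' @param n Crypts per specimen (default 5).
#' @param seed RNG seed.
#' @return Cohort tibble with `sum(min(n, available))` rows per group.
#' @export
sample_crypts <- function(morph, n = 5, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  cols <- intersect(
    c("specimen_id", "group", "crypt_id", "volume_um3",
      "ellipticity_prolate", "tortuosity", "net_twist_deg", "chirality"),
    names(morph)
  )
  out <- morph |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 0) return(df)
      if (nrow(df) < n) {
        warning("specimen ", key$specimen_id, " has only ", nrow(df),
                " crypts (requested ", n, ")", call. = FALSE)
        return(df)
      }
      df[sample.int(nrow(df), n), , drop = FALSE]
    }) |>
    dplyr::ungroup()
  empty <- setdiff(unique(morph$specimen_id), unique(out$specimen_id))
  if (length(empty)) {
    warning("excluded specimen(s) with no crypts: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}

#' Mann-Whitney U test (tie-corrected, exact at small n)
#'
#' Two-sided rank-sum test: when both samples have at most `exact_max`
#' observations the p-value is computed by full enumeration of all
#' `choose(n + m, n)` group assignments of the pooled midranks (valid under
#' ties); otherwise by the normal approximation with the tie-corrected
#' variance.
#'
#' @param x,y Numeric samples.
#' @param exact_max Enumeration cutoff (default 8 per sample).
#' @return List with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n <= exact_max && m <= exact_max) {
    idx <- utils::combn(n + m, n)
    Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n + m
    tt <- table(r)
    tiecor <- sum(tt^3 - tt) / (N * (N - 1))
    v <- n * m / 12 * ((N + 1) - tiecor)
    if (v <= 0) stop("degenerate samples: zero rank variance", call. = FALSE)
    z <- (U - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = U, p_value = min(p, 1), method = method)
}

#' Compare two groups with the normality-guided test ladder
#'
#' The test is chosen at `alpha = 0.05`: Shapiro-Wilk normality on each
#' sample; if both pass, an F test for homogeneity of variance selects
#' Student's t (equal variances) or Welch's t; if normality cannot be
#' assumed for either sample the Mann-Whitney U test is used
#' ([mann_whitney_u()]). Two-sided throughout.
#'
#' @param x,y Numeric samples, each with at least 3 values.
#' @param alpha Decision level for the normality and variance gates.
#' @return A `crypt_test` object recording which test fired, its statistic
#'   and p-value, and the gate p-values. Use [generics::tidy()] /
#'   [generics::glance()] for tibble views.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (stats::var(c(x, y)) == 0) {
    stop("degenerate input: both samples constant and identical", call. = FALSE)
  }
  sw <- function(v) tryCatch(stats::shapiro.test(v)$p.value,
                             error = function(e) 0)
  p_norm_x <- sw(x); p_norm_y <- sw(y)
  p_var <- NA_real_
  if (p_norm_x > alpha && p_norm_y > alpha) {
    p_var <- stats::var.test(x, y)$p.value
    tt <- stats::t.test(x, y, var.equal = p_var > alpha)
    test <- if (p_var > alpha) "Student t" else "Welch t"
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    mw <- mann_whitney_u(x, y)
    test <- paste0("Mann-Whitney U (", mw$method, ")")
    stat <- mw$statistic; p <- mw$p_value
  }
  structure(
    list(test = test, statistic = stat, p_value = p,
         n_x = length(x), n_y = length(y),
         p_normality = c(x = p_norm_x, y = p_norm_y),
         p_variance = p_var, alpha = alpha),
    class = "crypt_test"
  )
}

#' @export
print.crypt_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, %d)\n",
              x$test, x$statistic, x$p_value, x$n_x, x$n_y))
  invisible(x)
}

#' Spearman rank correlation (midranks, exact at small n)
#'
#' rho is the Pearson correlation of midranks. For `n <= exact_max` the
#' two-sided p-value enumerates all `n!` rank permutations; otherwise it
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @param exact_max Enumeration cutoff (default 7).
#' @return A `crypt_correlation` object with `rho`, `p_value`, `method`, `n`.
#' @export
spearman_correlation <- function(x, y, exact_max = 7) {
  n <- length(x)
  stopifnot(n == length(y), n >= 4)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero rank variance", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    method <- "exact enumeration"
  } else {
    tv <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tv), n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = min(p, 1), method = method, n = n),
            class = "crypt_correlation")
}

#' @export
print.crypt_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g (%s, n = %d)\n",
              x$rho, x$p_value, x$method, x$n))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pairwise group comparisons over a cohort table
#'
#' Applies [compare_groups()] to every pair of groups for each requested
#' morphometric variable.
#'
#' @param cohort Cohort tibble from [sample_crypts()].
#' @param variables Columns to compare.
#' @return Tidy tibble: one row per (variable, group pair) with the chosen
#'   test and p-value.
#' @export
compare_cohort <- function(cohort,
                           variables = c("volume_um3", "ellipticity_prolate",
                                         "tortuosity")) {
  grs <- sort(unique(cohort$group))
  out <- list()
  for (v in variables) {
    for (i in seq_along(grs)) for (j in seq_along(grs)) {
      if (j <= i) next
      a <- cohort[[v]][cohort$group == grs[i]]
      b <- cohort[[v]][cohort$group == grs[j]]
      ct <- compare_groups(a, b)
      out[[length(out) + 1L]] <- tibble::tibble(
        variable = v, group_a = grs[i], group_b = grs[j],
        test = ct$test, statistic = ct$statistic, p_value = ct$p_value,
        n_a = length(a), n_b = length(b)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Correlate specimen-averaged morphometry with inflammatory-cell counts
#'
#' Averages each morphometric variable per specimen and computes Spearman
#' correlations against per-specimen inflammatory-cell counts (mean count
#' per high-power field), per group.
#'
#' @param cohort Cohort tibble from [sample_crypts()].
#' @param cell_counts Tibble with `specimen_id` and count columns.
#' @param variables Morphometric columns to correlate.
#' @param count_cols Count columns; default all numeric columns of
#'   `cell_counts` except `specimen_id`.
#' @return Tidy tibble: one row per (group, variable, count type).
#' @export
correlate_cohort <- function(cohort, cell_counts,
                             variables = c("volume_um3", "ellipticity_prolate",
                                           "tortuosity"),
                             count_cols = NULL) {
  count_cols <- count_cols %||%
    setdiff(names(cell_counts)[vapply(cell_counts, is.numeric, TRUE)], "specimen_id")
  spec_means <- cohort |>
    dplyr::group_by(.data$specimen_id, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(variables), mean), .groups = "drop") |>
    dplyr::inner_join(cell_counts, by = "specimen_id")
  out <- list()
  for (g in sort(unique(spec_means$group))) {
    sub <- spec_means[spec_means$group == g, ]
    if (nrow(sub) < 4) next
    for (v in variables) for (cc in count_cols) {
      sc <- tryCatch(spearman_correlation(sub[[v]], sub[[cc]]),
                     error = function(e) NULL)
      if (is.null(sc)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g, variable = v, count = cc,
        rho = sc$rho, p_value = sc$p_value, n = sc$n
      )
    }
  }
  dplyr::bind_rows(out)
}
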