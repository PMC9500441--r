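#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.crypt_test <- function(x, ...) {
  tibble::tibble(
    test = x$test, statistic = x$statistic, p_value = x$p_value,
    n_x = x$n_x, n_y = x$n_y
  )
}

#' @export
glance.crypt_test <- function(x, ...) {
  tibble::tibble(
    test = x$test, p_value = x$p_value,
    p_normality_x = unname(x$p_normality["x"]),
    p_normality_y = unname(x$p_normality["y"]),
    p_variance = x$p_variance, alpha = x$alpha
  )
}

#' @export
tidy.crypt_correlation <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, method = x$method, n = x$n)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, accuracy_overall = x$accuracy_overall, macro_auc = x$macro_auc,
    macro_auc_2dp = round_half_up(x$macro_auc, 2)
  )
}

#' @export
tidy.ssc_report <- function(x, ...) {
  dplyr::mutate(
    x$crypt_chiralities,
    specimen_id = x$specimen_id,
    in_ssc_group = .data$crypt_id %in% unlist(x$ssc_groups),
    .before = 1
  )
}

#' @export
glance.ssc_report <- function(x, ...) {
  tibble::tibble(
    specimen_id = x$specimen_id,
    n_crypts = nrow(x$crypt_chiralities),
    n_groups = length(x$ssc_groups),
    ssc_positive = x$ssc_positive
  )
}
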