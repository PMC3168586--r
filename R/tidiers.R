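#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Fisher burden test result
#'
#' @param x A `cnv_fisher` object from [fisher_exact()] or [burden_test()].
#' @param ... Unused.
#' @return A one-row tibble with the odds-ratio estimate and both p-values.
#' @export
tidy.cnv_fisher <- function(x, ...) {
  tibble::tibble(
    estimate = x$odds_ratio,
    p.value = x$p_one_sided_greater,
    p.value.two.sided = x$p_two_sided,
    alternative = "greater",
    method = "Fisher's exact test (carrier burden)")
}

#' Glance at a Fisher burden test result
#'
#' @inheritParams tidy.cnv_fisher
#' @return A one-row tibble with cell counts, odds ratio and p-values.
#' @export
glance.cnv_fisher <- function(x, ...) {
  t <- x$table
  tibble::tibble(
    case_carriers = t$case_carriers,
    n_cases = t$case_carriers + t$case_noncarriers,
    control_carriers = t$control_carriers,
    n_controls = t$control_carriers + t$control_noncarriers,
    odds_ratio = x$odds_ratio,
    p_one_sided_greater = x$p_one_sided_greater,
    p_two_sided = x$p_two_sided,
    degenerate = x$degenerate)
}

#' Tidy a simulation recovery report
#'
#' @param x A `recovery_report` from [score_recovery()].
#' @param ... Unused.
#' @return A one-row tibble of recovery metrics.
#' @export
tidy.recovery_report <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$sensitivity,
    false_calls_per_sample = x$false_calls_per_sample,
    n_truth = x$n_truth,
    n_matched = x$n_matched,
    n_false = x$n_false)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "CNV recovery: %d/%d truth events matched (sensitivity %.3f), %.2f false calls/sample\n",
    x$n_matched, x$n_truth, x$sensitivity, x$false_calls_per_sample))
  invisible(x)
}
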