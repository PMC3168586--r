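#' Count carriers of large CNVs in a cohort
#'
#' A sample is a carrier when it has at least one call strictly larger than
#' `size_threshold_bp`; each sample counts once however many qualifying
#' calls it has, and samples with no calls at all count as non-carriers —
#' which is why the full assayed roster must be supplied, not just the
#' samples that produced calls.
#'
#' @param calls A CNV call tibble.
#' @param sample_ids Character vector: every assayed sample in the cohort.
#' @param size_threshold_bp Strict size threshold (default 500,000, i.e.
#'   carriers have a call > 500 kbp).
#' @return A one-row tibble with `carriers`, `noncarriers`, `n`.
#' @export
count_carriers <- function(calls, sample_ids,
                           size_threshold_bp = 500000) {
  sample_ids <- unique(as.character(sample_ids))
  unknown <- setdiff(calls$sample_id, sample_ids)
  if (length(unknown)) {
    rlang::abort(sprintf("call sample '%s' is not on the roster.",
                         unknown[1]))
  }
  carriers <- calls |>
    dplyr::filter(.data$size_bp > size_threshold_bp) |>
    dplyr::distinct(.data$sample_id) |>
    nrow()
  tibble::tibble(carriers = carriers,
                 noncarriers = length(sample_ids) - carriers,
                 n = length(sample_ids))
}

#' Assemble the 2x2 case-control burden table
#'
#' @param case_carriers,case_noncarriers,control_carriers,control_noncarriers
#'   Non-negative cell counts.
#' @return A `burden_table` (named list) validated so both cohorts are
#'   non-empty.
#' @export
burden_table <- function(case_carriers, case_noncarriers,
                         control_carriers, control_noncarriers) {
  cells <- c(case_carriers, case_noncarriers,
             control_carriers, control_noncarriers)
  if (any(cells < 0) || any(cells != round(cells))) {
    rlang::abort("burden table cells must be non-negative integers.")
  }
  if (case_carriers + case_noncarriers == 0 ||
      control_carriers + control_noncarriers == 0) {
    rlang::abort("both cohorts must contain at least one sample.")
  }
  structure(list(case_carriers = as.integer(case_carriers),
                 case_noncarriers = as.integer(case_noncarriers),
                 control_carriers = as.integer(control_carriers),
                 control_noncarriers = as.integer(control_noncarriers)),
            class = "burden_table")
}

# log hypergeometric point mass via log-gamma, stable to N ~ 1e5
log_dhyper <- function(k, K, N, n) {
  lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
}

#' Fisher's exact test on a carrier burden table
#'
#' Exact hypergeometric evaluation of the 2x2 table, computed over the full
#' support with log-gamma factorials. The one-sided (greater) p-value is
#' the probability of at least the observed number of case carriers under
#' the fixed margins; the two-sided p-value is the standard Fisher
#' convention, the sum of all outcome probabilities no larger than the
#' observed outcome's probability. The odds ratio is the sample
#' (cross-product) estimate ad/bc, infinite when bc = 0.
#'
#' A table with a zero row or column margin carries no information; both
#' p-values are then 1 and `degenerate` is set.
#'
#' @param table A [burden_table()].
#' @return An object of class `cnv_fisher` with fields
#'   `p_one_sided_greater`, `p_two_sided`, `odds_ratio`, `degenerate` and
#'   `table`.
#' @export
fisher_exact <- function(table) {
  stopifnot(inherits(table, "burden_table"))
  a <- table$case_carriers; b <- table$case_noncarriers
  cc <- table$control_carriers; d <- table$control_noncarriers
  N <- a + b + cc + d
  K <- a + cc          # carriers overall
  n <- a + b           # cases
  or <- if (b == 0 || cc == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else {
    (a / b) * (d / cc)
  }
  degenerate <- (K == 0 || K == N || n == 0 || n == N)
  if (degenerate) {
    res <- list(p_one_sided_greater = 1, p_two_sided = 1, odds_ratio = or,
                degenerate = TRUE, table = table)
    return(structure(res, class = "cnv_fisher"))
  }
  support <- max(0, n - (N - K)):min(K, n)
  logp <- log_dhyper(support, K, N, n)
  p <- exp(logp)
  p_obs <- exp(log_dhyper(a, K, N, n))
  p_greater <- sum(p[support >= a])
  # relative tolerance guards equal-probability outcomes against roundoff
  p_two <- sum(p[p <= p_obs * (1 + 1e-7)])
  structure(list(p_one_sided_greater = min(p_greater, 1),
                 p_two_sided = min(p_two, 1),
                 odds_ratio = or, degenerate = FALSE, table = table),
            class = "cnv_fisher")
}

#' @export
print.cnv_fisher <- function(x, ...) {
  t <- x$table
  cat("Carrier burden (Fisher's exact test)\n")
  cat(sprintf("  cases:    %d/%d carriers\n",
              t$case_carriers, t$case_carriers + t$case_noncarriers))
  cat(sprintf("  controls: %d/%d carriers\n",
              t$control_carriers,
              t$control_carriers + t$control_noncarriers))
  cat(sprintf("  odds ratio = %.3g\n", x$odds_ratio))
  cat(sprintf("  p (one-sided, cases enriched) = %.4g\n",
              x$p_one_sided_greater))
  cat(sprintf("  p (two-sided) = %.4g\n", x$p_two_sided))
  invisible(x)
}

#' Run the large-CNV burden test between two call sets
#'
#' Convenience wrapper: counts carriers of calls strictly larger than
#' `size_threshold_bp` in each cohort and applies [fisher_exact()].
#'
#' @param case_calls,control_calls CNV call tibbles.
#' @param case_ids,control_ids Full cohort rosters.
#' @param size_threshold_bp Strict size threshold (default 500 kbp).
#' @return A `cnv_fisher` object.
#' @export
burden_test <- function(case_calls, case_ids, control_calls, control_ids,
                        size_threshold_bp = 500000) {
  ca <- count_carriers(case_calls, case_ids, size_threshold_bp)
  co <- count_carriers(control_calls, control_ids, size_threshold_bp)
  fisher_exact(burden_table(ca$carriers, ca$noncarriers,
                            co$carriers, co$noncarriers))
}

# half-up rounding to one decimal (round() rounds half to even)
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Format diagnosis counts as "count (pct%)"
#'
#' Computes each diagnosis's percentage of the group and renders it the way
#' clinical summary tables print them: one decimal, half-up rounding, with
#' integral percentages (including 0 and 100) shown without the decimal —
#' so 63 of 117 renders as `"63 (53.8%)"` and 0 of 30 as `"0 (0%)"`.
#'
#' @param diagnoses A data frame with columns `diagnosis` and `count`.
#' @param n_group Group size (> 0); every count must be <= `n_group`.
#' @return The input tibble with numeric `pct` and formatted `label`
#'   columns.
#' @export
diagnosis_percentages <- function(diagnoses, n_group) {
  if (n_group <= 0) rlang::abort("`n_group` must be positive.")
  diagnoses <- tibble::as_tibble(diagnoses)
  if (any(diagnoses$count < 0) || any(diagnoses$count > n_group)) {
    rlang::abort("counts must be between 0 and `n_group`.")
  }
  pct <- round_half_up1(100 * diagnoses$count / n_group)
  label <- ifelse(pct == round(pct),
                  sprintf("%d (%d%%)", diagnoses$count, as.integer(round(pct))),
                  sprintf("%d (%.1f%%)", diagnoses$count, pct))
  dplyr::mutate(diagnoses, pct = pct, label = label)
}
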