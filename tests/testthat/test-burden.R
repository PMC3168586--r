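test_that("carrier counting is per-sample with a strict size threshold", {
  calls <- as_cnv_calls(tibble::tibble(
    sample_id = c("A", "A", "B"), chrom = "chr1",
    start = c(1e6, 10e6, 20e6),
    end = c(1e6 + 6e5 - 1, 10e6 + 7e5 - 1, 20e6 + 4e5 - 1),
    state = "decreased", n_probes = 20L, mean_z = -3))
  row <- count_carriers(calls, c("A", "B", "C"), 500000)
  expect_equal(row$carriers, 1)      # A counted once despite two large calls
  expect_equal(row$noncarriers, 2)   # B (400 kbp) and C (no calls)

  expect_equal(count_carriers(calls[0, ], letters[1:10], 500000)$carriers, 0)
  expect_equal(count_carriers(calls, c("A", "B"), 0)$carriers, 2)
  expect_error(count_carriers(calls, c("A"), 0), "roster")

  # invariant to call order and duplication
  shuffled <- calls[c(3, 1, 2, 2, 1), ]
  expect_equal(count_carriers(shuffled, c("A", "B", "C"), 500000), row)
})

test_that("the exact test reproduces known tables", {
  # the published large-CNV burden table: 6/113 cases vs 6/306 controls
  res <- fisher_exact(burden_table(6, 107, 6, 300))
  expect_equal(res$p_one_sided_greater, 0.07273273, tolerance = 1e-6)
  expect_equal(res$p_two_sided, 0.09442302, tolerance = 1e-6)
  expect_equal(res$odds_ratio, (6 / 107) * (300 / 6))

  # closed form: Hypergeom(N=6, K=3, n=3), P(X >= 2) = 10/20
  expect_equal(fisher_exact(burden_table(2, 1, 1, 2))$p_one_sided_greater,
               0.5)

  # degenerate margin
  res0 <- fisher_exact(burden_table(0, 10, 0, 20))
  expect_true(res0$degenerate)
  expect_equal(res0$p_one_sided_greater, 1)
  expect_equal(res0$p_two_sided, 1)

  expect_true(is.infinite(fisher_exact(burden_table(3, 0, 2, 5))$odds_ratio))
})

test_that("exact p-values match enumeration and stats::fisher.test", {
  set.seed(19)
  for (i in 1:60) {
    N <- sample(4:60, 1)
    a_ <- sample(0:N, 1); rest <- N - a_
    b_ <- sample(0:rest, 1); rest <- rest - b_
    c_ <- sample(0:rest, 1); d_ <- rest - c_
    if (a_ + b_ == 0 || c_ + d_ == 0) next
    res <- fisher_exact(burden_table(a_, b_, c_, d_))
    if (res$degenerate) {
      expect_equal(res$p_one_sided_greater, 1)
      next
    }
    oracle <- enumerate_fisher(a_, b_, c_, d_)
    expect_equal(res$p_one_sided_greater, oracle$greater, tolerance = 1e-10)
    expect_equal(res$p_two_sided, oracle$two_sided, tolerance = 1e-10)
    expect_equal(oracle$total, 1, tolerance = 1e-12)
    m <- matrix(c(a_, b_, c_, d_), 2, byrow = TRUE)
    expect_equal(res$p_one_sided_greater,
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(res$p_two_sided, fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("swapping cohorts maps greater to less; two-sided is invariant", {
  set.seed(23)
  for (i in 1:20) {
    a_ <- sample(0:8, 1); b_ <- sample(1:30, 1)
    c_ <- sample(0:8, 1); d_ <- sample(1:30, 1)
    res <- fisher_exact(burden_table(a_, b_, c_, d_))
    swp <- fisher_exact(burden_table(c_, d_, a_, b_))
    if (res$degenerate) next
    m <- matrix(c(a_, b_, c_, d_), 2, byrow = TRUE)
    expect_equal(swp$p_one_sided_greater,
                 fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-9)
    expect_equal(swp$p_two_sided, res$p_two_sided, tolerance = 1e-10)
  }
})

test_that("burden_test composes counting and the exact test", {
  big <- function(s, id) as_cnv_calls(tibble::tibble(
    sample_id = id, chrom = "chr1", start = 1e6, end = 1e6 + s - 1,
    state = "decreased", n_probes = 30L, mean_z = -4))
  case_calls <- dplyr::bind_rows(big(6e5, "case1"), big(3e5, "case2"))
  ctrl_calls <- big(7e5, "ctrl1")
  res <- burden_test(case_calls, c("case1", "case2", "case3"),
                     ctrl_calls, paste0("ctrl", 1:6))
  expect_equal(res$table$case_carriers, 1)
  expect_equal(res$table$control_carriers, 1)
  td <- tidy(res)
  expect_equal(td$p.value, res$p_one_sided_greater)
  gl <- glance(res)
  expect_equal(gl$n_cases, 3)
  expect_equal(gl$n_controls, 6)
})

test_that("diagnosis percentages print like clinical summary tables", {
  tab <- tibble::tibble(
    diagnosis = c("Major depression", "Personality disorders",
                  "Somatoform", "Lifetime Axis I"),
    count = c(63, 107, 5, 117))
  out <- diagnosis_percentages(tab, 117)
  expect_identical(out$label, c("63 (53.8%)", "107 (91.5%)", "5 (4.3%)",
                                "117 (100%)"))
  out30 <- diagnosis_percentages(
    tibble::tibble(diagnosis = c("Antisocial", "Phobic", "All"),
                   count = c(0, 6, 30)), 30)
  expect_identical(out30$label, c("0 (0%)", "6 (20%)", "30 (100%)"))
  # half-up rounding at the boundary: 0.25% -> 0.3%, where half-even gives 0.2%
  expect_identical(diagnosis_percentages(
    tibble::tibble(diagnosis = "x", count = 1), 400)$label, "1 (0.3%)")
  expect_error(diagnosis_percentages(
    tibble::tibble(diagnosis = "x", count = 31), 30), "between 0")
})
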