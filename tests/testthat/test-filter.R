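mk_calls <- function(sizes, n_probes = 10L, mean_z = -3,
                     sample_id = "s1", chrom = "chr1", start = 1000000) {
  starts <- start + cumsum(c(0, rep(5e6, length(sizes) - 1)))
  as_cnv_calls(tibble::tibble(
    sample_id = sample_id, chrom = chrom, start = starts,
    end = starts + sizes - 1,
    state = ifelse(mean_z < 0, "decreased", "increased"),
    n_probes = n_probes, mean_z = mean_z))
}

test_that("threshold filters enforce size, probe and z minima", {
  calls <- mk_calls(c(40000, 60000))
  kept <- apply_threshold_filters(calls)
  expect_equal(kept$size_bp, 60000L)      # 40 kbp call dropped (> 50 kbp rule)
  expect_equal(nrow(apply_threshold_filters(
    mk_calls(60000, n_probes = 3L))), 0)  # too few probes
  expect_equal(nrow(apply_threshold_filters(
    mk_calls(60000, mean_z = -1.0))), 0)  # |mean z| below 1.5
  # exactly 50,000 bp is not "> 50 kbp"
  expect_equal(nrow(apply_threshold_filters(mk_calls(50000))), 0)
  expect_equal(nrow(apply_threshold_filters(mk_calls(50001))), 1)
})

test_that("every threshold is monotone", {
  set.seed(55)
  calls <- mk_calls(sizes = sample(10000:900000, 30),
                    n_probes = sample(1:40, 30, replace = TRUE),
                    mean_z = -runif(30, 0.5, 6))
  for (fld in c("min_size_bp", "min_probes", "min_abs_mean_z")) {
    grid <- switch(fld,
                   min_size_bp = c(1, 50001, 200000, 900000),
                   min_probes = c(1, 5, 20, 50),
                   min_abs_mean_z = c(0.1, 1.5, 3, 7))
    counts <- vapply(grid, function(v) {
      args <- list(); args[[fld]] <- v
      nrow(apply_threshold_filters(calls, do.call(filter_policy, args)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("large-CNV classification is strict at 500 kbp", {
  calls <- mk_calls(c(600000, 500000, 500001, 100000))
  parts <- classify_large(calls)
  expect_setequal(parts$large$size_bp, c(600000L, 500001L))
  expect_setequal(parts$small$size_bp, c(500000L, 100000L))
  expect_equal(nrow(parts$large) + nrow(parts$small), nrow(calls))
  empty <- classify_large(calls[0, ])
  expect_equal(nrow(empty$large), 0)
  expect_equal(nrow(empty$small), 0)
})

test_that("control frequency sums carriers over reciprocal-overlap matches", {
  call <- mk_calls(430000, chrom = "chr15", start = 28000000)
  # full-overlap record: the 35-of-5,570 duplication carrier count
  cat1 <- control_catalog(
    tibble::tibble(chrom = "chr15", start = 28000000, end = 28429999,
                   carrier_count = 35L), 5570)
  expect_equal(control_frequency(call, cat1), 35 / 5570, tolerance = 1e-12)
  expect_equal(round(control_frequency(call, cat1), 6), 0.006284)
  # no overlapping record
  cat2 <- control_catalog(
    tibble::tibble(chrom = "chr15", start = 60000000, end = 60400000,
                   carrier_count = 100L), 306)
  expect_equal(control_frequency(call, cat2), 0)
  # a record overlapping only 40% reciprocally contributes nothing at 0.5
  cat3 <- control_catalog(
    tibble::tibble(chrom = "chr15", start = 28000000,
                   end = 28000000 + 172000 - 1, carrier_count = 50L), 306)
  expect_equal(control_frequency(call, cat3), 0)
  expect_gt(control_frequency(call, cat3, min_reciprocal_overlap = 0.3), 0)
})

test_that("rarity filtering keeps events rare in every catalog", {
  calls <- mk_calls(c(430000, 430000, 430000), chrom = "chr15",
                    start = 20000000)
  # catalogs covering the three calls at 0.63%, 5% and 0% frequency
  rec <- function(i, carriers, n) {
    control_catalog(tibble::tibble(
      chrom = "chr15", start = calls$start[i], end = calls$end[i],
      carrier_count = carriers), n)
  }
  big <- control_catalog(
    tibble::tibble(chrom = "chr15",
                   start = calls$start[1:2], end = calls$end[1:2],
                   carrier_count = c(35L, 279L)), 5570)
  nimh <- control_catalog(
    tibble::tibble(chrom = "chr15", start = calls$start[2],
                   end = calls$end[2], carrier_count = 16L), 306)
  out <- rare_filter(calls, list(big = big, nimh = nimh))
  # call 1: 35/5570 = 0.63% and 0/306 -> retained; call 2: 5% -> removed;
  # call 3: absent everywhere -> retained
  expect_equal(out$start, calls$start[c(1, 3)])
  expect_equal(out$freq_big[1], 35 / 5570)
  expect_equal(out$freq_nimh, c(0, 0))
})

test_that("an empty catalog is the identity and filters commute", {
  calls <- mk_calls(c(60000, 70000, 600000))
  empty_cat <- control_catalog(
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), carrier_count = integer()), 306)
  out <- rare_filter(calls, empty_cat)
  expect_equal(dplyr::select(out, -dplyr::starts_with("freq_")), calls)

  common <- control_catalog(
    tibble::tibble(chrom = "chr1", start = calls$start[2],
                   end = calls$end[2], carrier_count = 100L), 306)
  a <- rare_filter(apply_threshold_filters(calls), common)
  b <- apply_threshold_filters(rare_filter(calls, common))
  expect_equal(dplyr::select(a, dplyr::all_of(names(b))), b)
})
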