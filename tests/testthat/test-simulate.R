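test_that("design generation hits the expected probe budget", {
  # backbone only: 10 Mbp at 36-kbp spacing -> about 278 probes
  d0 <- generate_design(
    array_design_spec(n_hotspots = 0, chrom_sizes = c(chr1 = 10e6)),
    seed = 11)
  expect_gt(nrow(d0), 278 * 0.95 - 10)
  expect_lt(nrow(d0), 278 * 1.05 + 10)
  expect_true(all(d0$region_class == "backbone"))

  # a 260-kbp hotspot at 2.6-kbp spacing -> about 100 probes inside it
  d1 <- generate_design(
    array_design_spec(n_hotspots = 1, hotspot_size_bp = 260000,
                      chrom_sizes = c(chr1 = 10e6)),
    seed = 12)
  hs <- hotspot_regions(d1)
  inside <- sum(d1$start >= hs$start[1] & d1$end <= hs$end[1])
  expect_gt(inside, 85)
  expect_lt(inside, 115)
})

test_that("design generation is deterministic and validated", {
  spec <- array_design_spec(n_hotspots = 4, chrom_sizes = c(chr1 = 20e6))
  d1 <- generate_design(spec, seed = 3)
  d2 <- generate_design(spec, seed = 3)
  expect_identical(d1, d2)
  d3 <- generate_design(spec, seed = 4)
  expect_false(identical(d1$start, d3$start))
  # hotspots larger than every chromosome cannot be placed
  expect_error(
    array_design_spec(n_hotspots = 1, hotspot_size_bp = 5e6,
                      chrom_sizes = c(chr1 = 1e6)),
    "exceed")
})

test_that("simulated samples carry the configured signal", {
  design <- toy_design(10000, spacing = 3000)
  noise <- noise_model(probe_noise_sd = 0.2, sample_baseline_sd = 0)
  prof <- simulate_sample(design, NULL, noise, seed = 21)
  # SE of the mean is 0.2/sqrt(10000) = 0.002; 5 sigma band
  expect_lt(abs(mean(prof$value)), 0.01)

  # a deletion spanning 50 probes shifts exactly those probes by -1
  del <- cnv_spec("chr1", design$start[101], design$end[150], "deletion")
  prof2 <- simulate_sample(design, del, noise, seed = 21)
  expect_gt(mean(prof2$value[101:150]), -1.15)
  expect_lt(mean(prof2$value[101:150]), -0.85)

  # degenerate noise: values are exactly baseline + shift
  tiny <- noise_model(probe_noise_sd = 1e-12, sample_baseline_sd = 0)
  prof3 <- simulate_sample(design, del, tiny, seed = 21)
  expect_equal(prof3$value[101:150], rep(-1, 50), tolerance = 1e-9)
  expect_equal(prof3$value[1:100], rep(0, 100), tolerance = 1e-9)

  # determinism
  expect_identical(simulate_sample(design, del, noise, seed = 21),
                   prof2)
  # overlapping opposite-sign truths are rejected
  bad <- dplyr::bind_rows(
    cnv_spec("chr1", 100000, 200000, "deletion"),
    cnv_spec("chr1", 150000, 250000, "duplication"))
  expect_error(simulate_sample(design, bad, noise, seed = 1),
               "opposite sign")
})

test_that("cohort simulation draws carriers at the configured frequency", {
  design <- toy_design(20, spacing = 5000)
  ev <- function(f) cnv_spec("chr1", design$start[5], design$end[10],
                             "deletion", carrier_frequency = f)
  sim1 <- simulate_cohort(design, ev(1), ev(0), 10, 3, noise_model(),
                          seed = 31)
  expect_equal(dplyr::n_distinct(sim1$profiles$sample_id), 13)
  expect_equal(sum(sim1$truth$group == "case"), 10)
  expect_equal(sum(sim1$truth$group == "control"), 0)

  sim0 <- simulate_cohort(design, ev(0), ev(0), 10, 3, noise_model(),
                          seed = 31)
  expect_equal(nrow(sim0$truth), 0)

  # Binomial(1000, 0.5): 3.8 sigma band is [440, 560]
  simh <- simulate_cohort(design, ev(0.5), ev(0), 1000, 1, noise_model(),
                          seed = 32)
  k <- sum(simh$truth$group == "case")
  expect_gt(k, 440)
  expect_lt(k, 560)
  expect_error(simulate_cohort(design, ev(0), ev(0), 0, 3, noise_model()),
               "positive")
})

test_that("recovery scoring matches on sample, sign and reciprocal overlap", {
  truth <- tibble::tibble(sample_id = "s1", group = "case", chrom = "chr1",
                          start = 1000, end = 1999, kind = "deletion",
                          log2_shift = -1)
  call_exact <- as_cnv_calls(tibble::tibble(
    sample_id = "s1", chrom = "chr1", start = 1000, end = 1999,
    state = "decreased", n_probes = 10L, mean_z = -4))
  r <- score_recovery(call_exact, truth)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$false_calls_per_sample, 0)

  r0 <- score_recovery(call_exact[0, ], truth)
  expect_equal(r0$sensitivity, 0)

  # 60% mutual coverage at threshold 0.5 -> matched
  call_part <- as_cnv_calls(tibble::tibble(
    sample_id = "s1", chrom = "chr1", start = 1400, end = 2399,
    state = "decreased", n_probes = 10L, mean_z = -4))
  expect_equal(score_recovery(call_part, truth)$sensitivity, 1)
  expect_equal(score_recovery(call_part, truth,
                              min_reciprocal_overlap = 0.7)$sensitivity, 0)

  # wrong sign never matches
  call_dup <- as_cnv_calls(dplyr::mutate(call_exact, state = "increased",
                                         mean_z = 4))
  rw <- score_recovery(call_dup, truth)
  expect_equal(rw$sensitivity, 0)
  expect_equal(rw$n_false, 1)
  expect_error(score_recovery(call_exact, truth, min_reciprocal_overlap = 0),
               "min_reciprocal_overlap")
})
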