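probes_at <- function(starts, chrom = "chr1", len = 50) {
  tibble::tibble(chrom = chrom, start = starts, end = starts + len - 1)
}

test_that("same-state runs merge while probes are < 50 kbp apart", {
  probes <- probes_at(c(100000, 110000, 120000))
  segs <- states_to_segments(rep("decreased", 3), probes, c(-3, -3.5, -3),
                             merge_policy())
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_probes, 3L)
  expect_equal(segs$start, 100000)
  expect_equal(segs$end, 120049)
  expect_equal(segs$mean_z, mean(c(-3, -3.5, -3)))
})

test_that("a start-to-start gap of 50 kbp or more splits the run", {
  probes <- probes_at(c(100000, 160001))
  segs <- states_to_segments(rep("decreased", 2), probes, c(-3, -3),
                             merge_policy())
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_probes, c(1L, 1L))
  # boundary: gap of exactly 50 kbp still splits, one base less merges
  probes2 <- probes_at(c(100000, 150000))
  expect_equal(nrow(states_to_segments(rep("decreased", 2), probes2,
                                       c(-3, -3), merge_policy())), 2)
  probes3 <- probes_at(c(100000, 149999))
  expect_equal(nrow(states_to_segments(rep("decreased", 2), probes3,
                                       c(-3, -3), merge_policy())), 1)
})

test_that("all-normal paths produce no segments", {
  probes <- probes_at(c(1000, 2000, 3000))
  expect_equal(nrow(states_to_segments(rep("normal", 3), probes,
                                       rep(0, 3), merge_policy())), 0)
})

test_that("bridging fuses segments over short, sparse interruptions", {
  policy <- merge_policy()
  # 5 decreased, then `k` normal probes spanning `span_bp`, then 5 decreased
  build <- function(k, span_bp) {
    left <- 1000 + 2000 * (0:4)
    gap_start <- left[5] + 50 + 1       # intervening bases start here
    mids <- if (k > 0) {
      seq(gap_start, gap_start + span_bp - 1000, length.out = k)
    } else {
      numeric(0)
    }
    right0 <- gap_start + span_bp       # next segment starts after the gap
    right <- right0 + 2000 * (0:4)
    starts <- round(c(left, mids, right))
    probes <- probes_at(starts)
    states <- c(rep("decreased", 5), rep("normal", k), rep("decreased", 5))
    z <- ifelse(states == "decreased", -3, 0)
    raw <- states_to_segments(states, probes, z, policy)
    bridge_merge(raw, probes, z, policy)
  }
  # 4 intervening probes over ~8 kbp -> single variant, probes absorbed
  m <- build(4, 8000)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_probes, 14L)
  expect_equal(m$mean_z, mean(c(rep(-3, 10), rep(0, 4))))
  # 6 intervening probes -> probe condition fails
  expect_equal(nrow(build(6, 8000)), 2)
  # 3 probes but ~12 kbp span -> distance condition fails
  expect_equal(nrow(build(3, 12000)), 2)
})

test_that("bridging respects state identity and adjacency", {
  # decreased / increased / decreased: the opposite-state segment in the
  # middle blocks any bridge
  starts <- 1000 + 2000 * (0:8)
  probes <- probes_at(starts)
  states <- c(rep("decreased", 3), rep("increased", 3), rep("decreased", 3))
  z <- c(rep(-3, 3), rep(3, 3), rep(-3, 3))
  raw <- states_to_segments(states, probes, z, merge_policy())
  out <- bridge_merge(raw, probes, z, merge_policy())
  expect_equal(nrow(out), 3)
  expect_identical(out$state, c("decreased", "increased", "decreased"))
})

test_that("bridge_merge is idempotent", {
  set.seed(77)
  for (i in 1:200) {
    case <- random_segmentation()
    raw <- states_to_segments(case$states, case$probes, case$z,
                              merge_policy())
    once <- bridge_merge(raw, case$probes, case$z, merge_policy())
    twice <- bridge_merge(once, case$probes, case$z, merge_policy())
    expect_equal(twice, once)
  }
})
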