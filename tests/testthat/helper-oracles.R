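# Independent oracles and small fixture builders shared across tests.

# exhaustive maximization over all 3^n state paths -- the Viterbi oracle
brute_force_viterbi <- function(z, params = hmm_params()) {
  states <- copy_states()
  n <- length(z)
  grid <- do.call(expand.grid, rep(list(1:3), n))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    p <- as.integer(grid[r, ])
    lp <- unname(log(params$initial_probs[p[1]])) +
      sum(dnorm(z, params$means[p], params$sds[p], log = TRUE))
    if (n > 1) {
      for (t in 2:n) lp <- lp + log(params$transition[p[t - 1], p[t]])
    }
    if (lp > best) {
      best <- lp
      best_path <- p
    }
  }
  list(states = states[best_path], log_score = best)
}

# random emission/transition parameters that satisfy the hmm_params contract
random_hmm_params <- function() {
  m <- sort(runif(3, -5, 5))
  m <- m + c(-0.1, 0, 0.1)  # guarantee strict ordering
  hmm_params(mean_decreased = m[1], mean_normal = m[2], mean_increased = m[3],
             sd_decreased = runif(1, 0.3, 2), sd_normal = runif(1, 0.3, 2),
             sd_increased = runif(1, 0.3, 2),
             stay_prob = runif(1, 0.5, 0.999),
             initial_probs = {
               p <- runif(3, 0.05, 1)
               p / sum(p)
             })
}

# one-sided (greater) and two-sided Fisher p by direct enumeration over the
# hypergeometric support, using stats::dhyper as the mass function -- an
# implementation-independent route
enumerate_fisher <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_
  n <- a + b
  support <- max(0, n - (N - K)):min(K, n)
  p <- dhyper(support, K, N - K, n)
  p_obs <- dhyper(a, K, N - K, n)
  list(greater = sum(p[support >= a]),
       two_sided = sum(p[p <= p_obs * (1 + 1e-7)]),
       total = sum(p))
}

# a tiny hand-built design: evenly spaced probes on one or more chromosomes
toy_design <- function(n = 10, chrom = "chr1", spacing = 10000,
                       start0 = 100000, probe_len = 50) {
  per <- rep(n, length(chrom))
  rows <- purrr::map2(chrom, per, function(cc, k) {
    s <- start0 + spacing * (0:(k - 1))
    tibble::tibble(chrom = cc, start = s, end = s + probe_len - 1,
                   region_class = "backbone")
  })
  df <- purrr::list_rbind(rows)
  df$probe_id <- sprintf("p%03d", seq_len(nrow(df)))
  as_probe_design(df)
}

toy_profile <- function(design, values, sample_id = "s1",
                        kind = "log2_ratio") {
  cnvburden:::new_profiles(
    tibble::tibble(sample_id = sample_id, probe_id = design$probe_id,
                   value = values),
    kind)
}

# random segmentation instance for merge idempotence checks: probes with
# irregular gaps plus a random state path
random_segmentation <- function() {
  n <- sample(10:60, 1)
  gaps <- sample(c(500, 2000, 8000, 12000, 60000), n - 1, replace = TRUE)
  starts <- cumsum(c(1000, gaps))
  probes <- tibble::tibble(chrom = "chr1", start = starts,
                           end = starts + 49)
  states <- sample(copy_states(), n, replace = TRUE,
                   prob = c(0.2, 0.6, 0.2))
  z <- ifelse(states == "decreased", -3, ifelse(states == "increased", 3, 0)) +
    rnorm(n, 0, 0.1)
  list(probes = probes, states = states, z = z)
}
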