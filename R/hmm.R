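#' Viterbi decoding of a z-score vector
#'
#' Computes the single most probable hidden-state path through the
#' three-state copy-number HMM given one chromosome's z-scores, under
#' Gaussian emissions and the homogeneous transition matrix of
#' [hmm_params()]. All arithmetic is in log space, so there is no
#' probability underflow for any realistic |z|. Exact score ties are broken
#' toward `normal`, then `decreased`.
#'
#' @param z Numeric vector of z-scores for the probes of one chromosome,
#'   in genomic order.
#' @param params An [hmm_params()] object.
#' @return A list of class `state_path` with elements `states` (character
#'   vector, one of [copy_states()] per probe) and `log_score` (log joint
#'   probability of the decoded path and the data).
#' @export
viterbi_decode <- function(z, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  n <- length(z)
  states <- copy_states()
  if (n == 0) {
    return(structure(list(states = character(0), log_score = 0),
                     class = "state_path"))
  }
  if (anyNA(z) || any(!is.finite(z))) {
    rlang::abort("z values must be finite.")
  }
  # emission log-densities, n x 3
  emit <- vapply(states, function(s) {
    stats::dnorm(z, params$means[s], params$sds[s], log = TRUE)
  }, numeric(n))
  emit <- matrix(emit, nrow = n)
  log_trans <- log(params$transition)
  log_init <- log(params$initial_probs)
  # tie preference: normal beats decreased beats increased
  pref <- c(decreased = 2L, normal = 1L, increased = 3L)[states]

  pick <- function(scores) {
    best <- which(scores == max(scores))
    best[which.min(pref[best])]
  }

  delta <- matrix(-Inf, n, 3)
  psi <- matrix(NA_integer_, n, 3)
  delta[1, ] <- log_init + emit[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in 1:3) {
        cand <- delta[t - 1, ] + log_trans[, j]
        i <- pick(cand)
        psi[t, j] <- i
        delta[t, j] <- cand[i] + emit[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- pick(delta[n, ])
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  structure(list(states = states[path], log_score = max(delta[n, ])),
            class = "state_path")
}
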