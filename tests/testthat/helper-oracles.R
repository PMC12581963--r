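# Independent reference implementations used as oracles.

# Straightforward sample-by-sample auto-adjusting-sensitivity walker; the
# package implementation is chunk-vectorized, this one is not.
brute_sense_events <- function(x, fs, p) {
  n <- length(x)
  nb <- round(p$blank_ms / 1000 * fs)
  tau <- p$decay_tau_ms / 1000 * fs
  fl <- p$sensitivity_floor_mv
  ev <- integer(0)
  thr0 <- fl
  dstart <- 1
  i <- 1
  while (i <= n) {
    thr <- fl + (thr0 - fl) * exp(-max(0, i - dstart) / tau)
    if (x[i] >= thr) {
      ev <- c(ev, i)
      peak <- max(x[i:min(n, i + nb)])
      thr0 <- max(min(p$peak_fraction * peak, p$max_threshold_mv), fl)
      dstart <- i + nb
      i <- i + nb + 1
    } else {
      i <- i + 1
    }
  }
  (ev - 1) / fs
}

# Analytic P(X < a, Y < b) for a bivariate normal, by integrating the
# conditional normal CDF against the marginal density.
bvn_rect_prob <- function(mu, S, a, b) {
  s1 <- sqrt(S[1, 1]); s2 <- sqrt(S[2, 2])
  rho <- S[1, 2] / (s1 * s2)
  f <- function(x) stats::dnorm(x, mu[1], s1) *
    stats::pnorm((b - mu[2] - rho * s2 / s1 * (x - mu[1])) /
                   (s2 * sqrt(1 - rho^2)))
  stats::integrate(f, -Inf, a)$value
}

# Small calibrated episode library shared by the slower tests.
small_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_episode_library(12, c(0.15, 1.0),
                                                           seed = 11)
    cache
  }
})
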