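# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive implementations, kept separate from the
# package's computation paths.

# direct power-mean evaluation of the EUD sum (no scaling tricks)
eud_oracle <- function(v, d, a) {
  v <- v / sum(v)
  sum(v * d^a)^(1 / a)
}

# exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (midranks for ties); feasible for n <= ~12
wsr_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# random valid cumulative DVH on a fixed dose axis
random_cdvh <- function(name = "S", n_pts = 60, dmax = 85) {
  d <- c(0, sort(runif(n_pts - 2, 0.5, dmax)), dmax + runif(1, 0.5, 3))
  drops <- diff(c(1, sort(runif(n_pts - 1, 0, 1), decreasing = TRUE) *
                    runif(1, 0.2, 1), 0))
  f <- 1 + cumsum(c(0, drops[-1]))
  f <- pmax(0, pmin(1, cummin(f)))
  cumulative_dvh(name, d, f, total_volume = runif(1, 20, 300))
}

# random differential DVH with strictly positive doses
random_ddvh <- function(name = "S", n_bins = 40, dmin = 1, dmax = 90) {
  d <- sort(runif(n_bins, dmin, dmax))
  v <- runif(n_bins)
  differential_dvh(name, d, v / sum(v))
}

# cumulative step curve for a structure receiving a single uniform dose
uniform_cdvh <- function(dose, name = "S", volume = 100) {
  cumulative_dvh(name, c(0, dose, dose + 1e-9), c(1, 1, 0), volume)
}
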