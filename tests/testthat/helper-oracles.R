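# Independent oracles used across the suite.

# Fine-grid Riemann integration of the positive part of the piecewise-linear
# deficit signal. The grid includes the observation knots, so between knots
# the interpolant is exactly linear and only subintervals containing a
# zero-crossing contribute discretisation error.
riemann_twa_deficit <- function(t, map, pre, step = 0.01) {
  d <- 100 * (pre - map) / pre
  if (length(t) == 1) return(max(0, d))
  f <- stats::approxfun(t, d)
  grid <- sort(unique(c(seq(min(t), max(t), by = step), t)))
  v <- f(grid)
  # refine sign changes by generic bisection so the grid straddles no crossing
  flips <- which(v[-1] * v[-length(v)] < 0)
  roots <- vapply(flips, function(i) {
    stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-12)$root
  }, numeric(1))
  grid <- sort(unique(c(grid, roots)))
  vals <- pmax(0, f(grid))
  dt <- diff(grid)
  sum((vals[-length(vals)] + vals[-1]) / 2 * dt) / (max(t) - min(t))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value for a
# 2x2 table (events a/c, non-events b/d), via binomial coefficients.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Random 4-hourly MAP series with occasional gaps, for property tests.
random_map_series <- function(pre = 95) {
  n <- sample(3:30, 1)
  t <- cumsum(c(0, sample(c(4, 4, 4, 8, 12), n - 1, replace = TRUE)))
  map <- stats::rnorm(n, pre - sample(-5:25, 1), 8)
  list(t = t, map = pmin(195, pmax(25, map)), pre = pre)
}

toy_creatinine <- function(baseline = 80, at_rand = 100,
                           peaks = c(110, 130, 150), days = seq_along(peaks),
                           rrt_day = NA_integer_, death_day = NA_integer_,
                           discharge_day = NA_integer_) {
  creatinine_series(baseline, at_rand, peaks, days,
                    rrt_start_day = rrt_day, death_day = death_day,
                    icu_discharge_day = discharge_day)
}
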