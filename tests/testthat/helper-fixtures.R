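# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# small but fully featured synthetic system: 2 stations, 20 years,
# 21 members, 46-day range, known +2 degC tmax bias
small_system <- function() {
  if (is.null(.fixture_env$sys)) {
    cfg <- synth_config(seed = 42, n_stations = 2, n_years = 20,
                        n_members = 21, max_lead = 46)
    .fixture_env$cfg <- cfg
    .fixture_env$sys <- simulate_system(cfg, inits_per_year = 2)
  }
  list(cfg = .fixture_env$cfg, sys = .fixture_env$sys)
}

small_store <- function() {
  if (is.null(.fixture_env$store)) {
    fx <- small_system()
    .fixture_env$store <- fit_eqm_store(fx$sys$observations,
                                        fx$sys$hindcast)
  }
  .fixture_env$store
}

# exact CRPS by piecewise integration of the squared difference between the
# empirical member CDF and the observation step function; independent of
# the kernel form
crps_integral_oracle <- function(members, obs) {
  pts <- sort(unique(c(members, obs)))
  if (length(pts) == 1) return(0)
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    a <- pts[i]
    f_val <- mean(members <= a)
    h_val <- as.numeric(a >= obs)
    total <- total + (f_val - h_val)^2 * (pts[i + 1] - a)
  }
  total
}

# independent bisection for the psychrometer balance
psychro_bisect_oracle <- function(ta, td, pressure = 1013.25, iters = 60) {
  e <- 6.1121 * exp(17.502 * td / (240.97 + td))
  gamma <- 6.67e-4 * pressure
  f <- function(tw) 6.1121 * exp(17.502 * tw / (240.97 + tw)) - e -
    gamma * (ta - tw)
  lo <- td; hi <- ta
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
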