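## shared fixtures: the study's standard parameter set
preset_spring <- function(k = 1e6, ell0 = 0.32) spring_params(k, ell0)
preset_langevin <- function() langevin_params(M = 1, D = 1, gamma = 10)
preset_bath <- function() short_range_bath_params(r0 = 0.08, mu = 1e3,
                                                  gamma = 10, D = 1)

## CDF of the Maxwell speed distribution with per-component sd sigma
maxwell_speed_cdf <- function(s, sigma) {
  x <- s / sigma
  pchisq(x^2, df = 3)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
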