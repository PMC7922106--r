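# shared fixtures: parameter sets and small panels built in code

example_params <- function(rise_mid = 160, fall_mid = 250,
                           rise_steep = 0.15, fall_steep = 0.12,
                           base = 0.2, amplitude = 0.6) {
  list(base = base, amplitude = amplitude,
       rise_mid = rise_mid, rise_steep = rise_steep,
       fall_mid = fall_mid, fall_steep = fall_steep)
}

# single exact logistic branch NDVI(t) = c/(1 + exp(a + b t)) + d
logistic_branch_values <- function(t, a, b, c, d) c / (1 + exp(a + b * t)) + d

tiny_config <- function(...) {
  sim_config(n_counties = 4, pixels_per_county = 3, years = 2014:2016,
             seed = 42, ...)
}

noise_free_config <- function(n_counties = 12, years = 2015, seed = 5, ...) {
  sim_config(n_counties = n_counties, pixels_per_county = 3, years = years,
             noise_sd = 0, dropout_prob = 0, seed = seed, ...)
}

# a clean single-season "ramp" series: linear rise then linear fall
ramp_series <- function(d1 = 120, dpk = 190, d2 = 260, lo = 0.2, hi = 0.9) {
  day <- d1:d2
  ndvi <- ifelse(day <= dpk,
                 lo + (hi - lo) * (day - d1) / (dpk - d1),
                 hi - (hi - lo) * (day - dpk) / (d2 - dpk))
  data.frame(adj_day = day, ndvi = ndvi)
}
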