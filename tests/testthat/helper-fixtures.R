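# Shared fixtures: small populations and model-exact binned profiles.

fixture_shape <- function() gradient_shape(735, 1.45)
fixture_resp_g <- function() response_params(1, 1, 0.1)
fixture_resp_m <- function() response_params(3, 25, 5)

small_pop <- function(n = 1500) {
  population_config(n_receivers = n, n_emitters = 0)
}

# binned profiles whose means are exactly the model evaluated at bin
# centers (no sampling, no binning bias): the self-consistency input
exact_profiles <- function(shape = fixture_shape(),
                           resp_g = fixture_resp_g(),
                           resp_m = fixture_resp_m(),
                           width = 100, x_range = c(-2700, 2700)) {
  ctr <- seq(x_range[1] + width / 2, x_range[2] - width / 2, by = width)
  list(
    gfp = binned_profile(ctr, observed_response(ctr, shape, resp_g),
                         sem = 1, count = 100L, width = width, channel = "gfp"),
    len = binned_profile(ctr, observed_response(ctr, shape, resp_m),
                         sem = 1, count = 100L, width = width, channel = "length")
  )
}

# physical parameters with a given decay length and unit far-field value
phys_with_lambda <- function(lambda, D = 300) {
  physical_params(D = D, r = D / lambda, rho_alpha = 1, rho_A = 1,
                  Omega = D / lambda)
}
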