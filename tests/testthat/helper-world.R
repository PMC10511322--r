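# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

get_tiny_world <- function() cached("tiny", tiny_world(seed = 42))

# a noise-free, bias-free tiny world (degenerate limits)
get_clean_world <- function() cached("clean", tiny_world(
  seed = 43, bias_amplitude = 0, chem_noise_sd = 0, obs_noise_sd = 0))

# small grid helper for unit tests
test_grid <- function(nlat = 4, nlon = 5, dlat = 0.5, dlon = 0.5,
                      lat0 = 10.25, lon0 = 20.25)
  grid_spec(lat0, lon0, dlat, dlon, nlat, nlon)

random_field <- function(grid, n_days = 3, seed = 1,
                         start = as.Date("2018-01-01")) {
  set.seed(seed)
  daily_field(grid, start + seq_len(n_days) - 1,
              array(stats::runif(n_days * grid$nlat * grid$nlon, 1, 50),
                    c(n_days, grid$nlat, grid$nlon)))
}
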