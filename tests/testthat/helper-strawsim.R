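# quick constructors and a cached default-scenario simulation shared by tests

make_env <- function(temp, sr = rep(5, length(temp)),
                     start = as.Date("2021-09-18")) {
  environment_series(start + seq_along(temp) - 1L, temp, sr)
}

# the default synthetic forcing-culture season, simulated once per test run
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- scenario_spec(seed = 0)
      cache <<- simulate_season(generate_climate(spec),
                                generate_flowering_schedule(spec),
                                generate_lai_trajectory(spec, "lai"))
    }
    cache
  }
})

default_spec <- function(...) scenario_spec(...)
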