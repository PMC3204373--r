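# memoized training runs shared across acceptance tests: each configuration
# is simulated once per test session
.run_cache <- new.env(parent = emptyenv())

cached_runs <- function(key, seeds, make_cfg) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, lapply(seeds, function(s) run_training(make_cfg(s))),
           envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

runs_nh5 <- function(seeds = 1:6) {
  cached_runs("nh5", seeds, function(s) {
    experiment_config(n_hidden = 5, seed = s)
  })
}

runs_nh7 <- function(seeds = 1:8) {
  cached_runs("nh7", seeds, function(s) {
    experiment_config(n_hidden = 7, seed = s)
  })
}

runs_w4 <- function(seeds = 1:6) {
  cached_runs("w4", seeds, function(s) {
    experiment_config(n_hidden = 7, seed = s, window_ms = 4, episode_ms = 160)
  })
}

runs_w7 <- function(seeds = 1:6) {
  cached_runs("w7", seeds, function(s) {
    experiment_config(n_hidden = 7, seed = s, window_ms = 7, episode_ms = 280)
  })
}

runs_nh27 <- function(seeds = 1:3) {
  cached_runs("nh27", seeds, function(s) {
    experiment_config(n_hidden = 27, seed = s)
  })
}

runs_eta0 <- function(seeds = 1:8) {
  cached_runs("eta0", seeds, function(s) {
    experiment_config(n_hidden = 7, seed = s,
                      learning = learning_config(eta = 0))
  })
}

last50 <- function(run, col) mean(utils::tail(run$episodes[[col]], 50))
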