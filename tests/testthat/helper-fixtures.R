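# Shared fixtures: one default config and chirp, plus lazily-built cached
# objects so expensive synthesis is done once per test run.
test_cfg <- sonar_config()
test_chirp <- generate_chirp(test_cfg)

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# A hand-built correlation trace with Gaussian bumps at the given lags
# (seconds) and amplitudes, for exercising the peak picker in isolation.
fake_trace <- function(lags_s, amps, fs = 250e3, n = 8750, width = 5) {
  env <- numeric(n)
  for (k in seq_along(lags_s)) {
    i0 <- round(lags_s[k] * fs)
    idx <- pmax(1, pmin(n, i0 + (-30:30)))
    env[idx] <- pmax(env[idx], amps[k] * exp(-((idx - i0)^2) / (2 * width^2)))
  }
  list(env = env, raw = env, lag_s = (seq_len(n) - 1) / fs, ref = 1,
       blank_n = 0, norm = 1, sample_rate = fs)
}

# An ensemble whose six networks ignore their input and emit fixed sigmoid
# outputs (all weights zero, output bias = logit of the target), for
# exercising the voting logic deterministically.
const_ensemble <- function(sigmoids) {
  stopifnot(length(sigmoids) == 6)
  nets <- lapply(sigmoids, function(p) {
    net <- batsonar:::mlp_init(seed = 1)
    for (i in seq_along(net$layers)) {
      net$layers[[i]]$W[] <- 0
      net$layers[[i]]$b[] <- 1  # keep ReLU layers active
    }
    net$layers[[length(net$layers)]]$b <- log(p / (1 - p))
    net
  })
  scalers <- replicate(6, list(mu = numeric(483), sd = rep(1, 483)),
                       simplify = FALSE)
  structure(list(nets = nets, scalers = scalers,
                 signal_names = paste0("s", 1:6),
                 recipe = list()),
            class = "echo_ensemble")
}
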