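# Shared fixtures, generated in code. Unit tests run at a 512 Hz sampling
# rate and reduced trial counts to keep the suite fast; task structure
# (conditions, delays, cue timing) always uses the configured defaults.

quiet_cfg <- function(n_channels = 4, n_trials = 30, fs = 512, seed = 11L, ...) {
  sim_config(n_participants = 1, n_channels = n_channels, n_trials = n_trials,
             sampling_rate = fs, seed = seed, ...)
}

# lognormal (positive) pure-noise tensor: no label structure
rand_tensor <- function(ns = 4, nb = 1, nt = 40, nw = 10, seed = 1,
                        step = 50, window = 400) {
  set.seed(seed)
  v <- array(exp(rnorm(ns * nb * nt * nw, sd = 0.5)), c(ns, nb, nt, nw))
  power_tensor(v, seq(0, by = step, length.out = nw) + window / 2,
               window, step, "cue1")
}

# tensor with a class mean shift `delta` at given sites/windows (band 1)
shift_tensor <- function(z, ns = 4, nw = 10, sites = 1, windows = 1:2,
                         delta = 2, seed = 1, step = 50, window = 400) {
  set.seed(seed)
  nt <- length(z)
  v <- array(exp(rnorm(ns * nt * nw, sd = 0.5)), c(ns, 1, nt, nw))
  for (s in sites) for (w in windows) v[s, 1, z, w] <- v[s, 1, z, w] + delta
  power_tensor(v, seq(0, by = step, length.out = nw) + window / 2,
               window, step, "cue1")
}

# one small shared synthetic participant, reused across behavior tests
behavior_corpus <- local({
  corpus <- NULL
  function() {
    if (is.null(corpus)) {
      cfg <- quiet_cfg(n_channels = 1, n_trials = 60, seed = 21L,
                       effects = list())
      corpus <<- list(cfg = cfg, sim = simulate_participant(cfg, 21L))
    }
    corpus
  }
})
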