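# Shared fixtures: memoised reference simulations and crafted trials.

.ref_cache <- new.env(parent = emptyenv())

ref_trialset <- function(cond, n_pairs = 6, trials_per_pair = 25, seed = 1) {
  key <- paste(cond, n_pairs, trials_per_pair, seed, sep = "_")
  if (is.null(.ref_cache[[key]]))
    .ref_cache[[key]] <- simulate_trialset(
      reference_configs(cond, n_pairs = n_pairs,
                        trials_per_pair = trials_per_pair, seed = seed))
  .ref_cache[[key]]
}

# straight-line trial: both agents at constant velocity, inside the pitch
straight_trial <- function(n = 121, step = c(0.03, -0.03), rate = 120,
                           id = "straight") {
  i <- seq_len(n) - 1
  pa <- cbind(0.5 + i * step[1], 5 + i * step[2])
  pd <- cbind(-0.5 + i * step[1], -2 + i * step[2])
  chase_trial(id, pa, pd, condition = "square", sample_rate = rate,
              outcome = "timeout")
}

# zigzag trial: the agent's x velocity flips sign at the given sample
# indices (1-based velocity sample index); y drifts slowly downward
zigzag_trial <- function(flips_a, flips_d, n = 240, rate = 120,
                         id = "zigzag", step = 0.02) {
  mk <- function(flips) {
    s <- numeric(n - 1)
    cur <- 1
    for (i in seq_len(n - 1)) {
      if (i %in% flips) cur <- -cur
      s[i] <- cur
    }
    x <- cumsum(c(0, s * step))
    x - mean(x)   # keep inside the pitch
  }
  ya <- seq(4, 2, length.out = n)
  yd <- seq(0, -1, length.out = n)
  chase_trial(id, cbind(mk(flips_a), ya), cbind(mk(flips_d), yd),
              condition = "square", sample_rate = rate, outcome = "timeout")
}

# brute-force direction-change oracle: explicit scan with zero-inheritance
oracle_change_indices <- function(vx) {
  events <- integer(0)
  last <- 0
  for (i in seq_along(vx)) {
    s <- sign(vx[i])
    if (s != 0) {
      if (last != 0 && s != last) events <- c(events, i)
      last <- s
    }
  }
  events
}
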