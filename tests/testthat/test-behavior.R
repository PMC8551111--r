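# behavioral statistics: zero-crossing detection, response matching,
# entropy, spatial/interval/saturation analyses

make_vx_trial <- function(vx, rate = 120) {
  x <- cumsum(c(0, vx)); x <- x - mean(x)
  y <- seq(2, 1, length.out = length(x))
  chase_trial("vx", cbind(x, y), cbind(x * 0, y - 2), condition = "square",
              sample_rate = rate, outcome = "timeout")
}

test_that("direction changes are strict sign flips with zero inheritance", {
  ev <- detect_direction_changes(make_vx_trial(c(1, 1, -1, -1) * 0.02), "attacker")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$sign, "pos_to_neg")
  expect_equal(ev$sample_index, 3)
  expect_equal(ev$time, 2 / 120)

  expect_equal(nrow(detect_direction_changes(
    make_vx_trial(c(1, 0, 1) * 0.02), "attacker")), 0)   # touch, no cross
  expect_equal(nrow(detect_direction_changes(
    make_vx_trial(c(0, 0, 0)), "attacker")), 0)          # all zero

  ev3 <- detect_direction_changes(make_vx_trial(c(1, -1, 1, -1) * 0.02), "attacker")
  expect_equal(nrow(ev3), 3)
  expect_equal(ev3$sign, c("pos_to_neg", "neg_to_pos", "pos_to_neg"))

  # crossing through zero is still one event
  evz <- detect_direction_changes(make_vx_trial(c(1, 0, -1) * 0.02), "attacker")
  expect_equal(nrow(evz), 1)
})

test_that("detection matches the brute-force sign-scan oracle", {
  set.seed(42)
  for (k in 1:1000) {
    vx <- sample(c(-0.02, 0, 0.02), 25, replace = TRUE)
    got <- chasepred:::detect_changes_vx(vx, 120)$sample_index
    expect_identical(got, oracle_change_indices(vx))
  }
})

test_that("consecutive events of one agent alternate in sign", {
  ts <- ref_trialset("square")
  ev <- detect_changes_trialset(ts, "attacker")
  for (id in unique(ev$trial_id)[1:30]) {
    s <- ev$sign[ev$trial_id == id]
    if (length(s) > 1) expect_true(all(s[-1] != s[-length(s)]))
  }
})

test_that("response matching is greedy, sign-aware and bounded at 500 ms", {
  ae <- data.frame(trial_id = "t", agent = "attacker",
                   time = c(1.0, 2.0, 3.0),
                   sign = c("pos_to_neg", "pos_to_neg", "neg_to_pos"),
                   x_at_change = 0, y_at_change = 0, sample_index = 1:3)
  de <- data.frame(trial_id = "t", agent = "defender",
                   time = c(1.12, 2.6, 3.05),
                   sign = c("pos_to_neg", "pos_to_neg", "pos_to_neg"),
                   x_at_change = 0, y_at_change = 0, sample_index = 1:3)
  rec <- match_responses(ae, de)
  # 1.0 -> 1.12 matches (120 ms, short); 2.0 -> 2.6 is 600 ms (dropped);
  # 3.0 is neg_to_pos and finds no same-sign partner
  expect_equal(nrow(rec), 1)
  expect_equal(rec$latency_ms, 120)
  expect_true(rec$is_short)

  # one-to-one: a single defender event cannot serve two attacker events
  ae2 <- ae[1:2, ]; ae2$time <- c(1.0, 1.1)
  de2 <- de[1, , drop = FALSE]; de2$time <- 1.2
  expect_equal(nrow(match_responses(ae2, de2)), 1)
})

test_that("short-latency proportion counts below 150 ms", {
  rec <- data.frame(latency_ms = c(100, 200, 300, 120),
                    is_short = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(short_latency_proportion(rec), 0.5)
  rec2 <- data.frame(latency_ms = c(150, 200), is_short = c(FALSE, FALSE))
  expect_equal(short_latency_proportion(rec2), 0)
  expect_warning(p <- short_latency_proportion(rec[0, ]), "undefined")
  expect_true(is.na(p))
})

test_that("heading-change histogram bins signed wrapped differences", {
  ts1 <- trialset(list(straight_trial()))
  h <- heading_change_histogram(ts1, "attacker")
  expect_equal(sum(h$rel_freq), 1)
  # all mass in the bins containing 0 (floating-point deltas straddle it)
  mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
  expect_equal(sum(h$counts[abs(mids) < h$bin_width]), sum(h$counts))

  # single 90-degree left (counterclockwise) turn at the analysis rate
  pa <- rbind(t(sapply(0:5, function(i) c(i * 0.1, 0))),
              t(sapply(1:5, function(i) c(0.5, i * 0.1))))
  tr <- chase_trial("turn", pa, pa - 3, condition = "square",
                    sample_rate = 20, outcome = "timeout")
  h2 <- heading_change_histogram(trialset(list(tr)), "attacker")
  ix <- which(h2$counts > 0 & h2$breaks[-length(h2$breaks)] != -5)
  expect_equal(h2$breaks[ix], 85)     # the (85, 90] bin
  expect_equal(h2$counts[ix], 1)
})

test_that("entropy has the textbook values and bounds", {
  expect_equal(entropy(c(10, 0, 0)), 0)
  expect_equal(entropy(rep(3, 72)), log2(72))
  expect_equal(entropy(c(5, 5)), 1)
  expect_warning(e <- entropy(numeric(3)), "zero")
  expect_true(is.na(e))
  set.seed(1)
  for (k in 1:50) {
    h <- rpois(72, 2)
    if (sum(h) == 0) next
    e <- entropy(h)
    expect_gte(e, 0); expect_lte(e, log2(72))
  }
})

test_that("column stats flag unvisited columns and divide counts by time", {
  # agent confined to x > 0 (columns 5..8 of the square pitch)
  n <- 241
  x <- 3.75 + 2.9 * sin(seq(0, 6 * pi, length.out = n))
  tr <- chase_trial("col", cbind(x, seq(4, -4, length.out = n)),
                    cbind(x * 0, seq(0, -5, length.out = n)),
                    condition = "square", sample_rate = 120,
                    outcome = "timeout")
  cs <- column_stats(trialset(list(tr)), "attacker")
  expect_equal(nrow(cs), 8)
  expect_true(all(cs$missing[1:4]))
  expect_true(all(!cs$missing[5:8]))
  expect_true(all(is.na(cs$freq_per_s[cs$missing])))
  occupied <- which(!cs$missing)
  expect_equal(cs$freq_per_s[occupied],
               cs$n_changes[occupied] / cs$time_spent[occupied])
  expect_equal(sum(cs$time_spent), n / 120)
})

test_that("switch frequency per time is flat across occupied columns", {
  for (cond in c("narrow", "square", "wide")) {
    cs <- column_stats(ref_trialset(cond), "attacker")
    occ <- cs$time_spent / sum(cs$time_spent)
    f <- cs$freq_per_s[occ >= 0.05]   # columns with real occupancy
    expect_gt(length(f), 1)
    expect_lt(sd(f) / mean(f), 0.3,
              label = paste("column CV in", cond))
  }
})

test_that("change ratio is defender changes over attacker changes", {
  tr <- zigzag_trial(flips_a = c(40, 80, 120, 160, 200, 210, 220, 230),
                     flips_d = c(30, 50, 70, 90, 110, 130, 150, 170, 190, 225))
  cr <- change_ratio(trialset(list(tr)))
  expect_equal(cr$per_participant$n_attacker, 8)
  expect_equal(cr$per_participant$n_defender, 10)
  expect_equal(cr$mean, 1.25)
})

test_that("interval analysis: survival, censoring-aware tail MLE", {
  ev <- data.frame(trial_id = "t", time = seq(0, 10, by = 1))
  ia <- interval_analysis(ev)
  expect_true(all(ia$intervals == 1))
  expect_true(all(ia$intervals >= 0))
  expect_equal(ia$survival$S[nrow(ia$survival)], 0)

  # oracle: exact exponential intervals -> MLE recovers the rate
  set.seed(3)
  rate <- 1.5
  iv <- 0.4 + rexp(5000, rate)
  times <- cumsum(iv)
  ev2 <- data.frame(trial_id = "long", time = c(0, times))
  ia2 <- interval_analysis(ev2, tail_start = 0.5)
  expect_lt(abs(ia2$tail_rate - rate) / rate, 0.05)
  expect_false(ia2$low_confidence)

  # censoring: cutting the observation short must not bias the rate up
  ev3 <- ev2[ev2$time < 500, ]
  ends <- c(long = 500)
  ia3 <- interval_analysis(ev3, tail_start = 0.5, trial_ends = ends)
  expect_lt(abs(ia3$tail_rate - rate) / rate, 0.10)

  # low-confidence flag
  ia4 <- interval_analysis(data.frame(trial_id = "t", time = c(0, 0.1, 0.9)))
  expect_true(ia4$low_confidence)
})

test_that("speed saturation is 0 for a holding agent and 1 at the cap", {
  n <- 121
  pa <- cbind(seq(0, 5.5 * (n - 1) / 120, length.out = n) - 2, rep(2, n))
  pd <- matrix(rep(c(0, -2), each = n), ncol = 2)
  tr <- chase_trial("sat", pa, pd, condition = "square", sample_rate = 120,
                    outcome = "timeout")
  sat <- speed_saturation(trialset(list(tr)))
  expect_equal(sat$prop_above[sat$agent == "attacker"], 1)
  expect_equal(sat$prop_above[sat$agent == "defender"], 0)
})

test_that("distance-binned change counts are conserved and near-flat", {
  ts <- ref_trialset("square")
  db <- distance_binned_changes(ts, "attacker", bin_width = 0.5)
  ev <- detect_changes_trialset(ts, "attacker")
  expect_equal(sum(db$n_changes), nrow(ev))
  expect_equal(sum(db$time_spent),
               sum(ts$manifest$n_samples) / 120, tolerance = 1e-6)
  occ <- db$time_spent / sum(db$time_spent)
  f <- db$freq_per_s[occ >= 0.05]
  expect_lt(sd(f) / mean(f), 0.4)
})

test_that("single-distance events occupy a single bin", {
  n <- 61
  pa <- cbind(cumsum(c(0, rep(c(0.02, -0.02), length.out = n - 1))), rep(3, n))
  pd <- pa - rep(c(0, 3), each = n)   # constant distance 3
  tr <- chase_trial("d3", pa, pd, condition = "square", sample_rate = 120,
                    outcome = "timeout")
  db <- distance_binned_changes(trialset(list(tr)), "attacker", bin_width = 0.1)
  expect_equal(sum(db$n_changes > 0), 1)
})
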