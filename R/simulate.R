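# Agent-based chase-escape simulator.
#
# The simulated world mirrors the recorded task: two speed-capped disks on a
# bounded pitch, the attacker trying to reach the end line (Y = -height/2),
# the defender trying to touch it first. Attacker kinematics are
# heading-based (joystick tilt maps to velocity in the task, so velocity
# control is the faithful abstraction): a unit heading composed of a
# persistent horizontal sign and a constant pull toward the end line,
# reversed by a memoryless Bernoulli hazard outside a hard refractory
# window, and forced away from the side walls inside a margin. The defender
# pursues the linearly extrapolated attacker position as perceived one
# reaction delay earlier, with occasional anticipatory reversals injected at
# short (< 150 ms) latency.

#' Attacker policy parameters
#'
#' @param switch_hazard probability per second of a horizontal direction
#'   reversal outside the refractory window (memoryless Bernoulli per step).
#' @param refractory suppression window in s after each reversal; produces
#'   the secondary inter-switch interval mode near 0.5 s.
#' @param goal_bias dimensionless extra pull toward the end line mixed into
#'   the aim-point heading; larger values give steeper, faster descents.
#' @param boundary_margin distance in cm from a side wall at which the
#'   horizontal sign is forced inward.
#' @param speed_fraction fraction of the 5.5 cm/s cap the attacker moves at.
#' @param heading_noise_sd per-step angular noise in degrees (small, so the
#'   horizontal velocity sign never jitters across zero).
#' @param reach lateral overshoot in cm of the aim point beyond the side
#'   wall: the attacker runs toward `(sign * (width/2 + reach), -height/2)`,
#'   so on wider pitches runs are shallower and trials longer.
#' @param descent maximum downward fraction of the unit heading (caps the
#'   vertical approach speed; smaller values mean more lateral juking and
#'   longer trials).
#' @param turn_spread fraction of the reachable half-width over which the
#'   turn-back point of an outward run is randomized (each run turns at a
#'   fresh uniform draw from the outer `turn_spread` fraction of the
#'   half-width, down to the hard wall margin). 0 = always turn exactly at
#'   the wall margin; positive values spread wall turns over the pitch the
#'   way human attackers do, keeping the per-column switch frequency flat.
#' @param dwell_mean mean duration in s of the committed dive the attacker
#'   makes at a turn point before reversing (it rides nearly straight down,
#'   joystick pinned). Dives accrue occupancy near the turn regions without
#'   switches, which is what keeps switch frequency per unit time flat
#'   across the pitch. 0 disables dwelling.
#' @return list of class `attacker_policy`.
#' @export
attacker_policy <- function(switch_hazard = 1.2, refractory = 0.45,
                            goal_bias = 0.4, boundary_margin = 0.8,
                            speed_fraction = 0.95, heading_noise_sd = 6,
                            reach = 3, descent = 0.45, turn_spread = 0.6,
                            dwell_mean = 0.5) {
  stopifnot(descent > 0, descent <= 1, turn_spread >= 0, turn_spread < 1,
            dwell_mean >= 0)
  stopifnot(switch_hazard >= 0, refractory >= 0,
            speed_fraction > 0, speed_fraction <= 1)
  structure(list(switch_hazard = switch_hazard, refractory = refractory,
                 goal_bias = goal_bias, boundary_margin = boundary_margin,
                 speed_fraction = speed_fraction,
                 heading_noise_sd = heading_noise_sd, reach = reach,
                 descent = descent, turn_spread = turn_spread,
                 dwell_mean = dwell_mean),
            class = "attacker_policy")
}

#' Defender policy parameters
#'
#' The defender plays goalkeeper: laterally it matches the attacker's
#' horizontal velocity as perceived one reaction delay ago (plus a
#' proportional correction toward the extrapolated attacker X), vertically
#' it guards a buffer just below the attacker, retreating as the attacker
#' advances, and it lunges upward to catch once laterally aligned and
#' vertically close.
#'
#' @param reaction_delay sensorimotor delay in s (the defender acts on
#'   attacker state perceived this long ago; ~0.25 s).
#' @param anticipation_prob probability, per attacker reversal, that the
#'   defender pre-empts it with a short-latency (< 150 ms) reversal of its
#'   own. A stand-in for anticipatory (nonlinearly extrapolated) responses,
#'   not a cognitive model.
#' @param noise_sd per-step angular noise on the defender velocity, degrees.
#' @param false_alarm_rate rate (1/s) of spurious anticipatory reversals:
#'   short, self-corrected flips not caused by any attacker reversal. These
#'   are what push the defender/attacker change ratio above 1.
#' @param guard_dist vertical buffer in cm the defender keeps below the
#'   (extrapolated) attacker while guarding.
#' @param track_gain proportional gain (1/s) of the lateral correction
#'   toward the extrapolated attacker X position.
#' @param lunge_x,lunge_y lateral / vertical alignment thresholds in cm at
#'   which the defender lunges at the attacker instead of guarding.
#' @return list of class `defender_policy`.
#' @export
defender_policy <- function(reaction_delay = 0.25, anticipation_prob = 0.15,
                            noise_sd = 4, false_alarm_rate = 0.15,
                            guard_dist = 1.4, track_gain = 0.9,
                            lunge_x = 0.8, lunge_y = 2.5) {
  stopifnot(reaction_delay >= 0, anticipation_prob >= 0,
            anticipation_prob <= 1, false_alarm_rate >= 0)
  structure(list(reaction_delay = reaction_delay,
                 anticipation_prob = anticipation_prob,
                 noise_sd = noise_sd, false_alarm_rate = false_alarm_rate,
                 guard_dist = guard_dist,
                 track_gain = track_gain, lunge_x = lunge_x,
                 lunge_y = lunge_y),
            class = "defender_policy")
}

#' Simulation configuration
#'
#' @param condition pitch condition.
#' @param n_pairs number of participant pairs (defender participants);
#'   default 12 as in the emulated data set.
#' @param trials_per_pair trials per pair (default 50, one block).
#' @param seed integer seed; a fixed seed makes the whole trial set
#'   bit-reproducible.
#' @param attacker an [attacker_policy()].
#' @param defender a [defender_policy()].
#' @param sample_rate recording rate in Hz (120).
#' @param max_trial_duration hard stop in s; timeouts are labelled
#'   `"timeout"` (censored) rather than forced into a task outcome.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(condition = c("narrow", "square", "wide"),
                       n_pairs = 12L, trials_per_pair = 50L, seed = 1L,
                       attacker = attacker_policy(),
                       defender = defender_policy(),
                       sample_rate = 120, max_trial_duration = 20) {
  condition <- match.arg(condition)
  stopifnot(n_pairs >= 1, trials_per_pair >= 1, max_trial_duration > 0)
  structure(list(condition = condition, n_pairs = as.integer(n_pairs),
                 trials_per_pair = as.integer(trials_per_pair),
                 seed = as.integer(seed), attacker = attacker,
                 defender = defender, sample_rate = sample_rate,
                 max_trial_duration = max_trial_duration),
            class = "sim_config")
}

rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

#' Simulate a single chase-escape trial
#'
#' Per-step update at `sample_rate` Hz. The trial ends at catch (center
#' distance <= disk diameter, i.e. outer edges touching for two 1 cm disks),
#' end-line crossing, attacker out of bounds, or the time limit.
#'
#' Uses the current R RNG stream; call `set.seed()` first (or use
#' [simulate_trialset()], which seeds once) for reproducibility.
#'
#' @param cfg a [sim_config()].
#' @param trial_id,participant_pair,defender_participant identifiers.
#' @param seed optional integer; if given, seeds the RNG before simulating.
#' @return a `chase_trial`.
#' @export
simulate_trial <- function(cfg, trial_id = "sim_001",
                           participant_pair = "pair01",
                           defender_participant = "P01", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  geom <- pitch_geometry(cfg$condition)
  fs <- cfg$sample_rate; dt <- 1 / fs
  hw <- geom$width / 2; hh <- geom$height / 2
  ap <- cfg$attacker; dp <- cfg$defender
  n_max <- as.integer(round(cfg$max_trial_duration * fs)) + 1L

  pa <- matrix(0, n_max, 2); pd <- matrix(0, n_max, 2)
  pa[1, ] <- c(0, hh - 1.0)   # upper middle start, 1 cm inside
  pd[1, ] <- c(0, 0)          # pitch center

  s_a <- sample(c(-1, 1), 1L)            # horizontal sign of attacker heading
  refrac_left <- 0
  va_step <- ap$speed_fraction * geom$max_speed * dt
  gb <- ap$goal_bias
  # angular noise is AR(1) with ~100 ms time constant: slow joystick
  # wander, not per-sample tremor (white noise would jitter the velocity
  # sign back and forth whenever vx sweeps through zero)
  ar <- exp(-dt / 0.1)
  ar_noise <- function(n, sd_deg) {
    if (sd_deg <= 0) return(numeric(n))
    as.numeric(stats::filter(stats::rnorm(n, 0, sd_deg * pi / 180) *
                               sqrt(1 - ar^2), ar, method = "recursive",
                             init = stats::rnorm(1, 0, sd_deg * pi / 180)))
  }
  noise_a <- ar_noise(n_max, ap$heading_noise_sd)
  noise_d <- ar_noise(n_max, dp$noise_sd)
  u_switch <- stats::runif(n_max)
  u_fa <- stats::runif(n_max)
  p_switch <- ap$switch_hazard * dt
  p_fa <- dp$false_alarm_rate * dt
  d_lag <- max(1L, as.integer(round(dp$reaction_delay * fs)))

  # anticipation override: forces the defender's perceived lateral sign
  ant_sign <- 0; ant_from <- Inf; ant_until <- -Inf
  vd_f <- NULL   # low-passed defender velocity command (seeded on step 1)
  wall_at <- hw - ap$boundary_margin
  draw_turn <- function() stats::runif(1, (1 - ap$turn_spread) * wall_at, wall_at)
  x_turn <- draw_turn()
  dwell_until <- -Inf   # while dwelling, the attacker dives nearly straight

  outcome <- "timeout"; n <- n_max
  for (i in seq_len(n_max - 1L)) {
    t_now <- (i - 1L) * dt
    switched <- FALSE
    dwelling <- t_now < dwell_until
    # hazard-driven reversal outside the refractory window (suppressed
    # during a committed dive, which ends in a reversal anyway)
    if (!dwelling && refrac_left <= 0 && u_switch[i] < p_switch) {
      s_a <- -s_a; switched <- TRUE
    }
    # an outward run hitting this run's turn point starts a committed dive
    # (dwell), after which the attacker reverses; the hard wall margin
    # still forces an immediate reversal
    if (!switched && !dwelling && abs(pa[i, 1]) >= x_turn &&
        sign(pa[i, 1]) == s_a) {
      if (ap$dwell_mean > 0) {
        dwell_until <- t_now + stats::rexp(1, 1 / ap$dwell_mean)
        dwelling <- TRUE
      } else {
        s_a <- -s_a; switched <- TRUE
      }
    }
    if (dwelling && t_now >= dwell_until - dt / 2 && !switched) {
      s_a <- -s_a; switched <- TRUE   # dive over: reverse
    }
    if (abs(pa[i, 1]) >= hw - 0.3 && sign(pa[i, 1]) == s_a) {
      s_a <- -s_a; switched <- TRUE   # hard wall: reverse now
    }
    if (switched) {
      refrac_left <- ap$refractory
      dwell_until <- -Inf; dwelling <- FALSE
      x_turn <- draw_turn()
      if (dp$anticipation_prob > 0 && stats::runif(1) < dp$anticipation_prob) {
        ant_sign <- s_a
        ant_from <- t_now + stats::runif(1, 0, 0.149)
        ant_until <- t_now + dp$reaction_delay
      }
    } else if (t_now > ant_until && u_fa[i] < p_fa) {
      # spurious anticipation: brief reversal, then self-corrected
      ant_sign <- -s_a
      ant_from <- t_now
      ant_until <- t_now + stats::runif(1, 0.1, 0.25)
    }
    refrac_left <- refrac_left - dt

    # attacker step: run toward an aim point beyond the near side wall at
    # the end line, with an extra downward pull; while dwelling, dive
    # nearly straight down with the joystick pinned (reduced noise)
    if (dwelling) {
      ha <- rot2(c(s_a * 0.12, -1) / sqrt(1 + 0.12^2), 0.3 * noise_a[i])
    } else {
      nav <- c(s_a * (hw + ap$reach) - pa[i, 1], -hh - 1 - pa[i, 2])
      nav <- nav / sqrt(sum(nav^2))
      ha <- nav + c(0, -gb)
      ha <- ha / sqrt(sum(ha^2))
      if (ha[2] < -ap$descent)   # cap vertical approach speed
        ha <- c(sign(ha[1]) * sqrt(1 - ap$descent^2), -ap$descent)
      ha <- rot2(ha, noise_a[i])
    }
    pa[i + 1L, ] <- pa[i, ] + ha * va_step
    if (pa[i + 1L, 2] > hh) pa[i + 1L, 2] <- hh

    # defender step: goalkeeper policy on the delayed, linearly
    # extrapolated attacker state (the perception buffer is seeded with the
    # first actual attacker step so the defender starts jockeying at once)
    j <- min(max(2L, i - d_lag), i + 1L)
    v_del <- (pa[j, ] - pa[j - 1L, ]) * fs
    est <- pa[j, ] + v_del * dp$reaction_delay
    v_ax <- v_del[1]
    if (t_now >= ant_from && t_now <= ant_until) v_ax <- ant_sign * abs(v_ax)
    # lateral: match perceived attacker vx + correction toward its X;
    # below a small magnitude keep drifting in the previous direction
    # (hysteresis: humans do not dither the stick around zero)
    vx_des <- v_ax + dp$track_gain * (est[1] - pd[i, 1])
    if (abs(vx_des) < 0.8) {
      s_keep <- if (!is.null(vd_f) && vd_f[1] != 0) sign(vd_f[1])
                else if (vx_des != 0) sign(vx_des) else 1
      vx_des <- s_keep * 0.8
    }
    vx_des <- min(max(vx_des, -geom$max_speed), geom$max_speed)
    # vertical: guard a buffer below the attacker (never advance past
    # midfield unless lunging); lunge when laterally aligned and close
    lunge <- abs(est[1] - pd[i, 1]) < dp$lunge_x &&
      (est[2] - pd[i, 2]) < dp$lunge_y
    y_tgt <- if (lunge) est[2] else min(est[2] - dp$guard_dist, 0.5)
    vy_cap <- sqrt(max(geom$max_speed^2 - vx_des^2, 0))
    vy_des <- min(max(3 * (y_tgt - pd[i, 2]), -vy_cap), vy_cap)
    # low-pass the commanded velocity (joystick smoothness; suppresses
    # sign jitter near vx = 0), add angular noise, move at constant speed
    vd_f <- if (is.null(vd_f)) c(vx_des, vy_des) else
      0.85 * vd_f + 0.15 * c(vx_des, vy_des)
    spd <- sqrt(sum(vd_f^2))
    # a near-zero command means a released stick: hold still briefly
    vd <- if (spd > 0.05 * geom$max_speed)
      rot2(vd_f, noise_d[i]) * (0.97 * geom$max_speed / spd) else c(0, 0)
    pd[i + 1L, ] <- pd[i, ] + vd * dt
    pd[i + 1L, 1] <- min(max(pd[i + 1L, 1], -hw), hw)
    pd[i + 1L, 2] <- min(max(pd[i + 1L, 2], -hh), hh)

    # termination
    if (sqrt(sum((pa[i + 1L, ] - pd[i + 1L, ])^2)) <= geom$disk_diameter) {
      outcome <- "catch"; n <- i + 1L; break
    }
    if (pa[i + 1L, 2] <= -hh) {
      pa[i + 1L, 2] <- -hh            # clamp the crossing sample to the line
      outcome <- "endline_reached"; n <- i + 1L; break
    }
    if (abs(pa[i + 1L, 1]) > hw) { outcome <- "out_of_bounds"; n <- i + 1L; break }
  }

  chase_trial(trial_id = trial_id,
              attacker_xy = pa[seq_len(n), , drop = FALSE],
              defender_xy = pd[seq_len(n), , drop = FALSE],
              condition = cfg$condition, sample_rate = fs, outcome = outcome,
              participant_pair = participant_pair,
              defender_participant = defender_participant)
}

#' Simulate a full trial set
#'
#' `n_pairs * trials_per_pair` trials with participant identifiers assigned
#' per pair (`P01`, `P02`, ...). Seeding happens once from `cfg$seed`, so the
#' whole set is bit-reproducible.
#'
#' @param cfg a [sim_config()].
#' @return a `trialset`.
#' @export
simulate_trialset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  trials <- vector("list", cfg$n_pairs * cfg$trials_per_pair)
  k <- 0L
  for (p in seq_len(cfg$n_pairs)) {
    pid <- sprintf("P%02d", p)
    pair <- sprintf("pair%02d", p)
    for (j in seq_len(cfg$trials_per_pair)) {
      k <- k + 1L
      trials[[k]] <- simulate_trial(
        cfg,
        trial_id = sprintf("%s_%s_t%03d", cfg$condition, pid, j),
        participant_pair = pair, defender_participant = pid)
    }
  }
  trialset(trials)
}

# Calibrated per-condition policy constants. Frozen after one calibration
# pass against the qualitative orderings the analysis assumes: heading-change
# entropy and short-latency response proportion both decrease from narrow to
# wide, and speed saturation exceeds 90% for both agents everywhere.
REFERENCE_PARAMS <- list(
  narrow = list(hazard = 2.0, anticipation = 0.20, false_alarm = 0.15,
                descent = 0.38, reach = 2.0),
  square = list(hazard = 1.2, anticipation = 0.11, false_alarm = 0.10,
                descent = 0.45, reach = 3.5),
  wide   = list(hazard = 0.6, anticipation = 0.02, false_alarm = 0.06,
                descent = 0.38, reach = 7.0))

#' Reference simulator configuration per condition
#'
#' Curated, frozen configurations reproducing the qualitative structure the
#' behavioral analysis assumes: attacker switch hazard (and hence heading
#' -change entropy) and defender anticipation (hence short-latency response
#' proportion) are ordered narrow > square > wide.
#'
#' @param condition condition name.
#' @param n_pairs,trials_per_pair,seed overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
reference_configs <- function(condition = c("narrow", "square", "wide"),
                              n_pairs = 12L, trials_per_pair = 50L, seed = 1L) {
  condition <- match.arg(condition)
  rp <- REFERENCE_PARAMS[[condition]]
  sim_config(condition = condition, n_pairs = n_pairs,
             trials_per_pair = trials_per_pair, seed = seed,
             attacker = attacker_policy(switch_hazard = rp$hazard,
                                        descent = rp$descent,
                                        reach = rp$reach),
             defender = defender_policy(anticipation_prob = rp$anticipation,
                                        false_alarm_rate = rp$false_alarm))
}
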