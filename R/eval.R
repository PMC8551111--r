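# One-step and multi-step (rollout) evaluation.

#' Movement direction relative to the pursuer
#'
#' Signed angle in degrees, wrapped to (-180, 180], between a displacement
#' and the direction pointing from the moving agent toward the pursuer
#' (i.e. minus the range vector). 0 means motion directly toward the
#' pursuer; positive angles are counterclockwise (to the left with respect
#' to the pursuer).
#'
#' @param disp 2-vector displacement (cm).
#' @param range_vec 2-vector range from pursuer to target (cm).
#' @return angle in degrees; `NA` (with warning) for a zero displacement.
#' @export
relative_direction <- function(disp, range_vec) {
  if (sum(disp^2) == 0) {
    warning("zero displacement: relative direction undefined", call. = FALSE)
    return(NA_real_)
  }
  toward <- -range_vec
  wrap_angle(atan2(toward[1] * disp[2] - toward[2] * disp[1],
                   sum(toward * disp)) * 180 / pi)
}

# vectorized version on matrices (rows)
relative_direction_m <- function(D, R) {
  Tw <- -R
  out <- wrap_angle(atan2(Tw[, 1] * D[, 2] - Tw[, 2] * D[, 1],
                          Tw[, 1] * D[, 1] + Tw[, 2] * D[, 2]) * 180 / pi)
  out[D[, 1]^2 + D[, 2]^2 == 0] <- NA_real_
  out
}

phase_of <- function(abs_ddir) {
  ifelse(is.na(abs_ddir), NA_character_,
         ifelse(abs_ddir < 20, "ST", ifelse(abs_ddir <= 60, "GC", "SC")))
}

predicted_displacements <- function(model, z) {
  # z: one element of build_inputs(); returns m x 2 predicted displacement
  m <- nrow(z$X)
  if (model$kind == "L") {
    z$X[, 1:2, drop = FALSE]                    # repeat current velocity
  } else if (model$kind == "C") {
    P <- matrix(NA_real_, m, 2)
    for (t in seq_len(m)) {
      if (t == 1L) next                         # needs two displacements
      pr <- curvilinear_extrapolate(z$pa[t - 1, ], z$pa[t, ], z$pa[t + 1, ])
      P[t, ] <- pr - z$pa[t + 1, ]
    }
    P
  } else {
    predict_sequence(model, z$X)$mu
  }
}

#' One-step-ahead evaluation of a predictor
#'
#' For every valid step of every trial: the predicted and actual attacker
#' displacements are converted to directions relative to the pursuer, the
#' angular error is the absolute wrapped difference, and the step is
#' labelled by the actual heading-change phase: straight (ST, < 20 deg),
#' gentle curve (GC, 20-60 deg) or sharp curve (SC, > 60 deg).
#'
#' @param model a `cp_model` (network or L/C extrapolator).
#' @param ts a `trialset` or prebuilt [build_inputs()] list.
#' @param rate analysis rate (Hz).
#' @return data.frame: `trial_id`, `defender_participant`, `condition`,
#'   `step`, `pred_angle`, `actual_angle`, `error` (degrees in \[0, 180\]),
#'   `signed_error`, `phase`. Steps with zero actual displacement are
#'   dropped (count in attribute `"n_skipped"`).
#' @export
one_step_eval <- function(model, ts, rate = 20) {
  inputs <- if (inherits(ts, "trialset")) build_inputs(ts, rate) else ts
  rows <- vector("list", length(inputs))
  n_skipped <- 0L
  for (k in seq_along(inputs)) {
    z <- inputs[[k]]
    P <- predicted_displacements(model, z)
    R <- z$X[, 5:6, drop = FALSE]
    act <- relative_direction_m(z$Y, R)
    prd <- relative_direction_m(P, R)
    # actual heading change between step t-1->t and t->t+1
    ddir <- wrap_angle(atan2(z$Y[, 2], z$Y[, 1]) * 180 / pi -
                       atan2(z$X[, 2], z$X[, 1]) * 180 / pi)
    v0 <- z$X[, 1]^2 + z$X[, 2]^2 == 0
    ddir[v0] <- NA_real_
    ok <- !is.na(act) & !is.na(prd)
    n_skipped <- n_skipped + sum(is.na(act))
    if (!any(ok)) next
    serr <- wrap_angle(prd[ok] - act[ok])
    rows[[k]] <- data.frame(
      trial_id = z$trial_id, defender_participant = z$defender_participant,
      condition = z$condition, step = which(ok) + 1L,
      pred_angle = prd[ok], actual_angle = act[ok],
      error = abs(serr), signed_error = serr,
      phase = phase_of(abs(ddir[ok])),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame()
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Closed-loop multi-step rollout from one start step
#'
#' The model's predicted attacker displacement is fed back as the
#' attacker-state input at the next step, while defender inputs are read
#' from the *actual* recorded defender trajectory (own state assumed known
#' up to 250 ms ahead). Recurrent kinds warm their hidden state on the
#' actual inputs from the trial start and require at least `warmup` prior
#' steps. Rollouts never cross the trial boundary.
#'
#' @param model a `cp_model`.
#' @param tr a `chase_trial` (or one element of [build_inputs()]).
#' @param start_step index t (in decimated samples, >= 2; >= 3 for C;
#'   > `warmup` for recurrent kinds) at which the rollout starts; the
#'   prediction covers steps t+1 ... t+horizon.
#' @param horizon number of rolled-out steps (default 5 = 250 ms at 20 Hz).
#' @param rate analysis rate (Hz).
#' @param warmup minimum number of observed steps before `start_step` for
#'   recurrent kinds (default 50 = 2.5 s).
#' @param state0 optional precomputed hidden state at `start_step`
#'   (internal use by [rollout_eval()], which threads the state instead of
#'   re-warming per start).
#' @return list: `pred` (horizon x 2 predicted positions), `errors`
#'   (Euclidean error per horizon step, cm), `ade` (mean), `fde` (error at
#'   the last step), `phase` (actual phase label per step).
#' @export
rollout <- function(model, tr, start_step, horizon = 5L, rate = 20,
                    warmup = 50L, state0 = NULL) {
  z <- if (inherits(tr, "chase_trial")) {
    zz <- build_inputs(trialset(list(tr)), rate)
    if (!length(zz)) stop("trial too short for rollout", call. = FALSE)
    zz[[1]]
  } else tr
  n <- nrow(z$pa)
  t0 <- as.integer(start_step)
  min_start <- if (model$kind == "C") 3L else 2L
  if (is_recurrent(model$kind)) min_start <- max(min_start, warmup + 1L)
  if (t0 < min_start || t0 + horizon > n)
    stop(sprintf("start_step %d lacks context (need [%d, %d])",
                 t0, min_start, n - horizon), call. = FALSE)

  state <- state0
  if (is.null(state) && is_recurrent(model$kind) && t0 > 2L) {
    # consume actual inputs up to (not including) the one the first
    # closed-loop step will feed: rows 1..t0-2
    fw <- seq_forward(model$arch, model$params,
                      z$X[seq_len(t0 - 2L), , drop = FALSE],
                      B = 1L, T_len = t0 - 2L)
    state <- fw$state
  }

  pa_hat <- z$pa[t0, ]
  v_hat <- z$pa[t0, ] - z$pa[t0 - 1L, ]
  if (model$kind == "C") {
    d_prev <- z$pa[t0 - 1L, ] - z$pa[t0 - 2L, ]
    dth <- if (sum(d_prev^2) == 0 || sum(v_hat^2) == 0) 0 else
      atan2(d_prev[1] * v_hat[2] - d_prev[2] * v_hat[1], sum(d_prev * v_hat))
  }
  preds <- matrix(NA_real_, horizon, 2)
  errors <- numeric(horizon)
  for (k in seq_len(horizon)) {
    t_in <- t0 + k - 1L                  # defender state read at this step
    if (model$kind == "L") {
      step_d <- v_hat
    } else if (model$kind == "C") {
      step_d <- rot2(v_hat, dth)
      v_hat <- step_d
    } else {
      v_d <- z$pd[t_in, ] - z$pd[t_in - 1L, ]
      x <- c(v_hat, v_d, pa_hat - z$pd[t_in, ])
      fw <- seq_forward(model$arch, model$params, matrix(x, 1), B = 1L,
                        T_len = 1L, state = state)
      state <- fw$state
      step_d <- fw$out[1, 1:2]
      v_hat <- step_d
    }
    pa_hat <- pa_hat + step_d
    preds[k, ] <- pa_hat
    errors[k] <- sqrt(sum((pa_hat - z$pa[t0 + k, ])^2))
  }
  act_d <- diff(z$pa[(t0 - 1L):(t0 + horizon), , drop = FALSE])
  ang <- atan2(act_d[, 2], act_d[, 1]) * 180 / pi
  dd <- abs(wrap_angle(ang[-1] - ang[-length(ang)]))
  list(pred = preds, errors = errors, ade = mean(errors),
       fde = errors[horizon], phase = phase_of(dd))
}

#' Rollout evaluation over all valid start steps of a trial set
#'
#' Applies [rollout()] with a sliding start (every `stride`-th valid step)
#' and collects the per-horizon displacement errors.
#'
#' @param model a `cp_model`.
#' @param ts a `trialset` or [build_inputs()] list.
#' @param horizon,rate,warmup as in [rollout()].
#' @param stride start-step stride (1 = every valid step).
#' @return data.frame: `trial_id`, `defender_participant`, `condition`,
#'   `start`, `horizon`, `error` (cm); one row per rolled-out step.
#' @export
rollout_eval <- function(model, ts, horizon = 5L, rate = 20, warmup = 50L,
                         stride = 1L) {
  inputs <- if (inherits(ts, "trialset")) build_inputs(ts, rate) else ts
  rows <- list()
  min_start <- if (model$kind == "C") 3L else 2L
  if (is_recurrent(model$kind)) min_start <- max(min_start, warmup + 1L)
  recurrent <- is_recurrent(model$kind)
  for (z in inputs) {
    n <- nrow(z$pa)
    if (min_start > n - horizon) next
    starts <- seq(min_start, n - horizon, by = stride)
    state <- NULL; consumed <- 0L   # input rows already fed to the state
    for (t0 in starts) {
      if (recurrent) {
        if (t0 - 2L > consumed) {
          fw <- seq_forward(model$arch, model$params,
                            z$X[(consumed + 1L):(t0 - 2L), , drop = FALSE],
                            B = 1L, T_len = t0 - 2L - consumed, state = state)
          state <- fw$state; consumed <- t0 - 2L
        }
      }
      ro <- rollout(model, z, t0, horizon = horizon, rate = rate,
                    warmup = warmup, state0 = state)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = z$trial_id, defender_participant = z$defender_participant,
        condition = z$condition, start = t0, horizon = seq_len(horizon),
        error = ro$errors, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
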