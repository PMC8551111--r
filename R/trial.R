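# Trial and trial-set containers, resampling, velocities.

#' Construct a chase-escape trial
#'
#' A trial is one chase/escape episode: two synchronized 2-D position series
#' (attacker and defender, in cm, package coordinate frame), the condition,
#' the sample rate and the outcome.
#'
#' @param trial_id unique identifier string.
#' @param attacker_xy,defender_xy numeric n x 2 matrices of positions (cm);
#'   equal number of rows, at least 2.
#' @param condition `"narrow"`, `"square"` or `"wide"`.
#' @param sample_rate sampling rate in Hz (120 for raw recordings, 20 after
#'   [downsample()]).
#' @param outcome one of `"catch"`, `"endline_reached"`, `"out_of_bounds"`,
#'   `"timeout"` (censored: neither side won within the time limit).
#' @param participant_pair,defender_participant identifiers; the defender
#'   participant defines cross-validation folds.
#' @param validate check invariants (positions inside the pitch, equal
#'   lengths). The attacker is allowed outside the pitch only at the final
#'   sample of an `out_of_bounds` trial.
#' @return an object of class `chase_trial`.
#' @export
chase_trial <- function(trial_id, attacker_xy, defender_xy, condition,
                        sample_rate = 120,
                        outcome = c("catch", "endline_reached",
                                    "out_of_bounds", "timeout"),
                        participant_pair = "pair01",
                        defender_participant = "P01",
                        validate = TRUE) {
  outcome <- match.arg(outcome)
  attacker_xy <- as.matrix(attacker_xy)
  defender_xy <- as.matrix(defender_xy)
  storage.mode(attacker_xy) <- "double"
  storage.mode(defender_xy) <- "double"
  tr <- structure(
    list(trial_id = as.character(trial_id),
         participant_pair = as.character(participant_pair),
         defender_participant = as.character(defender_participant),
         condition = match.arg(condition, names(PITCH_WIDTHS)),
         sample_rate = as.numeric(sample_rate),
         attacker_xy = attacker_xy,
         defender_xy = defender_xy,
         outcome = outcome),
    class = "chase_trial")
  if (validate) validate_trial(tr)
  tr
}

validate_trial <- function(tr) {
  na <- nrow(tr$attacker_xy); nd <- nrow(tr$defender_xy)
  if (na != nd)
    stop(sprintf("trial '%s': attacker series length (%d) != defender series length (%d)",
                 tr$trial_id, na, nd), call. = FALSE)
  if (na < 2)
    stop(sprintf("trial '%s': needs at least 2 samples, got %d", tr$trial_id, na),
         call. = FALSE)
  if (ncol(tr$attacker_xy) != 2 || ncol(tr$defender_xy) != 2)
    stop(sprintf("trial '%s': position series must have 2 columns", tr$trial_id),
         call. = FALSE)
  geom <- pitch_geometry(tr$condition)
  hw <- geom$width / 2; hh <- geom$height / 2
  tol <- 1e-9
  inside <- function(m) m[, 1] >= -hw - tol & m[, 1] <= hw + tol &
    m[, 2] >= -hh - tol & m[, 2] <= hh + tol
  ok_d <- inside(tr$defender_xy)
  if (!all(ok_d))
    stop(sprintf("trial '%s': defender outside pitch at sample %d",
                 tr$trial_id, which(!ok_d)[1]), call. = FALSE)
  ok_a <- inside(tr$attacker_xy)
  if (tr$outcome == "out_of_bounds") ok_a[na] <- TRUE
  if (!all(ok_a))
    stop(sprintf("trial '%s': attacker outside pitch at sample %d",
                 tr$trial_id, which(!ok_a)[1]), call. = FALSE)
  invisible(tr)
}

#' @export
print.chase_trial <- function(x, ...) {
  cat(sprintf("<trial %s: %s, %d samples @ %g Hz, defender %s, outcome %s>\n",
              x$trial_id, x$condition, nrow(x$attacker_xy), x$sample_rate,
              x$defender_participant, x$outcome))
  invisible(x)
}

#' Duration of a trial in seconds
#' @param tr a `chase_trial`.
#' @return duration in s (samples minus one over the sample rate).
#' @export
trial_duration <- function(tr) (nrow(tr$attacker_xy) - 1) / tr$sample_rate

#' Construct a trial set
#'
#' A collection of trials plus a manifest table with one row per trial
#' (`trial_id`, `condition`, `participant_pair`, `defender_participant`,
#' `outcome`, `duration`, `sample_rate`, `n_samples`).
#'
#' @param trials list of `chase_trial` objects with unique ids.
#' @return an object of class `trialset`.
#' @export
trialset <- function(trials) {
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids))
    stop("duplicate trial_id: ", ids[duplicated(ids)][1], call. = FALSE)
  manifest <- data.frame(
    trial_id = ids,
    condition = vapply(trials, `[[`, character(1), "condition"),
    participant_pair = vapply(trials, `[[`, character(1), "participant_pair"),
    defender_participant = vapply(trials, `[[`, character(1), "defender_participant"),
    outcome = vapply(trials, `[[`, character(1), "outcome"),
    duration = vapply(trials, trial_duration, numeric(1)),
    sample_rate = vapply(trials, `[[`, numeric(1), "sample_rate"),
    n_samples = vapply(trials, function(t) nrow(t$attacker_xy), integer(1)),
    stringsAsFactors = FALSE)
  names(trials) <- ids
  structure(list(trials = trials, manifest = manifest), class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  cat(sprintf("<trialset: %d trials, %d defender participant(s), conditions: %s>\n",
              length(x$trials),
              length(unique(x$manifest$defender_participant)),
              paste(unique(x$manifest$condition), collapse = ", ")))
  invisible(x)
}

#' @export
length.trialset <- function(x) length(x$trials)

#' Downsample a trial by decimation
#'
#' Keeps every (`sample_rate`/`target_rate`)-th sample starting at the first
#' one. Decimation (sample-and-hold), not averaging, so at 20 Hz consecutive
#' samples are exactly 50 ms apart.
#'
#' @param tr a `chase_trial`.
#' @param target_rate target rate in Hz; must divide `tr$sample_rate`.
#' @return the decimated `chase_trial` with `sample_rate = target_rate`.
#' @export
#' @examples
#' # a 601-sample 120 Hz trial keeps 101 samples at 20 Hz
downsample <- function(tr, target_rate) {
  stopifnot(inherits(tr, "chase_trial"))
  if (target_rate <= 0) stop("target_rate must be positive", call. = FALSE)
  ratio <- tr$sample_rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("sample rate %g Hz is not an integer multiple of target %g Hz",
                 tr$sample_rate, target_rate), call. = FALSE)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(tr)
  keep <- seq(1L, nrow(tr$attacker_xy), by = ratio)
  tr$attacker_xy <- tr$attacker_xy[keep, , drop = FALSE]
  tr$defender_xy <- tr$defender_xy[keep, , drop = FALSE]
  tr$sample_rate <- target_rate
  tr
}

#' Downsample every trial of a trial set
#' @param ts a `trialset`.
#' @param target_rate target rate in Hz.
#' @return downsampled `trialset`.
#' @export
downsample_trialset <- function(ts, target_rate) {
  trialset(lapply(ts$trials, downsample, target_rate = target_rate))
}

#' Per-sample velocities of one agent
#'
#' Forward difference `p[i+1] - p[i]`. Units are cm per sample interval (not
#' cm/s) because the predictive models operate on per-step displacements;
#' multiply by the sample rate for cm/s.
#'
#' @param tr a `chase_trial`.
#' @param agent `"attacker"` or `"defender"`.
#' @return object of class `velocity_track`: list with `vx`, `vy`, `speed`
#'   (length `n_samples - 1`) and `sample_rate`.
#' @export
velocities <- function(tr, agent = c("attacker", "defender")) {
  agent <- match.arg(agent)
  p <- if (agent == "attacker") tr$attacker_xy else tr$defender_xy
  if (nrow(p) < 2) stop("need at least 2 samples to compute velocities", call. = FALSE)
  d <- diff(p)
  structure(list(vx = d[, 1], vy = d[, 2],
                 speed = sqrt(d[, 1]^2 + d[, 2]^2),
                 sample_rate = tr$sample_rate, agent = agent),
            class = "velocity_track")
}
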