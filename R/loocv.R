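# Leave-one-participant-out cross-validation and fold aggregation.

#' Leave-one-participant-out cross-validation
#'
#' One fold per defender participant: the model is trained on all other
#' participants' trials and evaluated (one-step angular error by phase, and
#' closed-loop rollout ADE/FDE by horizon) on the held-out participant.
#' L/C extrapolators skip the training stage.
#'
#' @param spec a [model_spec()].
#' @param ts a `trialset` with at least 2 defender participants.
#' @param rate analysis rate (Hz).
#' @param horizon rollout horizon (steps).
#' @param rollout_stride start-step stride for [rollout_eval()] (increase
#'   to cut evaluation cost).
#' @param max_folds evaluate only the first `max_folds` participants
#'   (useful for scaled-down checks); `NULL` = all.
#' @param verbose print progress.
#' @return list of class `cp_folds`; each fold has `participant`, `kind`,
#'   `model`, `one_step` (data.frame), `rollout` (data.frame), `n_train`,
#'   `n_test` (time-step counts), `n_train_trials`.
#' @export
loo_cv <- function(spec, ts, rate = 20, horizon = 5L, rollout_stride = 1L,
                   max_folds = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(ts, "trialset"))
  parts <- sort(unique(ts$manifest$defender_participant))
  if (length(parts) < 2) stop("need >= 2 defender participants", call. = FALSE)
  inputs <- build_inputs(ts, rate)
  by_part <- split(inputs,
                   vapply(inputs, `[[`, character(1), "defender_participant"))
  if (!is.null(max_folds)) parts <- parts[seq_len(min(max_folds, length(parts)))]
  folds <- list()
  for (p in parts) {
    test_in <- by_part[[p]]
    if (is.null(test_in) || !length(test_in)) {
      warning("participant ", p, " has no usable trials: fold skipped",
              call. = FALSE)
      next
    }
    train_in <- unlist(by_part[setdiff(names(by_part), p)], recursive = FALSE)
    if (verbose) message("fold ", p, ": ", length(train_in), " training trials")
    model <- if (spec$kind %in% NETWORK_KINDS)
      train_model(spec, train_in, rate = rate) else make_model(spec)
    model$fold <- p
    os <- one_step_eval(model, test_in, rate = rate)
    ro <- rollout_eval(model, test_in, horizon = horizon, rate = rate,
                       stride = rollout_stride)
    folds[[p]] <- list(
      participant = p, kind = spec$kind, model = model,
      one_step = os, rollout = ro,
      n_train = sum(vapply(train_in, function(z) nrow(z$X), integer(1))),
      n_test = sum(vapply(test_in, function(z) nrow(z$X), integer(1))),
      n_train_trials = length(train_in))
  }
  structure(folds, class = "cp_folds")
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
}

#' Aggregate cross-validation folds into a summary table
#'
#' Mean and s.e.m. across held-out participants of: overall one-step
#' angular error, one-step error per phase (ST/GC/SC), and rollout
#' displacement error per horizon step (`error_h`), plus cumulative
#' average displacement error (`ade_h`, mean over horizons 1..h) and final
#' displacement error (`fde_h`, error at horizon h).
#'
#' @param folds a `cp_folds` object (or a plain list of such objects from
#'   several models, which are stacked with their `kind`).
#' @return data.frame: `kind`, `metric`, `group`, `mean`, `sem`, `n_folds`.
#' @export
aggregate_folds <- function(folds) {
  if (!inherits(folds, "cp_folds") && is.list(folds) &&
      all(vapply(folds, inherits, logical(1), "cp_folds")))
    return(do.call(rbind, lapply(folds, aggregate_folds)))
  stopifnot(inherits(folds, "cp_folds"))
  if (!length(folds)) return(data.frame())
  kind <- folds[[1]]$kind
  rows <- list()
  add <- function(metric, group, vals)
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, metric = metric, group = group,
      mean = mean(vals, na.rm = TRUE), sem = sem(vals),
      n_folds = sum(!is.na(vals)), stringsAsFactors = FALSE)

  os_mean <- vapply(folds, function(f)
    if (nrow(f$one_step)) mean(f$one_step$error) else NA_real_, numeric(1))
  add("one_step_error", "all", os_mean)
  for (ph in c("ST", "GC", "SC")) {
    v <- vapply(folds, function(f) {
      e <- f$one_step$error[!is.na(f$one_step$phase) & f$one_step$phase == ph]
      if (length(e)) mean(e) else NA_real_
    }, numeric(1))
    add("one_step_error", ph, v)
  }
  horizons <- sort(unique(unlist(lapply(folds, function(f) f$rollout$horizon))))
  for (h in horizons) {
    step_err <- vapply(folds, function(f) {
      e <- f$rollout$error[f$rollout$horizon == h]
      if (length(e)) mean(e) else NA_real_
    }, numeric(1))
    add("error", as.character(h), step_err)
    ade <- vapply(folds, function(f) {
      e <- f$rollout$error[f$rollout$horizon <= h]
      if (length(e)) mean(e) else NA_real_
    }, numeric(1))
    add("ade", as.character(h), ade)
    add("fde", as.character(h), step_err)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Two-dimensional predicted-vs-actual direction histogram
#'
#' Joint relative-frequency histogram of predicted and actual
#' pursuer-relative movement directions at `bin_width`-degree resolution
#' (pooled over folds). Its marginals equal the 1-D predicted and actual
#' direction histograms.
#'
#' @param one_step a one-step evaluation data.frame (or the stacked
#'   `one_step` tables of several folds).
#' @param bin_width degrees (default 5).
#' @return list: `counts` (n x n matrix), `rel_freq`, `breaks`.
#' @export
direction_histogram_2d <- function(one_step, bin_width = 5) {
  breaks <- seq(-180, 180, by = bin_width)
  nb <- length(breaks) - 1L
  bin <- function(a) pmin(pmax(ceiling((a + 180) / bin_width), 1L), nb)
  counts <- matrix(0L, nb, nb)
  if (nrow(one_step)) {
    ip <- bin(one_step$pred_angle); ia <- bin(one_step$actual_angle)
    for (k in seq_along(ip)) counts[ip[k], ia[k]] <- counts[ip[k], ia[k]] + 1L
  }
  n <- sum(counts)
  list(counts = counts, rel_freq = if (n > 0) counts / n else counts,
       breaks = breaks)
}
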