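# Behavioral statistics of chase-escape trial sets: direction-change
# detection by X-velocity zero crossing, defender response times,
# heading-change entropy, spatial/column statistics, inter-switch interval
# (memorylessness) analysis, speed saturation.

SHORT_LATENCY_MS <- 150   # anticipatory response criterion
MAX_LATENCY_MS   <- 500   # responses longer than this are discarded

#' Detect horizontal direction changes of one agent
#'
#' A directional change is the X velocity crossing zero: one event per
#' strict sign flip of `vx`. Samples with `vx == 0` inherit the previous
#' nonzero sign, so touching zero without crossing is not an event. The
#' event time is the time of the first velocity sample carrying the new
#' sign; the location is the agent's position at that sample.
#'
#' @param tr a `chase_trial` (event analyses run on raw 120 Hz data,
#'   but any rate is accepted).
#' @param agent `"attacker"` or `"defender"`.
#' @return data.frame with columns `trial_id`, `agent`, `time` (s), `sign`
#'   (`"pos_to_neg"`/`"neg_to_pos"`), `x_at_change`, `y_at_change`,
#'   `sample_index` (index of the velocity sample with the new sign). Zero
#'   rows if `vx` never changes sign.
#' @export
detect_direction_changes <- function(tr, agent = c("attacker", "defender")) {
  agent <- match.arg(agent)
  v <- velocities(tr, agent)
  detect_changes_vx(v$vx, tr$sample_rate, tr$trial_id, agent,
                    if (agent == "attacker") tr$attacker_xy else tr$defender_xy)
}

# core sign-flip scan on a vx vector (kept separate so tests can feed raw
# velocity sequences)
detect_changes_vx <- function(vx, sample_rate, trial_id = "trial", agent = "attacker",
                              pos = NULL) {
  s <- sign(vx)
  # zeros inherit the previous nonzero sign; leading zeros carry no sign
  nz <- s != 0
  if (!any(nz)) return(empty_events())
  idx <- cumsum(nz)
  filled <- ifelse(idx == 0, 0, s[nz][pmax(idx, 1L)])
  prev <- c(0, filled[-length(filled)])
  flip <- which(filled != 0 & prev != 0 & filled != prev)
  if (!length(flip)) return(empty_events())
  data.frame(
    trial_id = trial_id, agent = agent,
    time = (flip - 1) / sample_rate,
    sign = ifelse(filled[flip] < 0, "pos_to_neg", "neg_to_pos"),
    x_at_change = if (is.null(pos)) NA_real_ else pos[flip, 1],
    y_at_change = if (is.null(pos)) NA_real_ else pos[flip, 2],
    sample_index = flip,
    stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(trial_id = character(0), agent = character(0), time = numeric(0),
              sign = character(0), x_at_change = numeric(0),
              y_at_change = numeric(0), sample_index = integer(0),
              stringsAsFactors = FALSE)
}

#' Detect direction changes across a whole trial set
#'
#' @param ts a `trialset`.
#' @param agent agent to scan.
#' @return combined event data.frame with `condition` and
#'   `defender_participant` attached.
#' @export
detect_changes_trialset <- function(ts, agent = c("attacker", "defender")) {
  agent <- match.arg(agent)
  out <- lapply(ts$trials, function(tr) {
    ev <- detect_direction_changes(tr, agent)
    if (nrow(ev)) {
      ev$condition <- tr$condition
      ev$defender_participant <- tr$defender_participant
    }
    ev
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out)) {
    e <- empty_events(); e$condition <- character(0)
    e$defender_participant <- character(0)
    return(e)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Match defender responses to attacker direction changes
#'
#' Greedy, in time order: each attacker event is matched to the earliest
#' unmatched defender event of the same sign with latency in
#' \[0, 500\] ms; matching is one-to-one and unmatched events are dropped.
#' Latencies below 150 ms are flagged as short (anticipatory).
#'
#' @param attacker_events,defender_events event data.frames from
#'   [detect_direction_changes()], from the same trial.
#' @return data.frame with one row per matched pair: `trial_id`, `sign`,
#'   `attacker_time`, `defender_time`, `latency_ms`, `is_short`,
#'   `defender_x`, `attacker_x`.
#' @export
match_responses <- function(attacker_events, defender_events) {
  if (!nrow(attacker_events) || !nrow(defender_events)) return(empty_records())
  ae <- attacker_events[order(attacker_events$time), ]
  de <- defender_events[order(defender_events$time), ]
  used <- rep(FALSE, nrow(de))
  rows <- vector("list", nrow(ae))
  for (i in seq_len(nrow(ae))) {
    lat <- (de$time - ae$time[i]) * 1000
    cand <- which(!used & de$sign == ae$sign[i] & lat >= 0 & lat <= MAX_LATENCY_MS)
    if (!length(cand)) next
    j <- cand[1]
    used[j] <- TRUE
    rows[[i]] <- data.frame(
      trial_id = ae$trial_id[i], sign = ae$sign[i],
      attacker_time = ae$time[i], defender_time = de$time[j],
      latency_ms = lat[j], is_short = lat[j] < SHORT_LATENCY_MS,
      defender_x = de$x_at_change[j], attacker_x = ae$x_at_change[i],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_records())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

empty_records <- function() {
  data.frame(trial_id = character(0), sign = character(0),
             attacker_time = numeric(0), defender_time = numeric(0),
             latency_ms = numeric(0), is_short = logical(0),
             defender_x = numeric(0), attacker_x = numeric(0),
             stringsAsFactors = FALSE)
}

#' Response records for every trial of a set
#'
#' Runs [detect_direction_changes()] on both agents of each trial and
#' matches them with [match_responses()].
#'
#' @param ts a `trialset`.
#' @return combined response data.frame with `condition` and
#'   `defender_participant` attached.
#' @export
response_records <- function(ts) {
  out <- lapply(ts$trials, function(tr) {
    rec <- match_responses(detect_direction_changes(tr, "attacker"),
                           detect_direction_changes(tr, "defender"))
    if (nrow(rec)) {
      rec$condition <- tr$condition
      rec$defender_participant <- tr$defender_participant
    }
    rec
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out)) {
    e <- empty_records(); e$condition <- character(0)
    e$defender_participant <- character(0)
    return(e)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Proportion of short-latency (< 150 ms) responses
#'
#' @param records response data.frame from [match_responses()] /
#'   [response_records()].
#' @param by_participant if TRUE and the records carry a
#'   `defender_participant` column, the proportion is computed per
#'   participant and then averaged (the group statistic); otherwise pooled.
#' @return a single proportion, `NA` (with a warning) on empty input. With
#'   `by_participant = TRUE` the per-participant table is attached as
#'   attribute `"per_participant"`.
#' @export
short_latency_proportion <- function(records, by_participant = FALSE) {
  if (!nrow(records)) {
    warning("no response records: proportion undefined", call. = FALSE)
    return(NA_real_)
  }
  if (by_participant && !is.null(records$defender_participant)) {
    per <- tapply(records$is_short, records$defender_participant, mean)
    out <- mean(per)
    attr(out, "per_participant") <- per
    return(out)
  }
  mean(records$is_short)
}

wrap_angle <- function(deg) {
  # wrap to (-180, 180]
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Heading-change histogram of an agent at the analysis rate
#'
#' Trials are decimated to `rate` (default 20 Hz, so consecutive headings
#' are 50 ms apart), the movement direction is computed wherever speed is
#' nonzero, and the signed per-step direction difference, wrapped to
#' (-180, 180\] degrees (positive = counterclockwise / leftward turn), is
#' binned at `bin_width`.
#'
#' @param ts a `trialset` (any mix of trials; raw 120 Hz input is decimated
#'   internally).
#' @param agent agent whose heading is analysed.
#' @param bin_width bin width in degrees (default 5: 72 bins).
#' @param rate analysis rate in Hz (default 20).
#' @return object of class `heading_histogram`: `breaks`, `counts`,
#'   `rel_freq`, `n_total`, `n_skipped` (zero-speed steps), `bin_width`.
#' @export
heading_change_histogram <- function(ts, agent = c("attacker", "defender"),
                                     bin_width = 5, rate = 20) {
  agent <- match.arg(agent)
  stopifnot(bin_width > 0, 360 %% bin_width == 0)
  deltas <- numeric(0); skipped <- 0L
  for (tr in ts$trials) {
    tr2 <- downsample(tr, rate)
    p <- if (agent == "attacker") tr2$attacker_xy else tr2$defender_xy
    if (nrow(p) < 3) next
    d <- diff(p)
    sp <- sqrt(d[, 1]^2 + d[, 2]^2)
    ang <- atan2(d[, 2], d[, 1]) * 180 / pi
    ok <- sp > 1e-12
    dd <- wrap_angle(ang[-1] - ang[-length(ang)])
    valid <- ok[-1] & ok[-length(ok)]
    skipped <- skipped + sum(!valid)
    deltas <- c(deltas, dd[valid])
  }
  breaks <- seq(-180, 180, by = bin_width)
  idx <- ceiling((deltas + 180) / bin_width)
  idx[idx < 1L] <- 1L   # exact -180 already wrapped to 180
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  n <- sum(counts)
  structure(list(breaks = breaks, counts = counts,
                 rel_freq = if (n > 0) counts / n else counts * NA_real_,
                 n_total = n, n_skipped = skipped, bin_width = bin_width,
                 agent = agent, rate = rate),
            class = "heading_histogram")
}

#' Shannon entropy (bits)
#'
#' For a heading-change histogram: `-sum p_i log2 p_i` over occupied bins,
#' quantifying unpredictability of the turning behaviour; 0 for a
#' deterministic heading, `log2(n_bins)` for a uniform one.
#'
#' @param x a `heading_histogram`, or a numeric vector of counts or
#'   probabilities.
#' @param ... unused.
#' @return entropy in bits; `NA` (with warning) for an empty histogram.
#' @export
entropy <- function(x, ...) UseMethod("entropy")

#' @rdname entropy
#' @export
entropy.heading_histogram <- function(x, ...) {
  if (x$n_total == 0) {
    warning("empty histogram: entropy undefined", call. = FALSE)
    return(NA_real_)
  }
  entropy.default(x$counts)
}

#' @rdname entropy
#' @export
entropy.default <- function(x, ...) {
  if (any(x < 0)) stop("negative mass", call. = FALSE)
  s <- sum(x)
  if (s == 0) {
    warning("zero total mass: entropy undefined", call. = FALSE)
    return(NA_real_)
  }
  p <- x[x > 0] / s
  -sum(p * log2(p))
}

column_index <- function(x, width, n_columns) {
  i <- ceiling((x + width / 2) / (width / n_columns))
  pmin(pmax(i, 1L), n_columns)
}

#' Per-column spatial statistics
#'
#' Divides the pitch into equal-width X columns (4/8/16 for
#' narrow/square/wide, i.e. constant column width) and reports, per column:
#' time spent by the agent, number of its direction changes, change
#' frequency per second of occupancy, and the mean defender response
#' latency attributed to the defender's own position at its change. Columns
#' the agent never visits are flagged missing and excluded from summary
#' statistics.
#'
#' @param ts a `trialset` of a single condition.
#' @param agent agent whose occupancy/changes are tabulated.
#' @param records optional response records (for the latency column).
#' @param n_columns override for the column count (defaults to the
#'   condition's 4/8/16).
#' @return data.frame with one row per column: `column`, `x_lo`, `x_hi`,
#'   `time_spent`, `n_changes`, `freq_per_s`, `mean_response_ms`, `missing`.
#' @export
column_stats <- function(ts, agent = c("attacker", "defender"),
                         records = NULL, n_columns = NULL) {
  agent <- match.arg(agent)
  conds <- unique(ts$manifest$condition)
  if (length(conds) != 1)
    stop("column_stats expects a single-condition trialset", call. = FALSE)
  geom <- pitch_geometry(conds)
  if (is.null(n_columns)) n_columns <- condition_columns(conds)
  time_spent <- numeric(n_columns); n_changes <- numeric(n_columns)
  for (tr in ts$trials) {
    p <- if (agent == "attacker") tr$attacker_xy else tr$defender_xy
    ci <- column_index(p[, 1], geom$width, n_columns)
    time_spent <- time_spent + tabulate(ci, n_columns) / tr$sample_rate
    ev <- detect_direction_changes(tr, agent)
    if (nrow(ev))
      n_changes <- n_changes +
        tabulate(column_index(ev$x_at_change, geom$width, n_columns), n_columns)
  }
  mean_rt <- rep(NA_real_, n_columns)
  if (!is.null(records) && nrow(records)) {
    ci <- column_index(records$defender_x, geom$width, n_columns)
    agg <- tapply(records$latency_ms, ci, mean)
    mean_rt[as.integer(names(agg))] <- agg
  }
  edges <- seq(-geom$width / 2, geom$width / 2, length.out = n_columns + 1)
  data.frame(column = seq_len(n_columns),
             x_lo = edges[-length(edges)], x_hi = edges[-1],
             time_spent = time_spent, n_changes = n_changes,
             freq_per_s = ifelse(time_spent > 0, n_changes / time_spent, NA_real_),
             mean_response_ms = mean_rt,
             missing = time_spent == 0)
}

#' Ratio of defender to attacker direction changes
#'
#' Total defender X-direction changes over total attacker changes, per
#' defender participant, with the group mean and s.e.m. A purely reactive
#' defender cannot exceed 1; incorrect anticipatory reversals push the
#' ratio above 1.
#'
#' @param ts a `trialset`.
#' @return list with `per_participant` (data.frame: participant, defender
#'   and attacker change counts, ratio), `mean`, `sem`, and the pooled
#'   `overall` ratio. Participants with zero attacker changes get `NA`
#'   ratios and are excluded from the summary with a warning.
#' @export
change_ratio <- function(ts) {
  ae <- detect_changes_trialset(ts, "attacker")
  de <- detect_changes_trialset(ts, "defender")
  parts <- sort(unique(ts$manifest$defender_participant))
  n_a <- vapply(parts, function(p) sum(ae$defender_participant == p), numeric(1))
  n_d <- vapply(parts, function(p) sum(de$defender_participant == p), numeric(1))
  ratio <- ifelse(n_a > 0, n_d / n_a, NA_real_)
  if (any(n_a == 0))
    warning("participant(s) with zero attacker changes excluded: ",
            paste(parts[n_a == 0], collapse = ", "), call. = FALSE)
  ok <- !is.na(ratio)
  list(per_participant = data.frame(defender_participant = parts,
                                    n_defender = n_d, n_attacker = n_a,
                                    ratio = ratio, row.names = NULL),
       mean = if (any(ok)) mean(ratio[ok]) else NA_real_,
       sem = if (sum(ok) > 1) stats::sd(ratio[ok]) / sqrt(sum(ok)) else NA_real_,
       overall = if (sum(n_a) > 0) sum(n_d) / sum(n_a) else NA_real_)
}

#' Inter-switch interval analysis (memorylessness)
#'
#' Within-trial intervals between consecutive direction changes of one
#' agent: histogram, empirical survival curve, and a maximum-likelihood
#' exponential rate fitted to the tail beyond `tail_start` (default 0.5 s,
#' past the refractory-induced interval mode). For a memoryless switching
#' process the tail is exponential and the fitted rate recovers the hazard.
#'
#' @param events event data.frame (from [detect_changes_trialset()] or
#'   [detect_direction_changes()]); intervals are computed within trial.
#' @param bin_width histogram bin width in s (default 0.05).
#' @param tail_start left edge in s of the tail used for the rate fit.
#' @param trial_ends optional named numeric vector of trial end times (s),
#'   names = trial ids. When supplied, the open interval from each trial's
#'   last event to the trial end enters the tail fit as right-censored
#'   exposure, giving the proper censored exponential MLE
#'   `rate = n_events / total_exposure` (ignoring censoring overestimates
#'   the rate, because trial ends cut off long intervals).
#' @return list: `intervals` (s), `histogram` (data.frame mid/count/
#'   rel_freq), `survival` (data.frame t/S), `tail_rate` (1/s), `n_tail`,
#'   `low_confidence` (fewer than 10 tail intervals).
#' @export
interval_analysis <- function(events, bin_width = 0.05, tail_start = 0.5,
                              trial_ends = NULL) {
  by_trial <- split(events$time, events$trial_id)
  ivs <- unlist(lapply(by_trial, function(tt) {
    if (length(tt) >= 2) diff(sort(tt)) else numeric(0)
  }), use.names = FALSE)
  if (!length(ivs))
    return(list(intervals = numeric(0), histogram = NULL, survival = NULL,
                tail_rate = NA_real_, n_tail = 0L, low_confidence = TRUE))
  brk <- seq(0, max(ivs) + bin_width, by = bin_width)
  h <- hist(ivs, breaks = brk, plot = FALSE)
  srt <- sort(ivs)
  surv <- data.frame(t = srt, S = 1 - seq_along(srt) / length(srt))
  tail_iv <- ivs[ivs > tail_start]
  n_tail <- length(tail_iv)
  exposure <- sum(tail_iv - tail_start)
  if (!is.null(trial_ends)) {
    cens <- vapply(names(by_trial), function(id) {
      te <- trial_ends[[id]]
      if (is.null(te) || !length(by_trial[[id]])) return(0)
      max(te - max(by_trial[[id]]) - tail_start, 0)
    }, numeric(1))
    exposure <- exposure + sum(cens)
  }
  rate <- if (n_tail > 0 && exposure > 0) n_tail / exposure else NA_real_
  list(intervals = ivs,
       histogram = data.frame(mid = h$mids, count = h$counts,
                              rel_freq = h$counts / length(ivs)),
       survival = surv, tail_rate = rate, n_tail = n_tail,
       low_confidence = n_tail < 10L)
}

#' Speed saturation check
#'
#' Fraction of velocity samples with speed above 90% of the 5.5 cm/s cap,
#' per agent (and per condition if the set mixes conditions). In the
#' recorded data this exceeds 0.9 everywhere, which is what licenses the
#' focus on movement *direction*.
#'
#' @param ts a `trialset`.
#' @param threshold fraction of the cap (default 0.9).
#' @return data.frame: `condition`, `agent`, `prop_above`, `n_samples`.
#' @export
speed_saturation <- function(ts, threshold = 0.9) {
  rows <- list()
  for (cond in unique(ts$manifest$condition)) {
    sel <- ts$trials[ts$manifest$condition == cond]
    for (agent in c("attacker", "defender")) {
      above <- 0L; total <- 0L
      for (tr in sel) {
        v <- velocities(tr, agent)
        lim <- threshold * MAX_SPEED / tr$sample_rate  # cm per interval
        above <- above + sum(v$speed > lim)
        total <- total + length(v$speed)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, agent = agent,
        prop_above = above / total, n_samples = total)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Direction changes binned by interpersonal distance
#'
#' Time spent, change counts and change frequency per second as a function
#' of the center-to-center distance between the agents, binned at
#' `bin_width` (default 0.1 cm = 1 mm).
#'
#' @param ts a `trialset`.
#' @param agent agent whose changes are counted.
#' @param bin_width distance bin width in cm.
#' @return data.frame: `dist_lo`, `dist_hi`, `time_spent`, `n_changes`,
#'   `freq_per_s` (NA where no time was spent).
#' @export
distance_binned_changes <- function(ts, agent = c("attacker", "defender"),
                                    bin_width = 0.1) {
  agent <- match.arg(agent)
  dmax <- 0
  dists <- vector("list", length(ts$trials)); evbin <- list()
  for (k in seq_along(ts$trials)) {
    tr <- ts$trials[[k]]
    dd <- sqrt(rowSums((tr$attacker_xy - tr$defender_xy)^2))
    dists[[k]] <- list(d = dd, fs = tr$sample_rate)
    dmax <- max(dmax, max(dd))
    ev <- detect_direction_changes(tr, agent)
    if (nrow(ev)) evbin[[length(evbin) + 1L]] <- dd[ev$sample_index]
  }
  nb <- max(1L, ceiling(dmax / bin_width))
  time_spent <- numeric(nb); n_changes <- numeric(nb)
  bin_of <- function(d) pmin(pmax(ceiling(d / bin_width), 1L), nb)
  for (x in dists)
    time_spent <- time_spent + tabulate(bin_of(x$d), nb) / x$fs
  for (d in evbin)
    n_changes <- n_changes + tabulate(bin_of(d), nb)
  data.frame(dist_lo = (seq_len(nb) - 1) * bin_width,
             dist_hi = seq_len(nb) * bin_width,
             time_spent = time_spent, n_changes = n_changes,
             freq_per_s = ifelse(time_spent > 0, n_changes / time_spent, NA_real_))
}

#' Condition-level behavioral summary of a trial set
#'
#' Convenience wrapper computing the headline descriptive statistics:
#' heading-change entropy, short-latency response proportion, defender /
#' attacker change ratio, speed saturation, outcome proportions and mean
#' trial duration.
#'
#' @param ts a `trialset` (single condition).
#' @param rate analysis rate for the entropy (Hz).
#' @param bin_width entropy histogram bin width (degrees).
#' @return named list of summary statistics.
#' @export
behavior_summary <- function(ts, rate = 20, bin_width = 5) {
  rec <- response_records(ts)
  hh <- heading_change_histogram(ts, "attacker", bin_width = bin_width, rate = rate)
  cr <- change_ratio(ts)
  sat <- speed_saturation(ts)
  out_tab <- table(ts$manifest$outcome)
  list(condition = unique(ts$manifest$condition),
       n_trials = length(ts$trials),
       entropy_bits = entropy(hh),
       short_latency_prop = short_latency_proportion(rec, by_participant = TRUE),
       n_responses = nrow(rec),
       change_ratio_mean = cr$mean, change_ratio_sem = cr$sem,
       speed_saturation = sat,
       outcome_props = as.list(out_tab / sum(out_tab)),
       mean_duration_s = mean(ts$manifest$duration))
}
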