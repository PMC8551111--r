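# Trial-set file I/O: one CSV per trial plus a JSON manifest.
#
# CSV dialect: header `t_index,ax,ay,dx,dy`, comma separated, decimal point,
# UTF-8, positions written with 17 significant digits so the write/read
# round trip is bit-exact for doubles.

MANIFEST_FILE <- "manifest.json"

#' Write a trial set to disk
#'
#' Writes `manifest.json` plus one `<trial_id>.csv` per trial (columns
#' `t_index, ax, ay, dx, dy`: sample index and attacker/defender positions in
#' cm). Positions are stored with enough digits that
#' `read_trialset(write_trialset(ts))` reproduces them bit-exactly.
#'
#' @param ts a `trialset`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trialset"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path, call. = FALSE)
  }
  for (tr in ts$trials) {
    df <- data.frame(t_index = seq_len(nrow(tr$attacker_xy)) - 1L,
                     ax = tr$attacker_xy[, 1], ay = tr$attacker_xy[, 2],
                     dx = tr$defender_xy[, 1], dy = tr$defender_xy[, 2])
    for (cl in c("ax", "ay", "dx", "dy")) df[[cl]] <- sprintf("%.17g", df[[cl]])
    f <- file.path(path, paste0(tr$trial_id, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  }
  meta <- ts$manifest
  jsonlite::write_json(list(format = "chasepred-trialset", version = 1L,
                            trials = meta),
                       file.path(path, MANIFEST_FILE),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial set from disk
#'
#' Reads the directory layout produced by [write_trialset()]. Malformed
#' trials are reported with the offending file; an empty directory yields an
#' empty trial set with a warning, while a non-empty directory without a
#' manifest is an error.
#'
#' @param path directory containing `manifest.json` and per-trial CSVs.
#' @return a `trialset`.
#' @export
read_trialset <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  mf <- file.path(path, MANIFEST_FILE)
  if (!file.exists(mf)) {
    if (length(list.files(path)) == 0L) {
      warning("empty directory '", path, "': returning empty trialset", call. = FALSE)
      return(trialset(list()))
    }
    stop("missing ", MANIFEST_FILE, " in ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rows <- meta$trials
  if (is.null(rows) || NROW(rows) == 0L) return(trialset(list()))
  trials <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    id <- rows$trial_id[i]
    f <- file.path(path, paste0(id, ".csv"))
    if (!file.exists(f)) stop("trial '", id, "': missing file ", f, call. = FALSE)
    df <- data.table::fread(f, colClasses = list(double = c("ax", "ay", "dx", "dy")),
                            data.table = FALSE)
    need <- c("t_index", "ax", "ay", "dx", "dy")
    if (!all(need %in% names(df)))
      stop("trial '", id, "' (", f, "): expected columns ",
           paste(need, collapse = ","), call. = FALSE)
    bad <- which(!stats::complete.cases(df[need]))
    if (length(bad))
      stop("trial '", id, "' (", f, "): malformed row at data line ", bad[1],
           call. = FALSE)
    trials[[i]] <- chase_trial(
      trial_id = id,
      attacker_xy = cbind(df$ax, df$ay),
      defender_xy = cbind(df$dx, df$dy),
      condition = rows$condition[i],
      sample_rate = rows$sample_rate[i],
      outcome = rows$outcome[i],
      participant_pair = rows$participant_pair[i],
      defender_participant = rows$defender_participant[i])
  }
  ts <- trialset(trials)
  ts
}
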