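#' Read spike events from delimited text
#'
#' Expects a header `unit_id,trial_id,time_s` (comma or tab separated).
#' Events are grouped by unit and trial; units and trials are ordered by
#' first appearance unless explicit id vectors are given.
#'
#' @param path file path
#' @param unit_ids,trial_ids optional id universes (so silent units / empty
#'   trials survive a round trip)
#' @return a [spike_train_set()]
#' @export
read_spike_events <- function(path, unit_ids = NULL, trial_ids = NULL) {
  df <- read_delimited(path, c("unit_id", "trial_id", "time_s"))
  df$time_s <- suppressWarnings(as.numeric(df$time_s))
  if (nrow(df) && anyNA(df$time_s)) {
    bad <- which(is.na(df$time_s))[1]
    stop(sprintf("malformed time_s at data line %d of %s", bad, path))
  }
  if (is.null(unit_ids)) unit_ids <- unique(df$unit_id)
  if (is.null(trial_ids)) trial_ids <- unique(df$trial_id)
  spikes <- lapply(unit_ids, function(u) {
    du <- df[df$unit_id == u, ]
    lapply(trial_ids, function(k) sort(du$time_s[du$trial_id == k]))
  })
  # sort() canonicalizes file order; ascending-within-train is then checked
  # against duplicates/negatives by the constructor
  spike_train_set(spikes, unit_ids, trial_ids)
}

#' Write spike events as delimited text
#'
#' Canonical order: unit, then trial, then time. `write(read(f))` is
#' byte-identical for a file already in canonical order.
#'
#' @param sts a [spike_train_set()]
#' @param path output path
#' @param sep field separator (default tab)
#' @export
write_spike_events <- function(sts, path, sep = "\t") {
  rows <- list()
  for (u in seq_len(sts$n_units)) {
    for (k in seq_len(sts$n_trials)) {
      tr <- sts$spikes[[u]][[k]]
      if (length(tr))
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = sts$unit_ids[u], trial_id = sts$trial_ids[k], time_s = tr)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(), trial_id = character(),
               time_s = numeric())
  write.table(format_num_df(df), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a trial table from delimited text
#' @param path file path
#' @return a [trial_table()]
#' @export
read_trial_table <- function(path) {
  df <- read_delimited(path, c("trial_id", "target_direction", "t_instruction",
                               "t_go", "t_movement_onset", "t_acquisition",
                               "correct"))
  num <- function(v) suppressWarnings(as.numeric(v))
  trial_table(df$trial_id, num(df$target_direction), num(df$t_instruction),
              num(df$t_go), num(df$t_movement_onset), num(df$t_acquisition),
              as.logical(df$correct),
              t_end = if ("t_end" %in% names(df)) num(df$t_end) else
                num(df$t_acquisition) + 0.5)
}

#' Write a trial table
#' @param trials a [trial_table()]
#' @param path output path
#' @param sep field separator
#' @export
write_trial_table <- function(trials, path, sep = "\t") {
  keep <- intersect(c("trial_id", "target_direction", "t_instruction", "t_go",
                      "t_movement_onset", "t_acquisition", "t_end", "correct",
                      "included"), names(trials))
  write.table(format_num_df(as.data.frame(trials)[, keep]), path, sep = sep,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read kinematics traces (`trial_id,t,x,y`)
#' @param path file path
#' @return named list of [kinematics_trace()] objects, one per trial id
#' @export
read_kinematics <- function(path) {
  df <- read_delimited(path, c("trial_id", "t", "x", "y"))
  for (v in c("t", "x", "y")) df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  out <- lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$t), ]
    kinematics_trace(d$t, d$x, d$y)
  })
  out[unique(df$trial_id)]
}

#' Write kinematics traces
#' @param kin named list of [kinematics_trace()] objects
#' @param path output path
#' @param sep field separator
#' @export
write_kinematics <- function(kin, path, sep = "\t") {
  df <- do.call(rbind, lapply(names(kin), function(id)
    data.frame(trial_id = id, t = kin[[id]]$t, x = kin[[id]]$x,
               y = kin[[id]]$y)))
  write.table(format_num_df(df), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a functional network (dense text matrix + JSON sidecar)
#'
#' The adjacency goes to `<path>` as a dense whitespace-delimited matrix;
#' unit ids and window metadata go to `<path>.json`.
#'
#' @param fn a [functional_network()]
#' @param path output path for the matrix
#' @export
write_fn <- function(fn, path) {
  write.table(fn$weights, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(unit_ids = fn$unit_ids, window = fn$window,
               trial_id = fn$trial_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a functional network written by [write_fn()]
#' @param path matrix path (sidecar at `<path>.json`)
#' @return a [functional_network()]
#' @export
read_fn <- function(path) {
  w <- as.matrix(read.table(path, header = FALSE))
  dimnames(w) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  functional_network(w, unit_ids = meta$unit_ids, window = meta$window,
                     trial_id = meta$trial_id)
}

read_delimited <- function(path, required) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               colClasses = "character", fill = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df
}

# fixed-notation numbers so written tables are locale/round-trip stable
format_num_df <- function(df) {
  for (v in names(df))
    if (is.numeric(df[[v]]))
      df[[v]] <- formatC(df[[v]], format = "g", digits = 15)
  df
}
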