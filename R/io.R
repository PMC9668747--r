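# Plain-text persistence: behaviour log CSV, trace matrices, run configs.

#' Write a behaviour session to CSV
#'
#' Columns: time_s, position_cm, velocity_cms, lick, lap_index.  Session
#' attributes (environment, reward/cue position, belt length, frame rate)
#' go to a JSON sidecar with the same stem.
#'
#' @param behavior a \code{\link{BehaviorSession}}.
#' @param path output CSV path.
#' @return invisibly, the path
#' @export
writeBehaviorCsv <- function(behavior, path) {
  df <- data.frame(time_s = behavior@time, position_cm = behavior@position,
                   velocity_cms = behavior@velocity, lick = behavior@lick,
                   lap_index = behavior@lapIndex)
  write.csv(df, path, row.names = FALSE)
  meta <- list(environment = behavior@environment,
               reward_position_cm = behavior@rewardPosition,
               cue_position_cm = behavior@cuePosition,
               belt_length_cm = behavior@beltLength,
               frame_rate_hz = behavior@frameRate)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a behaviour session from CSV
#'
#' @param path CSV written by \code{\link{writeBehaviorCsv}} (the JSON
#'   sidecar must sit next to it).
#' @return a \code{\link{BehaviorSession}}
#' @export
readBehaviorCsv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  cue <- meta$cue_position_cm
  obj <- new("BehaviorSession",
    time = df$time_s, position = df$position_cm,
    velocity = df$velocity_cms, lick = as.integer(df$lick),
    lapIndex = as.integer(df$lap_index),
    rewardPosition = meta$reward_position_cm,
    cuePosition = if (is.null(cue) || length(cue) == 0) NA_real_ else cue,
    beltLength = meta$belt_length_cm, environment = meta$environment,
    frameRate = meta$frame_rate_hz)
  validObject(obj)
  obj
}

#' Write / read ROI traces as CSV
#'
#' The raw fluorescence matrix goes to CSV (one row per ROI, one column
#' per frame, preceded by a roi_size column); frame rate and modality go
#' to a JSON sidecar.  This plain-text container is the entry point for
#' external trace data.
#'
#' @param traces a \code{\link{RoiTraceSet}}.
#' @param path output CSV path.
#' @return invisibly, the path
#' @export
writeTracesCsv <- function(traces, path) {
  df <- data.frame(roi_size = roiSize(traces), rawF(traces))
  write.csv(df, path, row.names = FALSE)
  meta <- list(frame_rate_hz = frameRate(traces),
               modality = modality(traces))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTracesCsv
#' @export
readTracesCsv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  F <- as.matrix(df[, -1, drop = FALSE])
  dimnames(F) <- NULL
  RoiTraceSet(F, roiSize = as.integer(df$roi_size),
              frameRate = meta$frame_rate_hz, modality = meta$modality)
}

#' Write an activity map as flat CSV
#'
#' One row per (unit, lap, bin) with mean dF/F, occupancy seconds and the
#' significance flag.
#'
#' @param map an \code{\link{ActivityMap}}.
#' @param path output CSV path.
#' @return invisibly, the path
#' @export
writeActivityMapCsv <- function(map, path) {
  d <- dim(map@meanDff)
  grid <- expand.grid(unit = seq_len(d[1]), lap = seq_len(d[2]),
                      bin = seq_len(d[3]))
  grid$mean_dff <- as.vector(map@meanDff)
  grid$occupancy_s <- as.vector(map@occupancy[cbind(grid$lap, grid$bin)])
  grid$significant <- as.integer(as.vector(map@significant))
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' The configuration carries a schema version; unknown top-level keys are
#' rejected on read (typo safety).
#'
#' @param config a run configuration list (see \code{\link{defaultRunConfig}}).
#' @param path YAML path.
#' @return invisibly, the path
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  config <- yaml::read_yaml(path)
  known <- names(defaultRunConfig())
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  config
}
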