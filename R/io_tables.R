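# Plain-text interchange: TSV for body-sensor streams, BIDS-style events TSV,
# and a JSON container for lead fields (named members "gain", "grid_mm",
# "spacing_mm", mirroring the datasets of an HDF5 layout).

#' Write a body-sensor stream as TSV
#'
#' Columns are `time_s` followed by one column per channel.
#'
#' @param x a [sensor_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_body_tsv <- function(x, path) {
  stopifnot(inherits(x, "SensorStream"))
  df <- data.table::data.table(time_s = stream_times(x))
  for (i in seq_along(x$labels)) df[[x$labels[i]]] <- x$data[i, ]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a body-sensor TSV into a SensorStream
#'
#' @param path TSV with a `time_s` column and one column per channel; samples
#'   must be uniformly spaced.
#' @param kind stream kind (`"accel"`, `"emg"`, `"pulse"`).
#' @return a [sensor_stream()].
#' @export
read_body_tsv <- function(path, kind = "accel") {
  df <- data.table::fread(path, sep = "\t")
  if (!"time_s" %in% names(df)) stop("TSV format error: missing 'time_s' column")
  t <- df$time_s
  dt <- diff(t)
  if (length(dt) < 1 || any(dt <= 0)) stop("TSV format error: time_s not increasing")
  if (diff(range(dt)) > 1e-6 * median(dt) * 10)
    stop("TSV format error: time_s not uniformly sampled")
  fs <- 1 / median(dt)
  chans <- setdiff(names(df), "time_s")
  data <- t(as.matrix(df[, chans, with = FALSE]))
  sensor_stream(data, fs, chans, kind = kind, start_time = t[1])
}

#' Write a gait event table as BIDS-style events TSV
#'
#' One row per event with `onset`, `duration` (0) and `trial_type` in
#' LHS/RTO/RHS/LTO.
#'
#' @param events a [gait_event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(inherits(events, "GaitEventTable"))
  long <- data.table::data.table(
    onset = c(events$t_LHS, tail(events$t_LHS_next, 1),
              events$t_RTO, events$t_RHS, events$t_LTO),
    duration = 0,
    trial_type = c(rep("LHS", nrow(events) + 1),
                   rep(c("RTO", "RHS", "LTO"), each = nrow(events)))
  )
  data.table::setorder(long, onset)
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' Read a BIDS-style events TSV back into a gait event table
#' @param path events TSV written by [write_events_tsv()].
#' @return a [gait_event_table()].
#' @export
read_events_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("onset", "trial_type") %in% names(df)))
  lhs <- sort(df$onset[df$trial_type == "LHS"])
  if (length(lhs) < 2) stop("events TSV holds fewer than 2 LHS events")
  pick <- function(type, lo, hi) {
    v <- df$onset[df$trial_type == type & df$onset > lo & df$onset < hi]
    if (length(v) == 0) NA_real_ else v[1]
  }
  cyc <- data.frame(
    t_LHS = lhs[-length(lhs)],
    t_RTO = NA_real_, t_RHS = NA_real_, t_LTO = NA_real_,
    t_LHS_next = lhs[-1]
  )
  for (i in seq_len(nrow(cyc))) {
    cyc$t_RTO[i] <- pick("RTO", cyc$t_LHS[i], cyc$t_LHS_next[i])
    cyc$t_RHS[i] <- pick("RHS", cyc$t_LHS[i], cyc$t_LHS_next[i])
    cyc$t_LTO[i] <- pick("LTO", cyc$t_LHS[i], cyc$t_LHS_next[i])
  }
  cyc <- cyc[stats::complete.cases(cyc), , drop = FALSE]
  gait_event_table(cyc)
}

#' Write a lead field to a JSON container
#'
#' Stores the members `gain` (channels x sources x 3), `grid_mm`
#' (sources x 3), `spacing_mm`, and electrode positions.
#'
#' @param lf a `LeadField` (see [make_lead_field()]).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_lead_field <- function(lf, path) {
  stopifnot(inherits(lf, "LeadField"))
  # arrays stored flat in column-major order alongside their dimensions
  obj <- list(gain = as.numeric(lf$gain), dim_gain = dim(lf$gain),
              grid_mm = as.numeric(lf$grid_mm), dim_grid = dim(lf$grid_mm),
              spacing_mm = lf$spacing_mm,
              electrodes_mm = as.numeric(lf$electrodes_mm),
              dim_electrodes = dim(lf$electrodes_mm))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a lead field from its JSON container
#' @param path path written by [write_lead_field()].
#' @return a `LeadField`.
#' @export
read_lead_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gain <- array(as.numeric(obj$gain), dim = obj$dim_gain)
  grid <- matrix(as.numeric(obj$grid_mm), obj$dim_grid[1], obj$dim_grid[2])
  elec <- matrix(as.numeric(obj$electrodes_mm),
                 obj$dim_electrodes[1], obj$dim_electrodes[2])
  new_lead_field(gain, grid, obj$spacing_mm, elec)
}
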