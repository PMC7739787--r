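#' Read a ski run from CSV (+ JSON sidecar metadata)
#'
#' The run format is a plain CSV with header
#' `time_s,knee,hip,acc_x,acc_y,acc_z` (`hip` optional) and a JSON sidecar
#' `<path>.json` holding `skier_id`, `session_id`, `discipline` and
#' `figure_spans`. The sampling rate is inferred from the time column, which
#' must be uniform within 1% of the median interval. Empty cells become
#' missing samples (`NA`), never zero.
#'
#' @param path CSV file path.
#' @param metadata optional named list overriding/replacing the sidecar.
#' @return A `ski_run`.
#' @export
read_run <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "knee", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(df)))
    stop("run CSV must have columns time_s,knee[,hip],acc_x,acc_y,acc_z")
  tt <- df$time_s
  if (anyNA(tt) || is.unsorted(tt, strictly = TRUE))
    stop("time column must be strictly increasing and complete")
  dt <- diff(tt)
  mdt <- stats::median(dt)
  if (any(abs(dt - mdt) > 0.01 * mdt))
    stop("non-uniform sampling: time gaps exceed 1% of the median interval")
  fs <- 1 / mdt
  meta <- list(skier_id = "unknown", session_id = "unknown",
               discipline = "SL", figure_spans = NULL)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(js)] <- js
  }
  if (!is.null(metadata)) meta[names(metadata)] <- metadata
  if (!meta$discipline %in% c("SL", "GS", "SG", "DH"))
    stop("unknown discipline: ", meta$discipline)
  fsp <- meta$figure_spans
  if (!is.null(fsp) && !is.data.frame(fsp)) fsp <- as.data.frame(fsp)
  if (!is.null(fsp) && !nrow(fsp)) fsp <- NULL
  mk <- function(col, units) ts_new(df[[col]], fs, units, t0 = tt[1])
  run_record(knee = mk("knee", "deg"),
             hip = if ("hip" %in% names(df)) mk("hip", "deg") else NULL,
             acc_x = mk("acc_x", "g"), acc_y = mk("acc_y", "g"),
             acc_z = mk("acc_z", "g"),
             skier_id = meta$skier_id, session_id = meta$session_id,
             discipline = meta$discipline, figure_spans = fsp)
}

#' Write a ski run to CSV (+ JSON sidecar metadata)
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces every sample bit-exactly (9 digits, the smallest
#' "pretty" width, cannot represent a double exactly).
#'
#' @param run a `ski_run`.
#' @param path destination CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ski_run"))
  n <- length(run$knee$values)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  df <- data.frame(time_s = fmt(ts_time(run$knee)),
                   knee = fmt(run$knee$values), stringsAsFactors = FALSE)
  if (!is.null(run$hip)) df$hip <- fmt(run$hip$values)
  df$acc_x <- fmt(run$acc_x$values)
  df$acc_y <- fmt(run$acc_y$values)
  df$acc_z <- fmt(run$acc_z$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(skier_id = run$skier_id, session_id = run$session_id,
               discipline = run$discipline,
               figure_spans = run$figure_spans)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Fit the three-posture goniometer calibration
#'
#' Electrogoniometers are calibrated per athlete from three reference
#' postures (standing, seated, crouched) whose joint angles are known from
#' video analysis. An affine map raw -> degrees is fitted by ordinary least
#' squares; the goniometer is assumed linear in angle over the calibrated
#' range. The result is order-invariant in the postures.
#'
#' @param raw_values raw sensor readings at the reference postures.
#' @param reference_angles_deg reference angles in degrees (same length).
#' @return List of class `ski_calibration`: `gain` (deg per raw unit),
#'   `offset` (deg), `residual_rmse` (deg, root of the mean squared
#'   residual).
#' @examples
#' fit_calibration(c(0, 1, 2), c(0, 90, 180))  # gain 90, offset 0
#' @export
fit_calibration <- function(raw_values, reference_angles_deg) {
  stopifnot(length(raw_values) == length(reference_angles_deg),
            length(raw_values) >= 2)
  if (length(unique(raw_values)) < 2)
    stop("degenerate calibration: all raw values equal")
  fit <- stats::lm(reference_angles_deg ~ raw_values)
  structure(list(gain = unname(stats::coef(fit)[2]),
                 offset = unname(stats::coef(fit)[1]),
                 residual_rmse = sqrt(mean(stats::residuals(fit)^2))),
            class = "ski_calibration")
}

#' @export
print.ski_calibration <- function(x, ...) {
  cat(sprintf("<ski_calibration> deg = %.6g * raw + %.6g (rmse %.3g deg)\n",
              x$gain, x$offset, x$residual_rmse))
  invisible(x)
}

#' Apply a calibration to a raw goniometer channel
#'
#' @param ts `ski_ts` with units `"raw"`.
#' @param cal a `ski_calibration`.
#' @return `ski_ts` in degrees.
#' @export
apply_calibration <- function(ts, cal) {
  stopifnot(inherits(ts, "ski_ts"), inherits(cal, "ski_calibration"))
  if (ts$units != "raw")
    stop("apply_calibration expects a raw-unit channel, got ", ts$units)
  ts_new(cal$gain * ts$values + cal$offset, ts$fs, "deg", ts$t0)
}

#' Write a per-cycle metrics table to CSV
#'
#' @param metrics data frame from [summarize_run()] and friends.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
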