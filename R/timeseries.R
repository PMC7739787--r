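#' Uniformly sampled scalar channel
#'
#' Lightweight container for one sensor channel: a numeric vector sampled at a
#' constant rate, with physical units and a start time. All signal-processing
#' functions in the package operate on these objects (or on bare numeric
#' vectors where the sample rate is irrelevant).
#'
#' @param values numeric vector of samples; `NA` marks missing samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param units one of `"deg"`, `"deg/s"`, `"g"`, `"raw"`.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `ski_ts`.
#' @examples
#' ts <- ts_new(sin(seq(0, 10, by = 1 / 148.15)), fs = 148.15, units = "deg")
#' ts_time(ts)[1:3]
#' @export
ts_new <- function(values, fs, units = c("deg", "deg/s", "g", "raw"), t0 = 0) {
  units <- match.arg(units)
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 units = units, t0 = as.numeric(t0)),
            class = "ski_ts")
}

#' @rdname ts_new
#' @param ts a `ski_ts` object.
#' @return `ts_time()` returns the sample times in seconds.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "ski_ts"))
  ts$t0 + (seq_along(ts$values) - 1) / ts$fs
}

#' @export
print.ski_ts <- function(x, ...) {
  cat(sprintf("<ski_ts> %d samples @ %.4g Hz [%s], t0 = %.3f s\n",
              length(x$values), x$fs, x$units, x$t0))
  invisible(x)
}

#' @export
length.ski_ts <- function(x) length(x$values)

# Coerce ski_ts or numeric to a bare numeric vector.
ts_values <- function(x) if (inherits(x, "ski_ts")) x$values else as.numeric(x)

#' One ski run: all channels plus metadata
#'
#' Bundles the goniometer and accelerometer channels of a single run with its
#' identifying metadata. All channels must share the sampling rate and length.
#' `figure_spans` lists course sections (double/triple gates, banana, jumps)
#' to exclude from analysis, as a data frame with columns `start_s`, `end_s`,
#' `label`.
#'
#' @param knee,hip `ski_ts` joint-angle channels in degrees of extension
#'   (larger = more extended; full knee extension is about 180 deg). `hip`
#'   may be `NULL`.
#' @param acc_x,acc_y,acc_z `ski_ts` trunk acceleration channels in g.
#' @param skier_id,session_id character identifiers; `session_id` is the
#'   skier-session triplet (skier, day, discipline) used as random-effect
#'   grouping factor in the statistics module.
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @param figure_spans data frame (`start_s`, `end_s`, `label`) or `NULL`.
#' @return An object of class `ski_run`.
#' @export
run_record <- function(knee, hip = NULL, acc_x, acc_y, acc_z,
                       skier_id = "unknown", session_id = "unknown",
                       discipline = c("SL", "GS", "SG", "DH"),
                       figure_spans = NULL) {
  discipline <- match.arg(discipline)
  chans <- list(knee = knee, acc_x = acc_x, acc_y = acc_y, acc_z = acc_z)
  if (!is.null(hip)) chans$hip <- hip
  for (nm in names(chans)) {
    if (!inherits(chans[[nm]], "ski_ts"))
      stop("channel `", nm, "` must be a ski_ts")
  }
  fs <- vapply(chans, function(ts) ts$fs, numeric(1))
  n <- vapply(chans, function(ts) length(ts$values), numeric(1))
  if (length(unique(fs)) != 1L || length(unique(n)) != 1L)
    stop("all channels must share the same sampling rate and length")
  if (is.null(figure_spans)) {
    figure_spans <- data.frame(start_s = numeric(0), end_s = numeric(0),
                               label = character(0))
  } else {
    stopifnot(all(c("start_s", "end_s", "label") %in% names(figure_spans)))
    figure_spans <- figure_spans[, c("start_s", "end_s", "label")]
  }
  structure(list(knee = knee, hip = hip, acc_x = acc_x, acc_y = acc_y,
                 acc_z = acc_z, skier_id = skier_id, session_id = session_id,
                 discipline = discipline, figure_spans = figure_spans),
            class = "ski_run")
}

#' @export
print.ski_run <- function(x, ...) {
  cat(sprintf("<ski_run> %s | skier %s | session %s | %d samples @ %.4g Hz%s\n",
              x$discipline, x$skier_id, x$session_id,
              length(x$knee$values), x$knee$fs,
              if (is.null(x$hip)) " | no hip" else ""))
  if (nrow(x$figure_spans))
    cat(sprintf("  %d figure span(s) flagged for exclusion\n",
                nrow(x$figure_spans)))
  invisible(x)
}
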