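#' Angular velocity by central differences
#'
#' First derivative of a (filtered) joint-angle signal. Central differences
#' are second-order accurate and phase-free, which matters because the
#' velocity feeds a threshold classifier: a one-sided difference would shift
#' every phase boundary by half a sample. One-sided differences are used at
#' the two endpoints. Sign convention: extension (increasing angle) is
#' positive.
#'
#' @param angle a `ski_ts` in degrees, or a numeric vector plus `fs`.
#' @param fs sampling rate in Hz when `angle` is a bare vector.
#' @return Angular velocity in deg/s, same class as the input.
#' @export
angular_velocity <- function(angle, fs = NULL) {
  x <- ts_values(angle)
  if (inherits(angle, "ski_ts")) fs <- angle$fs
  if (is.null(fs)) stop("`fs` required when `angle` is not a ski_ts")
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  if (inherits(angle, "ski_ts")) ts_new(v, fs, "deg/s", angle$t0) else v
}

#' Velocity-threshold (tripartite) contraction-mode classification
#'
#' Labels every sample eccentric (flexion faster than -threshold), concentric
#' (extension faster than +threshold) or quasi-isometric (the closed window
#' `[-threshold, +threshold]`). The window is closed: a velocity of exactly
#' +/-20 deg/s is quasi-isometric, with strict inequalities bounding the
#' dynamic modes.
#'
#' @param omega angular velocity in deg/s (`ski_ts` or numeric).
#' @param threshold quasi-isometric half-window in deg/s (>= 0), default 20.
#' @return Factor with levels `ECC`, `ISO`, `CON`, one per sample.
#' @export
classify_tripartite <- function(omega, threshold = 20) {
  if (threshold < 0) stop("threshold must be >= 0")
  w <- ts_values(omega)
  out <- rep("ISO", length(w))
  out[w < -threshold] <- "ECC"
  out[w > threshold] <- "CON"
  factor(out, levels = c("ECC", "ISO", "CON"))
}

#' Legacy extrema-based (bipartite) phase classification
#'
#' The traditional partition of a half-cycle: samples from the global maximum
#' to the global minimum angle are the flexion (eccentric) phase, and from
#' minimum to maximum the extension (concentric) phase, wrapping within the
#' segment so every sample is labeled. There is no isometric class. A
#' constant segment has no extrema; it is labeled all-concentric and flagged
#' degenerate.
#'
#' @param angle angle samples of one half-cycle (`ski_ts` or numeric).
#' @return Factor with levels `ECC`, `CON` and attribute `degenerate`.
#' @export
classify_bipartite <- function(angle) {
  x <- ts_values(angle)
  n <- length(x)
  if (n < 1) stop("empty segment")
  imin <- which.min(x)
  imax <- which.max(x)
  out <- rep("CON", n)
  degenerate <- imin == imax
  if (!degenerate) {
    if (imin == 1 && imax == n) {
      # monotone extension: all concentric
    } else if (imax == 1 && imin == n) {
      out[] <- "ECC"                             # monotone flexion
    } else if (imax < imin) {
      out[imax:(imin - 1)] <- "ECC"              # falling run, no wrap
    } else {
      out[imax:n] <- "ECC"                       # falling run wraps
      if (imin > 1) out[1:(imin - 1)] <- "ECC"
    }
  }
  structure(factor(out, levels = c("ECC", "CON")), degenerate = degenerate)
}

phase_metrics <- function(labels, omega, fs, modes) {
  n <- length(labels)
  out <- list()
  for (m in modes) {
    sel <- labels == m
    k <- sum(sel)
    out[[paste0(tolower(m), "_ms")]] <- k / fs * 1000
    out[[paste0(tolower(m), "_pct")]] <- 100 * k / n
    av <- abs(omega[sel])
    out[[paste0(tolower(m), "_mean_vel")]] <- if (k) mean(av) else NA_real_
    out[[paste0(tolower(m), "_max_vel")]] <- if (k) max(av) else NA_real_
  }
  out
}

#' Per-cycle phase summary for one half-cycle segment
#'
#' Computes, for one joint over one retained half-cycle: the angle extrema,
#' and for both partitions the absolute (ms) and relative (percent of cycle)
#' phase durations plus mean and maximum velocity magnitudes per mode. The
#' tripartite dynamic-mode means exclude quasi-isometric samples (that is the
#' point of the tripartition: the legacy bipartite means dilute dynamic
#' velocities with near-zero samples); bipartite means cover all samples of
#' each phase. Empty modes get zero duration and `NA` velocities.
#'
#' @param angle filtered angle samples of the segment (deg).
#' @param omega angular velocity samples of the segment (deg/s).
#' @param fs sampling rate in Hz.
#' @param threshold quasi-isometric half-window in deg/s.
#' @return One-row data frame; column `bi_degenerate` flags segments with no
#'   angle extrema (constant signal).
#' @export
summarize_cycle <- function(angle, omega, fs, threshold = 20) {
  angle <- ts_values(angle); omega <- ts_values(omega)
  stopifnot(length(angle) == length(omega), length(angle) >= 2)
  tri <- classify_tripartite(omega, threshold)
  bi <- classify_bipartite(angle)
  tri_m <- phase_metrics(tri, omega, fs, c("ECC", "ISO", "CON"))
  bi_m <- phase_metrics(bi, omega, fs, c("ECC", "CON"))
  names(tri_m) <- paste0("tri_", names(tri_m))
  names(bi_m) <- paste0("bi_", names(bi_m))
  row <- c(list(duration_ms = length(angle) / fs * 1000,
                min_angle = min(angle), max_angle = max(angle)),
           tri_m, bi_m,
           list(bi_degenerate = isTRUE(attr(bi, "degenerate"))))
  as.data.frame(row, stringsAsFactors = FALSE)
}
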