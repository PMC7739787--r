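#' Resultant (Euclidean norm) acceleration
#'
#' AccR(g) = sqrt(x^2 + y^2 + z^2) per sample. Turn switches show up as
#' local minima of the low-pass-filtered AccR: at the edge change the skier
#' is unloaded, between switches the centripetal load produces one smooth
#' maximum per half-cycle.
#'
#' @param x,y,z `ski_ts` acceleration channels in g (or numeric vectors of
#'   equal length; then `fs` is required).
#' @param fs sampling rate when bare vectors are given.
#' @return `ski_ts` (units g) or numeric vector.
#' @export
resultant_acceleration <- function(x, y, z, fs = NULL) {
  vx <- ts_values(x); vy <- ts_values(y); vz <- ts_values(z)
  if (length(vx) != length(vy) || length(vx) != length(vz))
    stop("acceleration channels must have equal length")
  r <- sqrt(vx^2 + vy^2 + vz^2)
  if (inherits(x, "ski_ts")) ts_new(r, x$fs, "g", x$t0)
  else if (!is.null(fs)) ts_new(r, fs, "g") else r
}

# prominence of local minima of y (classic peak-prominence on -y)
min_prominences <- function(y, idx) {
  v <- -y
  vapply(idx, function(i) {
    h <- v[i]
    j <- i - 1
    while (j >= 1 && v[j] <= h) j <- j - 1
    left <- min(v[max(j, 1):i])
    j <- i + 1
    while (j <= length(v) && v[j] <= h) j <- j + 1
    right <- min(v[i:min(j, length(v))])
    h - max(left, right)
  }, numeric(1))
}

#' Detect turn switches from the resultant acceleration
#'
#' Low-pass filters AccR (default: the standard 4th-order 1 Hz Butterworth,
#' zero phase), then takes strict local minima — negative-to-positive sign
#' changes of the first difference — keeping only minima with prominence at
#' least `min_prominence` and pairwise separation at least `min_separation`
#' (of two close minima the deeper one is kept).
#'
#' `min_separation = "auto"` bootstraps the spacing: a first pass with 0.3 s
#' estimates the median half-cycle duration, and a second pass uses 0.4
#' times that median.
#'
#' @param accr `ski_ts` resultant acceleration.
#' @param spec [filter_spec()] used to smooth AccR before minimum picking.
#' @param min_separation minimum spacing between switches in seconds, or
#'   `"auto"`.
#' @param min_prominence minimum prominence (g) of a retained minimum;
#'   default 0.1 g — low-frequency noise on long quasi-static segments can
#'   carve artifact dips of prominence up to ~0.06 g, while genuine
#'   unweighting minima stay well above 0.15 g.
#' @return Integer vector of switch sample indices (ascending).
#' @export
detect_turn_switches <- function(accr, spec = NULL, min_separation = "auto",
                                 min_prominence = 0.1) {
  stopifnot(inherits(accr, "ski_ts"))
  if (is.null(spec)) spec <- filter_spec(4, 1, accr$fs)
  y <- ts_values(apply_filter(accr, spec))
  d <- diff(y)
  cand <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (!length(cand)) stop("no acceleration minima found (monotone signal?)")
  prom <- min_prominences(y, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) stop("no minima above the prominence floor")
  pick <- function(cand, sep_samples) {
    keep <- integer(0)
    for (i in cand[order(y[cand])]) {          # deepest first
      if (!length(keep) || min(abs(keep - i)) >= sep_samples)
        keep <- c(keep, i)
    }
    sort(keep)
  }
  if (identical(min_separation, "auto")) {
    first <- pick(cand, round(0.3 * accr$fs))
    if (length(first) < 2) stop("too few minima to bootstrap the separation")
    med <- stats::median(diff(first)) / accr$fs
    sep <- 0.4 * med
  } else {
    sep <- min_separation
  }
  out <- pick(cand, round(sep * accr$fs))
  if (!length(out)) stop("no acceleration minima found")
  out
}

#' Cut a run into half-cycle segments at the detected switches
#'
#' Consecutive switch pairs become half-open sample spans
#' `[start_idx, end_idx)`; legs are assigned with [assign_leg()] from the
#' knee angle, and cycle numbers increment once per consecutive IL+OL pair
#' (a "cycle" is two turns).
#'
#' @param run a `ski_run`.
#' @param switches integer switch sample indices (>= 3 of them).
#' @param knee_filtered optional pre-filtered knee angle (`ski_ts`); when
#'   missing the raw knee channel is used for leg assignment.
#' @return Data frame of class `ski_segments`: `start_idx`, `end_idx`, `leg`,
#'   `cycle`, `duration_ms`, `excluded`, `reason`, plus attribute
#'   `leg_confidence`.
#' @export
segment_cycles <- function(run, switches, knee_filtered = NULL) {
  stopifnot(inherits(run, "ski_run"))
  if (length(switches) < 3) stop("need at least 3 switches")
  switches <- sort(as.integer(switches))
  angle <- ts_values(if (is.null(knee_filtered)) run$knee else knee_filtered)
  k <- length(switches) - 1
  start <- switches[seq_len(k)]
  end <- switches[seq_len(k) + 1]
  means <- vapply(seq_len(k), function(i) {
    mean(angle[start[i]:(end[i] - 1)], na.rm = TRUE)
  }, numeric(1))
  la <- assign_leg(means)
  seg <- data.frame(start_idx = start, end_idx = end,
                    leg = as.vector(la),
                    cycle = (seq_len(k) + 1L) %/% 2L,
                    duration_ms = (end - start) / run$knee$fs * 1000,
                    excluded = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  attr(seg, "leg_confidence") <- attr(la, "confidence")
  class(seg) <- c("ski_segments", "data.frame")
  seg
}

#' Assign inside/outside leg from half-cycle mean angles
#'
#' The instrumented (right) leg is the outside leg when extended and the
#' inside leg when flexed, so half-cycles whose mean knee angle exceeds the
#' run median are provisionally OL. A single global alternation phase is
#' then chosen by majority vote over those provisional labels — legs must
#' alternate, and a run-level decision avoids per-segment flips from noisy
#' means. An all-equal degenerate input gets first segment = OL and a
#' low-confidence flag.
#'
#' @param segment_means numeric vector of per-half-cycle mean knee angles.
#' @return Character vector of `"IL"`/`"OL"` with attribute `confidence`
#'   (fraction of provisional labels agreeing with the chosen alternation).
#' @export
assign_leg <- function(segment_means) {
  stopifnot(length(segment_means) >= 1)
  med <- stats::median(segment_means)
  prov <- ifelse(segment_means > med, "OL", "IL")
  k <- length(segment_means)
  pat1 <- rep(c("OL", "IL"), length.out = k)
  pat2 <- rep(c("IL", "OL"), length.out = k)
  a1 <- sum(prov == pat1); a2 <- sum(prov == pat2)
  if (a1 == a2) {
    # tie-break: put OL on the half-cycles with the larger mean angle;
    # if even that ties (all-equal input) default to OL first
    m1 <- mean(segment_means[pat1 == "OL"]); m2 <- mean(segment_means[pat2 == "OL"])
    out <- if (m1 >= m2) pat1 else pat2
    conf <- max(a1, a2) / k
  } else {
    out <- if (a1 > a2) pat1 else pat2
    conf <- max(a1, a2) / k
  }
  structure(out, confidence = conf)
}

#' Apply the exclusion rules to segmented half-cycles
#'
#' Marks as excluded: the first and last full cycle (IL+OL pair) of the run
#' (push-off and finish are not representative), every segment overlapping a
#' figure span (double/triple gates, banana, jumps), and every segment
#' containing missing samples in any channel (such data are systematically
#' discarded rather than imputed).
#'
#' @param segments a `ski_segments` data frame.
#' @param run the `ski_run` the segments index into.
#' @return The segments with `excluded`/`reason` filled in; reasons are
#'   `"first_last"`, `"figure"`, `"missing_data"`.
#' @export
trim_cycles <- function(segments, run) {
  stopifnot(inherits(segments, "ski_segments"), inherits(run, "ski_run"))
  seg <- segments
  if (nrow(seg)) {
    cyc <- seg$cycle
    first_last <- cyc %in% c(min(cyc), max(cyc))
    seg$excluded[first_last] <- TRUE
    seg$reason[first_last] <- "first_last"
    fs <- run$knee$fs
    t0 <- run$knee$t0
    if (nrow(run$figure_spans)) {
      s_t <- t0 + (seg$start_idx - 1) / fs
      e_t <- t0 + (seg$end_idx - 1) / fs
      for (i in seq_len(nrow(run$figure_spans))) {
        ov <- s_t < run$figure_spans$end_s[i] & e_t > run$figure_spans$start_s[i]
        seg$excluded[ov & !seg$excluded] <- TRUE
        seg$reason[ov & is.na(seg$reason)] <- "figure"
        seg$reason[ov & seg$reason != "first_last"] <- "figure"
      }
    }
    chans <- list(run$knee, run$hip, run$acc_x, run$acc_y, run$acc_z)
    na_idx <- sort(unique(unlist(lapply(chans, function(ch) {
      if (is.null(ch)) integer(0) else which(is.na(ch$values))
    }))))
    if (length(na_idx)) {
      for (i in seq_len(nrow(seg))) {
        if (any(na_idx >= seg$start_idx[i] & na_idx < seg$end_idx[i])) {
          if (!seg$excluded[i]) {
            seg$excluded[i] <- TRUE
            seg$reason[i] <- "missing_data"
          }
        }
      }
    }
  }
  seg
}

#' Time-normalize a segment to 0-100% of the half-cycle
#'
#' Linear interpolation of the segment's samples onto `n_points` evenly
#' spaced points spanning 0-100% inclusive; the first and last normalized
#' values equal the original endpoints.
#'
#' @param x segment samples (`ski_ts` or numeric vector, >= 4 samples).
#' @param n_points grid size, default 101 (0, 1, ..., 100 percent).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, n_points = 101) {
  v <- ts_values(x)
  if (length(v) < 4) stop("segment too short to normalize (need >= 4 samples)")
  stats::approx(seq_along(v), v, xout = seq(1, length(v), length.out = n_points))$y
}
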