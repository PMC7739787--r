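#' Run the full per-run analysis pipeline
#'
#' Filters the joint-angle channels (zero-phase Butterworth), detects turn
#' switches from the filtered resultant acceleration, segments the run into
#' IL/OL half-cycles, applies the exclusion rules, and computes the
#' per-cycle phase metrics for the knee (and hip when present) under both
#' the velocity-threshold tripartition and the legacy extrema bipartition.
#'
#' Missing samples are linearly interpolated before filtering (an IIR filter
#' cannot cross an `NA`), but every segment containing an originally missing
#' sample is excluded from the metrics, so imputed values never reach a
#' reported number.
#'
#' @param run a `ski_run`.
#' @param threshold quasi-isometric half-window in deg/s, default 20.
#' @param spec [filter_spec()] for the angle and AccR low-pass.
#' @param min_separation,min_prominence passed to [detect_turn_switches()].
#' @return Data frame with one row per retained (cycle, leg, joint):
#'   identifiers (`run_id`, `id`, `discipline`, `joint`, `leg`, `cycle`),
#'   `duration_ms`, angle extrema, and the `tri_*`/`bi_*` metric columns of
#'   [summarize_cycle()]. The segment table (including excluded segments) is
#'   attached as attribute `"segments"`, the switch indices as
#'   `"switches"`.
#' @export
summarize_run <- function(run, threshold = 20, spec = NULL,
                          min_separation = "auto", min_prominence = 0.1) {
  stopifnot(inherits(run, "ski_run"))
  fs <- run$knee$fs
  if (is.null(spec)) spec <- filter_spec(4, 1, fs)
  impute <- function(ts) {
    v <- ts$values
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      v <- stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
    }
    ts_new(v, ts$fs, ts$units, ts$t0)
  }
  knee_f <- apply_filter(impute(run$knee), spec)
  hip_f <- if (!is.null(run$hip)) apply_filter(impute(run$hip), spec) else NULL
  accr <- resultant_acceleration(impute(run$acc_x), impute(run$acc_y),
                                 impute(run$acc_z))
  switches <- detect_turn_switches(accr, spec = filter_spec(4, 1, fs),
                                   min_separation = min_separation,
                                   min_prominence = min_prominence)
  seg <- segment_cycles(run, switches, knee_filtered = knee_f)
  seg <- trim_cycles(seg, run)
  omega_k <- angular_velocity(knee_f)
  omega_h <- if (!is.null(hip_f)) angular_velocity(hip_f) else NULL
  rows <- list()
  for (i in which(!seg$excluded)) {
    span <- seg$start_idx[i]:(seg$end_idx[i] - 1)
    for (joint in c("knee", if (!is.null(hip_f)) "hip")) {
      ang <- if (joint == "knee") knee_f$values[span] else hip_f$values[span]
      om <- if (joint == "knee") omega_k$values[span] else omega_h$values[span]
      m <- summarize_cycle(ang, om, fs, threshold)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(run_id = run$session_id, id = run$session_id,
                   skier_id = run$skier_id, discipline = run$discipline,
                   joint = joint, leg = seg$leg[i], cycle = seg$cycle[i],
                   stringsAsFactors = FALSE),
        m)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  attr(out, "segments") <- seg
  attr(out, "switches") <- switches
  out
}

#' Simulate a multi-skier metrics dataset through the full pipeline
#'
#' Generates one simulated run per skier-session (each session belongs to a
#' single discipline, mirroring the skier-day-discipline grouping of real
#' data), runs [summarize_run()] on each, and stacks the knee metrics into
#' one table ready for [fit_mixed()]. Between-session variability is
#' injected by perturbing each session's quasi-isometric plateau fractions
#' with a Gaussian of standard deviation `id_iso_sd` (fraction units) and
#' its turn duration by a lognormal factor with cv `id_dur_cv`.
#'
#' @param profiles named list of [discipline_profile()]s to draw from.
#' @param n_ids total number of skier-sessions, allocated round-robin across
#'   the profiles.
#' @param cycles_per_id retained cycles wanted per session (the run is
#'   simulated with two extra cycles that the trimming rule removes).
#' @param id_iso_sd between-session SD of the plateau fractions.
#' @param id_dur_cv between-session cv of the mean turn duration.
#' @param seed master seed; per-session seeds are drawn from it.
#' @param fs sampling rate in Hz.
#' @return Metrics data frame (knee rows only) with an `id` column.
#' @export
simulate_metrics_dataset <- function(profiles = default_profiles(),
                                     n_ids = 10, cycles_per_id = 10,
                                     id_iso_sd = 0.03, id_dur_cv = 0.05,
                                     seed = 1, fs = 148.15) {
  disc <- rep(names(profiles), length.out = n_ids)
  sub_seeds <- with_seed(seed, sample.int(2^31 - 2, n_ids))
  n_turns <- 2 * (cycles_per_id + 2)
  out <- list()
  for (i in seq_len(n_ids)) {
    pr <- profiles[[disc[i]]]
    pert <- with_seed(sub_seeds[i], {
      list(iso = stats::rnorm(2, 0, id_iso_sd),
           dur = stats::rlnorm(1, -id_dur_cv^2 / 2, id_dur_cv))
    })
    pr$iso_plateau_frac_ol <- min(0.9, max(0, pr$iso_plateau_frac_ol + pert$iso[1]))
    pr$iso_plateau_frac_il <- min(0.9, max(0, pr$iso_plateau_frac_il + pert$iso[2]))
    pr$turn_duration_mean <- pr$turn_duration_mean * pert$dur
    sim <- simulate_run(pr, n_turns = n_turns, seed = sub_seeds[i], fs = fs)
    m <- summarize_run(sim$run)
    m <- m[m$joint == "knee", , drop = FALSE]
    m$id <- sprintf("ID%03d", i)
    out[[i]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
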