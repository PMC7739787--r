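#' Low-pass filter specification
#'
#' The package standardizes on a 4th-order Butterworth low-pass with a 1 Hz
#' cut-off, applied forward and backward (zero phase) so that no temporal
#' distortion is introduced: joint-angle signals have discipline natural
#' frequencies of 0.21-0.54 Hz while ski/slope vibrations live above 2 Hz.
#' Attenuation figures are characterized from the single-pass transfer
#' function (the conventional way filter selectivity is reported) even though
#' signals are filtered twice.
#'
#' @param order filter order (>= 1); default 4.
#' @param cutoff -3 dB cut-off frequency in Hz; default 1.
#' @param fs sampling rate in Hz.
#' @param mode `"zero_phase"` (forward-backward) or `"single_pass"`.
#' @return An object of class `ski_filter_spec`.
#' @export
filter_spec <- function(order = 4L, cutoff = 1, fs = 148.15,
                        mode = c("zero_phase", "single_pass")) {
  mode <- match.arg(mode)
  stopifnot(order >= 1, cutoff > 0, fs > 0)
  if (cutoff >= fs / 2)
    stop("cutoff must be below the Nyquist frequency fs/2")
  structure(list(order = as.integer(order), cutoff = cutoff, fs = fs,
                 mode = mode), class = "ski_filter_spec")
}

# Butterworth low-pass coefficients via bilinear transform with frequency
# pre-warping. Returns list(b, a) in descending powers of z^-1, a[1] = 1.
butter_lowpass <- function(order, cutoff, fs) {
  warped <- 2 * fs * tan(pi * cutoff / fs)
  k <- seq_len(order)
  # analog prototype poles, scaled to the warped cutoff (left half-plane)
  p <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  pz <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))    # bilinear-mapped poles
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))    # zeros at z = -1
  # unit DC gain
  gain <- sum(a) / sum(b)
  list(b = b * gain, a = a)
}

poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

#' Design the Butterworth low-pass filter
#'
#' @param spec a [filter_spec()].
#' @return List with numerator `b`, denominator `a` (powers of z^-1) and the
#'   spec, class `ski_filter`.
#' @examples
#' fc <- design_filter(filter_spec())
#' Mod(filter_response(fc, c(0, 1, 2)))  # 1, 1/sqrt(2), ~0.062
#' @export
design_filter <- function(spec) {
  stopifnot(inherits(spec, "ski_filter_spec"))
  co <- butter_lowpass(spec$order, spec$cutoff, spec$fs)
  structure(list(b = co$b, a = co$a, spec = spec), class = "ski_filter")
}

#' Complex frequency response of a designed filter
#'
#' Evaluates the single-pass transfer function H(e^{i 2 pi f / fs}); in
#' zero-phase use the effective magnitude is `Mod(H)^2` with zero phase, but
#' printed attenuation figures refer to the single pass.
#'
#' @param filter a `ski_filter` from [design_filter()] (or a
#'   `ski_filter_spec`, designed on the fly).
#' @param freqs frequencies in Hz.
#' @return Complex vector of responses.
#' @export
filter_response <- function(filter, freqs) {
  if (inherits(filter, "ski_filter_spec")) filter <- design_filter(filter)
  stopifnot(inherits(filter, "ski_filter"))
  w <- 2 * pi * freqs / filter$spec$fs
  ez <- function(coefs, w) {
    k <- seq_along(coefs) - 1
    vapply(w, function(wi) sum(coefs * exp(-1i * wi * k)), complex(1))
  }
  ez(filter$b, w) / ez(filter$a, w)
}

# Direct-form IIR filtering, vectorized through stats::filter:
# MA stage by convolution, AR stage by the recursive filter.
lfilter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb - 1 + seq_along(x)]
  if (length(a) > 1)
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  u
}

# Number of padding samples needed for start-up transients to decay below
# ~1e-9 relative, from the slowest pole of the recursion.
transient_length <- function(a) {
  if (length(a) <= 1) return(1L)
  rho <- max(Mod(polyroot(rev(a))))
  rho <- min(rho, 1 - 1e-8)
  max(3L * (length(a) - 1L), ceiling(log(1e-9) / log(rho)))
}

#' Apply the low-pass filter to a time series
#'
#' In `zero_phase` mode the filter runs forward then backward, which doubles
#' the attenuation in dB and cancels the phase exactly (group delay 0 at all
#' frequencies). Edges are handled by odd-reflection padding long enough for
#' the filter transient to die out; the padding is removed before returning.
#'
#' @param ts a `ski_ts` or numeric vector.
#' @param spec a [filter_spec()]; its `fs` is overridden by the series' own
#'   sampling rate when `ts` is a `ski_ts`.
#' @return Filtered series of the same class and length as the input.
#' @export
apply_filter <- function(ts, spec = filter_spec()) {
  stopifnot(inherits(spec, "ski_filter_spec"))
  x <- ts_values(ts)
  if (inherits(ts, "ski_ts") && !isTRUE(all.equal(ts$fs, spec$fs)))
    spec <- filter_spec(spec$order, spec$cutoff, ts$fs, spec$mode)
  if (anyNA(x)) stop("input contains missing samples; impute or exclude first")
  if (length(x) <= 3 * spec$order)
    stop("input too short: need more than 3x the filter order")
  co <- butter_lowpass(spec$order, spec$cutoff, spec$fs)
  pad <- min(length(x) - 1L, transient_length(co$a))
  y <- if (spec$mode == "single_pass") {
    x0 <- x[1]  # DC offset removal keeps the start-up transient small
    lfilter(co$b, co$a, x - x0) + x0
  } else {
    n <- length(x)
    ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    x0 <- ext[1]
    f1 <- lfilter(co$b, co$a, ext - x0) + x0
    f1 <- rev(f1)
    x1 <- f1[1]
    f2 <- lfilter(co$b, co$a, f1 - x1) + x1
    rev(f2)[pad + seq_len(n)]
  }
  if (inherits(ts, "ski_ts")) ts_new(y, ts$fs, ts$units, ts$t0) else y
}

#' Roll-off slope of the filter's stopband
#'
#' Slope of the single-pass magnitude response, in dB per decade of
#' frequency, evaluated between 10x and 100x the cutoff on a digital design
#' at a sampling rate far above the cutoff (so bilinear warping is
#' negligible). A Butterworth filter of order n rolls off at -20 n dB/decade;
#' the default 4th-order design gives -80 dB/decade.
#'
#' @param spec a [filter_spec()].
#' @return Slope in dB/decade (negative).
#' @export
rolloff_slope <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "ski_filter_spec"))
  fs_hi <- 4000 * spec$cutoff
  fc <- design_filter(filter_spec(spec$order, spec$cutoff, fs_hi, spec$mode))
  h <- Mod(filter_response(fc, c(10, 100) * spec$cutoff))
  20 * (log10(h[2]) - log10(h[1]))
}

#' One-sided amplitude spectral density and dominant frequency
#'
#' Computes the one-sided amplitude spectral density (ASD, signal units per
#' sqrt(Hz)) of a linearly detrended series, and locates the natural
#' frequency as the ASD maximum above a 0.05 Hz floor (excluding slow drift;
#' discipline natural frequencies are >= 0.21 Hz). The ASD is normalized so
#' that `sum(asd^2) * df` equals the mean square of the detrended signal
#' (discrete Parseval identity).
#'
#' @param ts a `ski_ts` (or numeric vector plus `fs`).
#' @param fs sampling rate in Hz, required when `ts` is a bare vector.
#' @param floor_hz lower bound of the natural-frequency search (Hz).
#' @return List of class `ski_spectrum` with `freqs`, `asd`, `natural_freq`.
#' @export
spectrum_report <- function(ts, fs = NULL, floor_hz = 0.05) {
  x <- ts_values(ts)
  if (inherits(ts, "ski_ts")) fs <- ts$fs
  if (is.null(fs)) stop("`fs` required when `ts` is not a ski_ts")
  n <- length(x)
  if (n < 64) stop("need at least 64 samples for a spectrum")
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ tt))   # linear detrend
  X <- stats::fft(x)
  nf <- floor(n / 2)
  k <- seq_len(nf)                           # exclude DC
  df <- fs / n
  scale <- rep(2, nf)
  if (n %% 2 == 0) scale[nf] <- 1            # Nyquist bin is not doubled
  psd <- scale * Mod(X[k + 1])^2 / (n * fs)
  asd <- sqrt(psd)
  freqs <- k * df
  sel <- freqs >= floor_hz
  natural <- freqs[sel][which.max(asd[sel])]
  structure(list(freqs = freqs, asd = asd, natural_freq = natural),
            class = "ski_spectrum")
}

#' @export
print.ski_spectrum <- function(x, ...) {
  cat(sprintf("<ski_spectrum> %d bins, df = %.4g Hz, natural_freq = %.3g Hz\n",
              length(x$freqs), x$freqs[2] - x$freqs[1], x$natural_freq))
  invisible(x)
}

#' Render a raw-vs-filtered overview (time and spectral domain)
#'
#' Two panels for one channel: the raw and low-pass-filtered signal in the
#' time domain, and their one-sided amplitude spectral densities on
#' log-log axes with the cutoff marked — the inspection plot used to choose
#' the cut-off frequency.
#'
#' @param ts a `ski_ts` channel (e.g. a knee angle).
#' @param spec [filter_spec()] applied for the comparison.
#' @param file output `.png` path; `NULL` draws on the active device.
#' @param title panel title prefix.
#' @param width,height image size in pixels.
#' @return `file`, invisibly.
#' @export
render_spectrum <- function(ts, spec = NULL, file = NULL, title = "knee",
                            width = 1200, height = 500) {
  stopifnot(inherits(ts, "ski_ts"))
  if (is.null(spec)) spec <- filter_spec(4, 1, ts$fs)
  filt <- apply_filter(ts, spec)
  sp_raw <- spectrum_report(ts)
  sp_fil <- spectrum_report(filt)
  if (!is.null(file)) grDevices::png(file, width = width, height = height)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  tt <- ts_time(ts)
  graphics::plot(tt, ts$values, type = "l", col = "steelblue",
                 xlab = "time (s)", ylab = paste0(title, " (", ts$units, ")"),
                 main = paste(title, "- time domain"))
  graphics::lines(tt, filt$values, col = "firebrick", lwd = 1.5)
  graphics::legend("topright", c("raw", "filtered"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  keep <- sp_raw$freqs > 0 & sp_raw$asd > 0
  graphics::plot(sp_raw$freqs[keep], sp_raw$asd[keep], type = "l", log = "xy",
                 col = "steelblue", xlab = "frequency (Hz)",
                 ylab = "amplitude spectral density",
                 main = paste(title, "- spectral domain"))
  keep2 <- sp_fil$freqs > 0 & sp_fil$asd > 0
  graphics::lines(sp_fil$freqs[keep2], sp_fil$asd[keep2], col = "firebrick")
  graphics::abline(v = spec$cutoff, lty = 2)
  invisible(file)
}
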