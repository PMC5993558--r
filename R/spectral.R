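# Power-spectrum estimation (Welch averaged periodogram) and the derived
# observables: dominant peaks, band peak power, suppression and entrainment
# scans.

welch_psd <- function(x, fs, segment, overlap, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  x <- x - mean(x)
  N <- min(n, round(segment * fs))
  step <- max(1, round(N * (1 - overlap)))
  w <- if (taper == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / N) else rep(1, N)
  nseg <- max(1, floor((n - N) / step) + 1)
  P <- numeric(N)
  for (k in seq_len(nseg) - 1) {
    xs <- x[(k * step + 1):(k * step + N)] * w
    P <- P + abs(stats::fft(xs))^2
  }
  P <- P / nseg / (fs * sum(w^2))
  f <- (seq_len(N) - 1) * fs / N
  keep <- f <= fs / 2
  # one-sided density: double everything except DC (and Nyquist if present)
  P2 <- 2 * P[keep]
  P2[1] <- P[1]
  if (N %% 2 == 0) P2[length(P2)] <- P[keep][length(P2)]
  list(freq = f[keep], power = P2, nseg = nseg, seg_len = N)
}

#' Power spectrum of a simulated rate series
#'
#' Mean-removed, Hann-tapered averaged periodogram (Welch estimate) of a
#' population rate field over a time window of a simulation, or of a raw
#' uniformly sampled series.
#'
#' @param x a `ctbg_sim` from [simulate_ctbg()], or a numeric series.
#' @param population population label when `x` is a simulation (default the
#'   subthalamic nucleus, `"z"`).
#' @param t_start,t_end analysis window (s) inside the simulated span.
#' @param fs sampling rate (Hz); required when `x` is a numeric series,
#'   inferred from the simulation otherwise.
#' @param segment segment length (s) of the averaged periodogram; the
#'   frequency resolution is `1/segment`.  Use `segment = t_end - t_start`
#'   for a single maximally resolved periodogram.
#' @param overlap fractional segment overlap.
#' @param taper `"hann"` (default) or `"none"`.
#' @return An object of class `ctbg_spectrum`: list with `freq` (Hz,
#'   0 to Nyquist), `power` (one-sided density, s^-2 Hz^-1 for rate input)
#'   and `meta`.
#' @export
power_spectrum <- function(x, population = "z", t_start = NULL, t_end = NULL,
                           fs = NULL, segment = 4, overlap = 0.5,
                           taper = "hann") {
  src <- "series"
  if (inherits(x, "ctbg_sim")) {
    fs <- 1 / (x$meta$dt * x$meta$thin)
    tt <- x$time
    if (is.null(t_start)) t_start <- tt[1]
    if (is.null(t_end)) t_end <- tt[length(tt)]
    if (t_start < tt[1] - 1e-9 || t_end > tt[length(tt)] + 1e-9)
      stop("analysis window outside the simulated span")
    keep <- tt >= t_start - 1e-12 & tt <= t_end + 1e-12
    series <- x$phi[keep, population]
    src <- population
  } else {
    if (is.null(fs)) stop("fs is required for a plain numeric series")
    series <- as.numeric(x)
    if (!is.null(t_start) || !is.null(t_end)) {
      tt <- (seq_along(series) - 1) / fs
      if (is.null(t_start)) t_start <- 0
      if (is.null(t_end)) t_end <- tt[length(tt)]
      if (t_end > tt[length(tt)] + 1e-9) stop("analysis window outside series")
      series <- series[tt >= t_start - 1e-12 & tt <= t_end + 1e-12]
    }
  }
  if (length(series) < 16) stop("window too short")
  est <- welch_psd(series, fs, segment, overlap, taper)
  structure(
    list(freq = est$freq, power = est$power,
         meta = list(source = src, fs = fs, t_start = t_start, t_end = t_end,
                     segment = segment, overlap = overlap, taper = taper,
                     n_segments = est$nseg,
                     resolution = fs / est$seg_len)),
    class = "ctbg_spectrum"
  )
}

#' @export
print.ctbg_spectrum <- function(x, ...) {
  cat(sprintf(
    "CTBG spectrum of '%s': %d bins to %.4g Hz (resolution %.4g Hz, %d segments)\n",
    x$meta$source, length(x$freq), max(x$freq), x$meta$resolution,
    x$meta$n_segments))
  pk <- dominant_peak(x, max(x$meta$resolution, 0.5), min(60, max(x$freq)))
  cat(sprintf("  dominant non-DC peak below 60 Hz: %.4g Hz (power %.4g)\n",
              pk$frequency, pk$power))
  invisible(x)
}

band_index <- function(spec, f_lo, f_hi) {
  if (f_lo <= 0) stop("f_lo must be positive (DC excluded)")
  if (f_hi <= f_lo) stop("empty band")
  k <- which(spec$freq >= f_lo & spec$freq <= f_hi)
  if (!length(k)) stop("no frequency bins inside the band")
  k
}

#' Dominant spectral peak in a band
#'
#' @param spec a `ctbg_spectrum`.
#' @param f_lo,f_hi band limits (Hz), `f_lo > 0`.
#' @return List with `frequency` (Hz) and `power`; ties break toward the
#'   lower frequency.
#' @export
dominant_peak <- function(spec, f_lo, f_hi) {
  k <- band_index(spec, f_lo, f_hi)
  i <- k[which.max(spec$power[k])]   # which.max returns the first maximum
  list(frequency = spec$freq[i], power = spec$power[i])
}

#' Peak spectral power in a band
#'
#' Maximum of the spectral density inside a band, optionally masking bins
#' near the harmonics of a stimulus frequency so that a stimulus line inside
#' the band is not mistaken for intrinsic activity.
#'
#' @inheritParams dominant_peak
#' @param exclude_harmonics_of optional frequency (Hz) whose harmonics are
#'   masked.
#' @param exclude_halfwidth half-width of the mask around each harmonic (Hz).
#' @return Peak power (density units).
#' @export
band_peak_power <- function(spec, f_lo, f_hi, exclude_harmonics_of = NULL,
                            exclude_halfwidth = 0.5) {
  k <- band_index(spec, f_lo, f_hi)
  if (!is.null(exclude_harmonics_of) && exclude_harmonics_of > 0 &&
      exclude_harmonics_of <= f_hi + exclude_halfwidth) {
    harm <- seq(exclude_harmonics_of, f_hi + exclude_halfwidth,
                by = exclude_harmonics_of)
    masked <- rep(FALSE, length(k))
    for (h in harm)
      masked <- masked | abs(spec$freq[k] - h) <= exclude_halfwidth
    if (all(masked)) return(0)
    k <- k[!masked]
  }
  max(spec$power[k])
}

#' Beta-band suppression as a function of DBS pulse frequency
#'
#' For each stimulus frequency, simulates the stimulated system and measures
#' the peak spectral power of the STN rate inside a band, together with an
#' unstimulated baseline.  Stimulus harmonics falling inside the band are
#' masked.  Failed runs are annotated in the output instead of aborting the
#' sweep.
#'
#' @param model a [ctbg_model()].
#' @param protocol a [stim_protocol()] with a numeric amplitude; its
#'   `f_stim` is replaced by each scanned value.
#' @param f_list stimulus frequencies to scan (Hz).
#' @param band length-2 band (Hz), default 20-30 Hz.
#' @param duration,window run length and analysis window (s).
#' @param dt integration step (s).
#' @param noise,init,seed_offset passed to [simulate_ctbg()]; spectra of the
#'   marginally stable operating state require the noise excitation.
#' @param segment spectral segment length (s).
#' @return Data frame with columns `f_stim` (NA for the baseline row),
#'   `band_peak_power`, `ratio_to_baseline`, `status`.
#' @export
suppression_curve <- function(model, protocol, f_list, band = c(20, 30),
                              duration = 40, window = c(20, 40), dt = 1e-4,
                              noise = NULL, init = NULL, seed_offset = 1e-6,
                              segment = 4) {
  if (is.null(init))
    init <- select_operating_state(solve_steady_states(model))
  measure <- function(proto) {
    sim <- simulate_ctbg(model, protocol = proto, duration = duration,
                         dt = dt, init = init, noise = noise,
                         seed_offset = seed_offset)
    sp <- power_spectrum(sim, "z", window[1], window[2], segment = segment)
    band_peak_power(sp, band[1], band[2],
                    exclude_harmonics_of = if (!is.null(proto)) proto$f_stim)
  }
  base <- measure(NULL)
  rows <- lapply(f_list, function(f) {
    proto <- protocol
    proto$f_stim <- f
    p <- tryCatch(measure(proto), error = function(e) e)
    if (inherits(p, "error"))
      data.frame(f_stim = f, band_peak_power = NA_real_,
                 ratio_to_baseline = NA_real_,
                 status = conditionMessage(p))
    else
      data.frame(f_stim = f, band_peak_power = p,
                 ratio_to_baseline = p / base, status = "ok")
  })
  out <- rbind(
    data.frame(f_stim = NA_real_, band_peak_power = base,
               ratio_to_baseline = 1, status = "baseline"),
    do.call(rbind, rows))
  attr(out, "band") <- band
  attr(out, "window") <- window
  out
}

# predicted wave-wave interaction frequencies of a stimulus line with the
# intrinsic beta line
intermod_frequencies <- function(f_stim, f_beta) {
  unique(round(c(abs(f_stim - f_beta), f_stim + f_beta,
                 abs(-f_stim + 2 * f_beta), abs(2 * f_stim - f_beta),
                 abs(-2 * f_stim + 3 * f_beta)), 6))
}

#' Entrainment scan over low-frequency DBS
#'
#' Scans stimulus frequencies bracketing the intrinsic beta peak.  For each
#' run the dominant STN spectral peak is located at fine frequency
#' resolution (one segment spanning the whole analysis window) and compared
#' with the stimulus frequency: 1:1 locking is declared when they agree
#' within one frequency bin.  Secondary peaks at the predicted wave-wave
#' interaction frequencies (sums, differences and low-order combinations of
#' the stimulus and beta frequencies) are tested against the local spectral
#' floor.
#'
#' @inheritParams suppression_curve
#' @param f_beta intrinsic beta frequency (Hz) used for the predicted
#'   combination frequencies; measured from the unstimulated baseline when
#'   `NULL`.
#' @param floor_halfwidth half-width (Hz) of the neighbourhood used for the
#'   local floor estimate.
#' @return Data frame with one row per stimulus frequency: `f_stim`,
#'   `dominant_freq`, `locked`, `n_intermod_detected`, `intermod_detected`
#'   (comma-separated Hz), `status`.
#' @export
entrainment_scan <- function(model, protocol, f_list, duration = 20,
                             window = c(10, 20), dt = 1e-4, noise = NULL,
                             init = NULL, seed_offset = 1e-6, f_beta = NULL,
                             floor_halfwidth = 2) {
  if (is.null(init))
    init <- select_operating_state(solve_steady_states(model))
  seg <- diff(window)
  spec_of <- function(proto) {
    sim <- simulate_ctbg(model, protocol = proto, duration = duration,
                         dt = dt, init = init, noise = noise,
                         seed_offset = seed_offset)
    power_spectrum(sim, "z", window[1], window[2], segment = seg)
  }
  if (is.null(f_beta)) {
    sp0 <- spec_of(NULL)
    f_beta <- dominant_peak(sp0, 1, 60)$frequency
  }
  rows <- lapply(f_list, function(f) {
    proto <- protocol
    proto$f_stim <- f
    sp <- tryCatch(spec_of(proto), error = function(e) e)
    if (inherits(sp, "error"))
      return(data.frame(f_stim = f, dominant_freq = NA_real_, locked = NA,
                        n_intermod_detected = NA_integer_,
                        intermod_detected = "", status = conditionMessage(sp)))
    bin <- sp$meta$resolution
    dom <- dominant_peak(sp, 1, 60)$frequency
    locked <- abs(dom - f) <= bin + 1e-9
    pred <- intermod_frequencies(f, f_beta)
    pred <- pred[pred > 1 & pred < max(sp$freq) - floor_halfwidth]
    detected <- vapply(pred, function(fp) {
      near <- abs(sp$freq - fp) <= 1.5 * bin
      ring <- abs(sp$freq - fp) <= floor_halfwidth &
        abs(sp$freq - fp) > 3 * bin
      any(near) && max(sp$power[near]) > 2 * stats::median(sp$power[ring])
    }, logical(1))
    data.frame(f_stim = f, dominant_freq = dom, locked = locked,
               n_intermod_detected = sum(detected),
               intermod_detected = paste(pred[detected], collapse = ","),
               status = "ok")
  })
  out <- do.call(rbind, rows)
  attr(out, "f_beta") <- f_beta
  out
}
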