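#' Balloon-Windkessel configuration
#'
#' Constants of the hemodynamic model translating excitatory activity into a
#' BOLD readout: vasodilatory signal `s`, inflow `f`, venous volume `v` and
#' deoxyhemoglobin content `q`, with
#' `B = V_0 (k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v))`.
#'
#' @param tau_s,tau_f,tau_v,tau_q time constants of signal decay, inflow,
#'   volume and deoxyhemoglobin, seconds.
#' @param kappa vessel stiffness (Grubb) exponent parameter; the outflow is
#'   `v^(1/kappa)`.
#' @param E_0 resting oxygen extraction fraction, in (0, 1).
#' @param V_0 resting venous blood volume fraction, in (0, 1).
#' @param k_1,k_2,k_3 kinetic constants of the readout.
#' @param dt hemodynamic Euler step, seconds.
#' @return A list of class `hemo_config`.
#' @export
hemo_config <- function(tau_s = 0.65, tau_f = 0.41, tau_v = 0.98,
                        tau_q = 0.98, kappa = 0.32, E_0 = 0.4, V_0 = 0.04,
                        k_1 = 2.77, k_2 = 0.2, k_3 = 0.5, dt = 1e-3) {
  cfg <- list(tau_s = tau_s, tau_f = tau_f, tau_v = tau_v, tau_q = tau_q,
              kappa = kappa, E_0 = E_0, V_0 = V_0, k_1 = k_1, k_2 = k_2,
              k_3 = k_3, dt = dt)
  if (any(unlist(cfg) <= 0)) stop("all hemodynamic constants must be positive")
  if (E_0 >= 1 || V_0 >= 1) stop("E_0 and V_0 must lie in (0, 1)")
  class(cfg) <- "hemo_config"
  cfg
}

#' Construct a BOLD series container
#'
#' @param values region-by-time numeric matrix (arbitrary units).
#' @param sampling_interval seconds between samples.
#' @param filtered has the band-pass been applied?
#' @param band `(low, high)` Hz, or `NULL`.
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(values, sampling_interval, filtered = FALSE,
                        band = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("BOLD series must be finite")
  if (sampling_interval <= 0) stop("sampling_interval must be positive")
  structure(list(values = values, sampling_interval = sampling_interval,
                 filtered = filtered, band = band), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat("BOLD series:", nrow(x$values), "regions x", ncol(x$values),
      "samples at", x$sampling_interval, "s;",
      if (x$filtered) paste0("band-passed [", x$band[1], ", ", x$band[2], "] Hz")
      else "unfiltered", "\n")
  invisible(x)
}

#' Balloon-Windkessel hemodynamic response
#'
#' Euler-integrates the four hemodynamic state equations from rest
#' (`s = 0`, `f = v = q = 1`) driven by an excitatory activity series sampled
#' at the hemodynamic step (`config$dt`, 1 ms by default), and returns the
#' BOLD readout at the same sampling.
#'
#' @param E_series region-by-time drive matrix (or a `wc_trajectory`, whose
#'   `E` is used), sampled at `config$dt`.
#' @param config a [hemo_config()].
#' @return An unfiltered [bold_series()].
#' @export
balloon_windkessel <- function(E_series, config = hemo_config()) {
  if (inherits(E_series, "wc_trajectory")) {
    if (abs(E_series$sample_interval - config$dt) > 1e-12)
      stop("trajectory sampling (", E_series$sample_interval,
           " s) does not match hemodynamic dt (", config$dt, " s)")
    E_series <- E_series$E
  }
  E_series <- as.matrix(E_series)
  if (!all(is.finite(E_series))) stop("drive series must be finite")
  B <- bw_sim_cpp(E_series, unclass(config))
  bold_series(B, config$dt)
}

# Second-order band-pass from the analog Bessel low-pass prototype
# (denominator s^2 + 3 s + 3, scaled so the -3 dB point sits at the corner),
# band-transformed and bilinear-digitized with the signal package plumbing.
# W is c(low, high) as a fraction of the Nyquist frequency.
bessel_bandpass <- function(W) {
  if (length(W) != 2 || any(W <= 0) || any(W >= 1) || W[1] >= W[2])
    stop("band corners must satisfy 0 < low < high < 1 (Nyquist units)")
  T <- 2
  Wp <- 2 / T * tan(pi * W / T)  # prewarped analog corners
  w3db <- sqrt((-3 + sqrt(45)) / 2)  # -3 dB frequency of s^2 + 3 s + 3
  pole <- (c(-3 + 1i * sqrt(3), -3 - 1i * sqrt(3)) / 2) / w3db
  gain <- Re(pole[1] * pole[2])  # unit DC gain
  zpg <- signal::Zpg(zero = numeric(0), pole = pole, gain = gain)
  zpg <- signal::sftrans(zpg, W = Wp, stop = FALSE)
  signal::as.Arma(signal::bilinear(zpg, T = T))
}

#' Band-pass filter and downsample a BOLD series
#'
#' Applies a zero-phase (forward-backward) 2nd-order Bessel band-pass and
#' decimates to one sample per `TR`. By default the series is decimated
#' first and the filter designed at the `1/TR` output rate, where a
#' 2nd-order design is numerically well-conditioned; `filter_first = TRUE`
#' filters at the native sampling rate before decimating (only advisable
#' when the native rate is within a few decades of the band).
#'
#' @param bold a [bold_series()] (unfiltered).
#' @param band `(low, high)` corner frequencies in Hz.
#' @param TR output sampling interval, seconds.
#' @param filter_first filter at the native rate before decimation.
#' @param zero_phase use forward-backward filtering (default); `FALSE` runs
#'   the filter forward only.
#' @return A filtered, TR-sampled [bold_series()].
#' @export
bold_postprocess <- function(bold, band = c(0.01, 0.1), TR = 2,
                             filter_first = FALSE, zero_phase = TRUE) {
  stopifnot(inherits(bold, "bold_series"))
  si <- bold$sampling_interval
  fs <- 1 / si
  if (fs <= 2 * band[2])
    stop("input sampling rate must exceed twice the upper band corner")
  dur <- ncol(bold$values) * si
  if (dur < 3 / (2 * pi * band[1]))
    stop("series too short for the band: need at least ",
         round(3 / (2 * pi * band[1]), 1), " s")
  k <- as.integer(round(TR / si))
  if (k < 1 || abs(k * si - TR) > 1e-9)
    stop("TR must be an integer multiple of the sampling interval")
  run_filter <- function(m, rate) {
    flt <- bessel_bandpass(2 * band / rate)
    t(apply(m, 1, function(x) {
      x <- x - mean(x)  # avoid DC-step edge transients in filtfilt
      if (zero_phase) signal::filtfilt(flt, x)
      else as.numeric(signal::filter(flt, x))
    }))
  }
  if (filter_first) {
    v <- run_filter(bold$values, fs)
    v <- v[, seq(k, ncol(v), by = k), drop = FALSE]
  } else {
    v <- bold$values[, seq(k, ncol(bold$values), by = k), drop = FALSE]
    v <- run_filter(v, 1 / TR)
  }
  bold_series(v, TR, filtered = TRUE, band = band)
}

#' Simulate BOLD functional data in one pass
#'
#' Runs the neural simulation, hemodynamic stage and post-processing
#' together in compiled code without materialising the millisecond state:
#' the hemodynamic state advances once per hemodynamic step during both
#' transient and analysis windows (so it is warm when recording starts), and
#' BOLD is recorded at `TR` then band-pass filtered.
#'
#' @param connectome a [connectome()] or weight matrix.
#' @param config a [sim_config()].
#' @param hemo a [hemo_config()].
#' @param seed integer RNG seed.
#' @param TR output sampling interval, seconds.
#' @param band band-pass corners in Hz; `NULL` skips filtering.
#' @return List with `bold` (a [bold_series()]), `e_mean` (per-node mean
#'   excitatory activity over the analysis window) and `seed`.
#' @export
simulate_bold <- function(connectome, config = sim_config(),
                          hemo = hemo_config(), seed = 1, TR = 2,
                          band = c(0.01, 0.1)) {
  C <- conn_weights(connectome)
  vec <- cfg_vectors(config, nrow(C))
  rec_every <- as.integer(round(TR / hemo$dt))
  set.seed(seed)
  out <- wc_bold_cpp(C, vec$G, vec$sigma_E, unclass(config), unclass(hemo),
                     rec_every)
  b <- bold_series(out$bold, TR)
  if (!is.null(band)) {
    b <- bold_postprocess(b, band = band, TR = TR)
  }
  list(bold = b, e_mean = out$e_mean, seed = seed)
}
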