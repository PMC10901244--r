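#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking at
#' `peak_delay` seconds and an undershoot peaking at `under_delay` seconds,
#' scaled by `1/ratio`.
#'
#' @param t time, s (vector).
#' @param peak_delay time-to-peak of the response, s.
#' @param under_delay time-to-peak of the undershoot, s.
#' @param disp_peak,disp_under dispersions (gamma scale parameters), s.
#' @param ratio undershoot-to-peak amplitude ratio.
#' @return HRF values at `t` (arbitrary scale).
#' @export
#' @examples
#' curve(hrf_double_gamma(x), 0, 32)
hrf_double_gamma <- function(t, peak_delay = 6, under_delay = 16,
                             disp_peak = 1, disp_under = 1, ratio = 1 / 6) {
  stopifnot(peak_delay > 0, under_delay > 0, disp_peak > 0, disp_under > 0,
            ratio > 0)
  a1 <- peak_delay / disp_peak
  a2 <- under_delay / disp_under
  h <- stats::dgamma(t, shape = a1, scale = disp_peak) -
    ratio * stats::dgamma(t, shape = a2, scale = disp_under)
  h[t < 0] <- 0
  h
}

#' Block activation protocols of the two simulated situations
#'
#' Two hypothetical combinations of scalp (U) and gray-matter (L)
#' hemodynamics, five blocks each:
#' \describe{
#'   \item{Situation 1 (48 s blocks, 240 s total)}{both layers activate
#'     simultaneously at 8 s for 8 s: U +10\% HbO, -5\% HbR; L +50\% HbO,
#'     -25\% HbR; 32 s final rest.}
#'   \item{Situation 2 (50 s blocks, 250 s total)}{U: -25\% HbO from 6 s
#'     for 8 s, HbR constant; L: +50\% HbO, -25\% HbR from 10 s for 12 s;
#'     28 s final rest. The two layers are time-shifted and of opposite
#'     HbO sign.}
#' }
#'
#' @param which 1 or 2.
#' @param sample_rate sampling rate, Hz.
#' @param n_blocks number of block repetitions.
#' @return Object of class `activation_protocol`: list with per-role
#'   schedules (onset_s, duration_s, frac_hbo, frac_hbr), `block_length_s`,
#'   `n_blocks`, `sample_rate_hz`.
#' @export
#' @examples
#' situation_protocol(1)
situation_protocol <- function(which, sample_rate = 10, n_blocks = 5L) {
  if (!length(which) == 1L || !which %in% c(1, 2))
    stop("'which' must be 1 or 2")
  stopifnot(sample_rate > 0, n_blocks >= 1L)
  if (which == 1) {
    p <- list(
      U = data.frame(onset_s = 8, duration_s = 8, frac_hbo = 0.10,
                     frac_hbr = -0.05),
      L = data.frame(onset_s = 8, duration_s = 8, frac_hbo = 0.50,
                     frac_hbr = -0.25),
      block_length_s = 48)
  } else {
    p <- list(
      U = data.frame(onset_s = 6, duration_s = 8, frac_hbo = -0.25,
                     frac_hbr = 0),
      L = data.frame(onset_s = 10, duration_s = 12, frac_hbo = 0.50,
                     frac_hbr = -0.25),
      block_length_s = 50)
  }
  p$n_blocks <- as.integer(n_blocks)
  p$sample_rate_hz <- sample_rate
  p$situation <- which
  class(p) <- "activation_protocol"
  p
}

#' @export
print.activation_protocol <- function(x, ...) {
  cat(sprintf("Activation protocol (situation %s): %d blocks of %g s at %g Hz\n",
              x$situation %||% "custom", x$n_blocks, x$block_length_s,
              x$sample_rate_hz))
  for (r in c("U", "L")) {
    s <- x[[r]]
    cat(sprintf("  %s: onset %g s, duration %g s, dHbO %+g%%, dHbR %+g%%\n",
                r, s$onset_s, s$duration_s, 100 * s$frac_hbo,
                100 * s$frac_hbr))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one block of an HRF-convolved schedule entry, normalised so that the
# convolved waveform's own peak magnitude is 1 (the nominal fractional
# change is then met exactly at the peak).
.block_waveform <- function(onset, duration, block_len, fs, hrf_args) {
  dt <- 1 / fs
  t <- seq(0, block_len - dt, by = dt)
  box <- as.numeric(t >= onset & t < onset + duration)
  if (!any(box > 0)) return(rep(0, length(t)))
  kern <- do.call(hrf_double_gamma,
                  c(list(t = seq(0, 32, by = dt)), hrf_args))
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(t)]
  conv / max(abs(conv))
}

#' HRF-convolved hemoglobin concentration time courses
#'
#' Builds the per-role \[HbO\](t), \[HbR\](t) series implied by a block
#' protocol: per block, the boxcar of the fractional change is convolved
#' with the canonical HRF and normalised to its own peak, so the printed
#' peak concentration equals baseline times (1 + fractional change); blocks
#' are then concatenated.
#'
#' @param protocol an [situation_protocol()] (or compatible list).
#' @param baselines named list of baseline concentrations per role, each
#'   `c(hbo=, hbr=)` in uM; default derived from the head-model baseline
#'   absorptions 0.018 (U) and 0.036 (L) mm^-1.
#' @param hrf_args optional list of overrides for [hrf_double_gamma()].
#' @param table extinction table used for the default baselines.
#' @return Object of class `concentration_series`: data.frame with columns
#'   `time_s`, `hbo_U`, `hbr_U`, `hbo_L`, `hbr_L` (uM), plus attributes
#'   `baselines` and `sample_rate_hz`.
#' @export
#' @examples
#' cs <- concentration_timeseries(situation_protocol(1))
#' max(cs$hbo_L)   # 176.33 uM
concentration_timeseries <- function(protocol,
                                     baselines = NULL,
                                     hrf_args = list(),
                                     table = default_extinction_table()) {
  fs <- protocol$sample_rate_hz
  if (is.null(baselines)) {
    baselines <- list(U = mua_to_conc(0.018, table),
                      L = mua_to_conc(0.036, table))
  }
  nblk <- protocol$n_blocks
  blen <- protocol$block_length_s
  out <- list()
  for (r in c("U", "L")) {
    s <- protocol[[r]]
    wav <- .block_waveform(s$onset_s, s$duration_s, blen, fs, hrf_args)
    wav <- rep(wav, nblk)
    b <- baselines[[r]]
    out[[paste0("hbo_", r)]] <- b[["hbo"]] * (1 + s$frac_hbo * wav)
    out[[paste0("hbr_", r)]] <- b[["hbr"]] * (1 + s$frac_hbr * wav)
  }
  n <- length(out$hbo_U)
  df <- data.frame(time_s = seq(0, by = 1 / fs, length.out = n),
                   hbo_U = out$hbo_U, hbr_U = out$hbr_U,
                   hbo_L = out$hbo_L, hbr_L = out$hbr_L)
  structure(df, baselines = baselines, sample_rate_hz = fs,
            class = c("concentration_series", "data.frame"))
}
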