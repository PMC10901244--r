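#' Probe layout: long and short separation channels
#'
#' Each channel pairs a long-separation detector (cortex-sensitive) with a
#' short-separation detector (scalp-dominated) of the same source.
#'
#' @param channel_id integer id(s).
#' @param long_mm long separations, mm.
#' @param short_mm short separations, mm (each < long).
#' @param on_active logical; whether the channel lies over the active
#'   cortical region.
#' @return Object of class `probe_layout` (data.frame).
#' @export
#' @examples
#' probe_layout()          # channel 1: 31.3 (8.3) mm
#' standard_layout()       # the full 8-channel montage
probe_layout <- function(channel_id = 1L, long_mm = 31.3, short_mm = 8.3,
                         on_active = TRUE) {
  stopifnot(length(long_mm) == length(short_mm),
            all(short_mm > 0), all(long_mm > short_mm))
  structure(data.frame(channel_id = as.integer(channel_id),
                       long_mm = long_mm, short_mm = short_mm,
                       on_active = on_active),
            class = c("probe_layout", "data.frame"))
}

#' @rdname probe_layout
#' @export
standard_layout <- function() {
  probe_layout(channel_id = 1:8,
               long_mm = c(31.3, 32.1, 27.6, 27.7, 33.9, 33.2, 28.8, 28.9),
               short_mm = c(8.3, 6.5, 10.4, 10.5, 7.3, 7.9, 8.3, 8.9),
               on_active = c(TRUE, NA, FALSE, FALSE, NA, TRUE, TRUE, TRUE))
}

#' Simulate channel attenuation from concentration time courses
#'
#' Maps per-role hemoglobin time courses onto the absorption of the scalp
#' and gray-matter layers (other layers stay at their nominal values at
#' both wavelengths) and produces natural-log attenuation
#' \eqn{A = -\ln(I/I_0)} per channel, wavelength and separation.
#'
#' Two generation modes: `"nonlinear"` re-solves the layered diffusion
#' forward model at every timepoint (the attenuation then carries the full
#' nonlinear dependence on absorption); `"linear"` applies the modified
#' Beer-Lambert model \eqn{A = L_U \Delta\mu_{a,U} + L_L \Delta\mu_{a,L}}
#' with mean partial pathlengths fixed at baseline (useful for
#' inverse-crime validation).
#'
#' @param series a [concentration_timeseries()].
#' @param medium a `layered_medium`; its scalp / gray-matter roles receive
#'   the absorption time courses.
#' @param layout a [probe_layout()].
#' @param table an [extinction_table()].
#' @param mode `"nonlinear"` or `"linear"`.
#' @param noise_sd relative intensity noise (Gaussian, sd as a fraction of
#'   the intensity); 0 disables noise.
#' @param seed integer seed for the noise generator (required if
#'   `noise_sd > 0`).
#' @param wavelengths working wavelengths, nm.
#' @param ... passed to [layered_reflectance()] / [mppl()].
#' @return Object of class `attenuation_series`: data.frame with columns
#'   `time_s`, `channel_id`, `wavelength_nm`, `separation_mm`, `role`
#'   ("long"/"short"), `attenuation`; the generating series and layout are
#'   kept as attributes.
#' @export
forward_attenuation <- function(series, medium, layout = probe_layout(),
                                table = default_extinction_table(),
                                mode = c("nonlinear", "linear"),
                                noise_sd = 0, seed = NULL,
                                wavelengths = c(690, 830), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "concentration_series"),
            inherits(medium, "layered_medium"))
  roles <- roles_head_model(medium)
  nt <- nrow(series)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("'seed' is required when noise_sd > 0")
    set.seed(as.integer(seed))
  }
  # per-wavelength active-layer absorption time courses
  mua_t <- lapply(wavelengths, function(w)
    cbind(U = conc_to_mua(series$hbo_U, series$hbr_U, w, table),
          L = conc_to_mua(series$hbo_L, series$hbr_L, w, table)))
  names(mua_t) <- as.character(wavelengths)

  out <- list()
  for (ic in seq_len(nrow(layout))) {
    for (side in c("short", "long")) {
      rho <- layout[[paste0(side, "_mm")]][ic]
      for (w in as.character(wavelengths)) {
        mu <- mua_t[[w]]
        if (mode == "nonlinear") {
          m0 <- set_mua(medium, mu[1, ], roles)
          I0 <- layered_reflectance(m0, rho, ...)$reflectance
          I <- vapply(seq_len(nt), function(i) {
            if (i > 1L && all(mu[i, ] == mu[1, ])) return(I0)
            mi <- set_mua(medium, mu[i, ], roles)
            layered_reflectance(mi, rho, ...)$reflectance
          }, numeric(1))
        } else {
          mw <- set_mua(medium, mu[1, ], roles)
          L <- mppl(mw, rho, ...)[roles]
          dA <- (mu[, "U"] - mu[1, "U"]) * L[1] +
            (mu[, "L"] - mu[1, "L"]) * L[2]
          I0 <- 1
          I <- exp(-dA)
        }
        if (noise_sd > 0) {
          I <- I * (1 + stats::rnorm(nt, 0, noise_sd))
          bad <- I < 1e-12 * I0
          if (any(bad)) {
            warning(sum(bad), " noisy intensities clipped at 1e-12 * I0")
            I[bad] <- 1e-12 * I0
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          time_s = series$time_s,
          channel_id = layout$channel_id[ic],
          wavelength_nm = as.numeric(w),
          separation_mm = rho,
          role = side,
          attenuation = -log(I / I0))
      }
    }
  }
  structure(do.call(rbind, out),
            series = series, layout = layout, mode = mode,
            wavelengths = wavelengths,
            class = c("attenuation_series", "data.frame"))
}

# pull one channel's A(t) as a time x (wavelength, separation) matrix
.channel_matrix <- function(aseries, channel, side) {
  sub <- aseries[aseries$channel_id == channel & aseries$role == side, ]
  if (!nrow(sub)) stop("channel ", channel, " (", side, ") not present")
  wl <- sort(unique(sub$wavelength_nm))
  t0 <- sort(unique(sub$time_s))
  M <- sapply(wl, function(w)
    sub$attenuation[sub$wavelength_nm == w][order(sub$time_s[sub$wavelength_nm == w])])
  dimnames(M) <- list(NULL, as.character(wl))
  list(time_s = t0, A = M, rho = sub$separation_mm[1])
}

#' Write / read attenuation series as tidy CSV with a JSON sidecar
#'
#' @param aseries an `attenuation_series`.
#' @param path CSV path; the sidecar is written next to it with extension
#'   `.json`.
#' @param meta optional named list merged into the sidecar (seed, medium,
#'   protocol description, ...).
#' @return `path` invisibly.
#' @export
write_attenuation_csv <- function(aseries, path, meta = list()) {
  df <- as.data.frame(aseries)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- c(list(format = "layernirs-attenuation-v1",
                 mode = attr(aseries, "mode"),
                 wavelengths_nm = attr(aseries, "wavelengths"),
                 n_rows = nrow(df)), meta)
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_attenuation_csv
#' @export
read_attenuation_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(df, wavelengths = sort(unique(df$wavelength_nm)),
            class = c("attenuation_series", "data.frame"))
}
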