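#' Root-mean-squared error between retrieved and proposed time courses
#'
#' @param retrieved,proposed numeric vectors of equal length, uM.
#' @return RMSE, uM.
#' @export
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))   # sqrt(4/3)
rmse <- function(retrieved, proposed) {
  if (length(retrieved) != length(proposed))
    stop("length mismatch between retrieved and proposed series")
  if (!length(retrieved)) stop("empty series")
  sqrt(mean((retrieved - proposed)^2))
}

#' Pearson correlation of two time courses
#'
#' Thin wrapper over [stats::cor()] with explicit degenerate-input errors.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least two points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Sensitivity of the layered reconstruction to prior assumptions
#'
#' The layered inversion needs baseline absorption coefficients and layer
#' thicknesses as priors. This sweeps a symmetric relative grid around the
#' assumed values of the two active layers (scalp and gray matter),
#' rebuilds the pathlength matrix at each grid point, re-runs the layered
#' inversion, and records the RMSE between retrieved and proposed changes
#' for each role and hemoglobin species.
#'
#' @param aseries an `attenuation_series` (the data to invert).
#' @param truth the generating [concentration_timeseries()].
#' @param base_medium the assumed head model (grid centre = truth when its
#'   parameters match the generator's).
#' @param which `"mua"` (baseline absorptions, e.g. +/-50\%) or
#'   `"thickness"` (scalp and gray-matter thicknesses, e.g. +/-25\%).
#' @param rel_range half-width of the relative grid (0.5 = +/-50\%).
#' @param n_steps grid points per axis; odd and >= 3 so the centre is a
#'   node.
#' @param channel channel id.
#' @param table an [extinction_table()].
#' @param ... passed to [mppl_matrix()].
#' @return Object of class `sensitivity_grid`: data.frame with columns
#'   `p1`, `p2` (the perturbed parameter values), `role`, `species`,
#'   `rmse_uM`; attributes `which`, `axes`, `centre`, `argmin` (per
#'   role/species coordinates of minimum RMSE).
#' @export
prior_sensitivity <- function(aseries, truth, base_medium,
                              which = c("mua", "thickness"),
                              rel_range = 0.5, n_steps = 5L, channel = 1L,
                              table = default_extinction_table(), ...) {
  which <- match.arg(which)
  n_steps <- as.integer(n_steps)
  if (n_steps < 3L || n_steps %% 2L == 0L)
    stop("'n_steps' must be odd and >= 3 so the centre value is a node")
  roles <- roles_head_model(base_medium)
  base <- switch(which, mua = base_medium$mua[roles],
                 thickness = base_medium$thickness[roles])
  grid1 <- base[1] * seq(1 - rel_range, 1 + rel_range, length.out = n_steps)
  grid2 <- base[2] * seq(1 - rel_range, 1 + rel_range, length.out = n_steps)

  long <- .channel_matrix(aseries, channel, "long")
  short <- .channel_matrix(aseries, channel, "short")
  rhos <- c(short$rho, long$rho)
  wavelengths <- as.numeric(colnames(long$A))
  A4 <- cbind(short$A[, 1], long$A[, 1], short$A[, 2], long$A[, 2])
  tr <- delta_truth(truth)
  comp <- c(dhbo_U = "dhbo_U", dhbo_L = "dhbo_L",
            dhbr_U = "dhbr_U", dhbr_L = "dhbr_L")

  rows <- list()
  for (i1 in seq_along(grid1)) for (i2 in seq_along(grid2)) {
    m <- base_medium
    if (which == "mua") {
      m <- set_mua(m, c(grid1[i1], grid2[i2]), roles)
    } else {
      m <- set_thickness(m, c(grid1[i1], grid2[i2]), roles)
    }
    r <- tryCatch({
      L <- mppl_matrix(m, rhos, wavelengths, table, ...)
      inv <- layered_invert(A4, L, table, wavelengths)
      vapply(comp, function(k) rmse(inv$delta[, k], tr[[k]]), numeric(1))
    }, error = function(e) stats::setNames(rep(NA_real_, 4L), names(comp)))
    rows[[length(rows) + 1L]] <- data.frame(
      p1 = grid1[i1], p2 = grid2[i2],
      role = c("U", "L", "U", "L"),
      species = c("hbo", "hbo", "hbr", "hbr"),
      rmse_uM = unname(r))
  }
  df <- do.call(rbind, rows)
  am <- lapply(split(df, list(df$role, df$species)), function(g) {
    g <- g[is.finite(g$rmse_uM), ]
    g[which.min(g$rmse_uM), c("p1", "p2")]
  })
  structure(df, which = which, centre = base,
            axes = list(p1 = grid1, p2 = grid2), argmin = am,
            class = c("sensitivity_grid", "data.frame"))
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("Prior-sensitivity grid over %s (%d points)\n",
              attr(x, "which"), length(attr(x, "axes")$p1)^2))
  cat(sprintf("  centre: %s\n",
              paste(signif(attr(x, "centre"), 4), collapse = ", ")))
  for (k in names(attr(x, "argmin"))) {
    a <- attr(x, "argmin")[[k]]
    cat(sprintf("  argmin RMSE %-6s: p1 = %.4g, p2 = %.4g\n", k, a$p1, a$p2))
  }
  invisible(x)
}
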