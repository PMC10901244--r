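#' Homogeneous modified Beer-Lambert inversion
#'
#' Per-timepoint solution of the two-wavelength extinction system under
#' the differential-pathlength-factor approximation: the effective photon
#' pathlength is `dpf * rho` and the medium is treated as homogeneous, so
#' a single pair of concentration changes is recovered.
#'
#' @param A numeric matrix, timepoints x 2 wavelengths of natural-log
#'   attenuation (columns ordered as `wavelengths`).
#' @param rho source-detector distance, mm.
#' @param dpf differential pathlength factor (default 6).
#' @param table an [extinction_table()].
#' @param wavelengths the two working wavelengths, nm.
#' @return Matrix timepoints x 2 (`dhbo`, `dhbr`), uM.
#' @export
homogeneous_mbll <- function(A, rho, dpf = 6,
                             table = default_extinction_table(),
                             wavelengths = c(690, 830)) {
  stopifnot(is.matrix(A), ncol(A) == 2L, dpf > 0, rho > 0)
  E <- .eps_matrix(table, wavelengths)
  X <- t(solve(E, t(A))) / (dpf * rho)
  colnames(X) <- c("dhbo", "dhbr")
  X
}

#' Short-separation channel regression (scalp correction)
#'
#' Removes the scalp-dominated component of a long channel by subtracting
#' the short channel scaled by the inner-product ratio
#' \eqn{K = \langle A_{short}, A_{long}\rangle / \langle A_{short},
#' A_{short}\rangle}, computed over the full series (per wavelength).
#'
#' @param a_long,a_short attenuation time courses (equal length).
#' @param center mean-center both series before forming the inner products
#'   (default FALSE: plain dot product).
#' @return List with `corrected` (time course) and `K`.
#' @export
#' @examples
#' x <- sin(seq(0, 10, 0.1))
#' short_channel_correct(3 * x, x)$K   # 3; corrected is ~0
short_channel_correct <- function(a_long, a_short, center = FALSE) {
  stopifnot(length(a_long) == length(a_short))
  l <- a_long; s <- a_short
  if (center) { l <- l - mean(l); s <- s - mean(s) }
  ss <- sum(s * s)
  if (ss == 0) {
    warning("all-zero short channel; K set to 0 (no correction)")
    return(list(corrected = a_long, K = 0))
  }
  K <- sum(s * l) / ss
  list(corrected = a_long - K * a_short, K = K)
}

#' Two-role layered inversion of attenuation data
#'
#' Assembles the 4x4 linear system linking the attenuation at two
#' wavelengths and two source-detector separations to the hemoglobin
#' concentration changes in the scalp (U) and gray-matter (L) roles,
#' through the extinction coefficients and the per-layer mean partial
#' pathlengths, and solves it per timepoint by SVD pseudo-inverse.
#'
#' @param A numeric matrix, timepoints x 4, columns ordered (lambda1 rho1,
#'   lambda1 rho2, lambda2 rho1, lambda2 rho2).
#' @param mppl an [mppl_matrix()] for the same wavelengths/separations.
#' @param table an [extinction_table()].
#' @param wavelengths the two wavelengths, nm.
#' @param sv_tol relative singular-value truncation threshold.
#' @param cond_cap condition number above which the result is flagged.
#' @return List with `delta` (timepoints x 4 matrix: `dhbo_U`, `dhbo_L`,
#'   `dhbr_U`, `dhbr_L`, uM), `condition`, `flagged`, `system` (the 4x4
#'   matrix).
#' @export
layered_invert <- function(A, mppl, table = default_extinction_table(),
                           wavelengths = c(690, 830), sv_tol = 1e-12,
                           cond_cap = 1e10) {
  stopifnot(is.matrix(A), ncol(A) == 4L)
  E <- .eps_matrix(table, wavelengths)
  rhos <- dimnames(mppl)$rho
  M <- matrix(0, 4, 4,
              dimnames = list(NULL, c("dhbo_U", "dhbo_L", "dhbr_U", "dhbr_L")))
  row <- 0L
  for (iw in 1:2) for (ir in 1:2) {
    row <- row + 1L
    M[row, ] <- c(E[iw, "hbo"] * mppl["U", iw, ir],
                  E[iw, "hbo"] * mppl["L", iw, ir],
                  E[iw, "hbr"] * mppl["U", iw, ir],
                  E[iw, "hbr"] * mppl["L", iw, ir])
  }
  sv <- svd(M)
  keep <- sv$d > sv_tol * sv$d[1]
  # condition of the untruncated system decides the rank-deficiency flag
  cond <- if (min(sv$d) > 0) sv$d[1] / min(sv$d) else Inf
  dinv <- ifelse(keep, 1 / sv$d, 0)
  pinv <- sv$v %*% (dinv * t(sv$u))
  X <- A %*% t(pinv)
  colnames(X) <- colnames(M)
  list(delta = X, condition = cond, flagged = cond > cond_cap, system = M)
}

#' Reconstruct hemoglobin concentration changes from attenuation data
#'
#' The central fitting function: takes an [forward_attenuation()] series
#' (or one read from CSV) for one channel and estimates the time courses
#' of oxy-/deoxyhemoglobin concentration changes by one of three methods:
#' \describe{
#'   \item{`"layered"`}{two-distance, two-wavelength SVD inversion with
#'     analytical mean partial pathlengths of a layered head model (roles
#'     U = scalp, L = gray matter). `medium` chooses the model order (2 or
#'     5 layers).}
#'   \item{`"homogeneous"`}{single long channel, differential pathlength
#'     factor approximation.}
#'   \item{`"short_corrected"`}{homogeneous inversion of the long channel
#'     after short-separation regression of the scalp signal.}
#' }
#'
#' @param aseries an `attenuation_series`.
#' @param method reconstruction method (see above).
#' @param medium layered head model for `method = "layered"`; default
#'   [head_model()].
#' @param channel channel id to reconstruct.
#' @param dpf differential pathlength factor for the homogeneous methods.
#' @param table an [extinction_table()].
#' @param mppl optional precomputed [mppl_matrix()]; computed at the
#'   medium's baseline if missing.
#' @param center_inner mean-center the short-channel inner products.
#' @param ... passed to [mppl_matrix()].
#' @return Object of class `hb_recon`: list with `delta` (data.frame
#'   time_s plus per-role change columns, uM), `method`, `condition`, `K`,
#'   `channel`, and the inputs needed by the methods below.
#' @seealso [coef.hb_recon()], [fitted.hb_recon()], [plot.hb_recon()]
#' @export
reconstruct_hb <- function(aseries,
                           method = c("layered", "homogeneous",
                                      "short_corrected"),
                           medium = head_model(), channel = 1L, dpf = 6,
                           table = default_extinction_table(),
                           mppl = NULL, center_inner = FALSE, ...) {
  method <- match.arg(method)
  long <- .channel_matrix(aseries, channel, "long")
  wavelengths <- as.numeric(colnames(long$A))
  out <- list(method = method, channel = channel, time_s = long$time_s,
              table = table, wavelengths = wavelengths, dpf = dpf,
              rho_long = long$rho)
  if (method == "layered") {
    short <- .channel_matrix(aseries, channel, "short")
    rhos <- c(short$rho, long$rho)
    if (is.null(mppl))
      mppl <- mppl_matrix(medium, rhos, wavelengths, table, ...)
    # columns (l1 r1, l1 r2, l2 r1, l2 r2)
    A4 <- cbind(short$A[, 1], long$A[, 1], short$A[, 2], long$A[, 2])
    inv <- layered_invert(A4, mppl, table, wavelengths)
    out$delta <- data.frame(time_s = long$time_s, inv$delta)
    out$condition <- inv$condition
    out$flagged <- inv$flagged
    out$mppl <- mppl
    out$system <- inv$system
    out$A <- A4
    out$rho_short <- short$rho
  } else {
    A <- long$A
    if (method == "short_corrected") {
      short <- .channel_matrix(aseries, channel, "short")
      K <- numeric(2)
      for (iw in 1:2) {
        sc <- short_channel_correct(A[, iw], short$A[, iw],
                                    center = center_inner)
        A[, iw] <- sc$corrected
        K[iw] <- sc$K
      }
      names(K) <- colnames(long$A)
      out$K <- K
      out$rho_short <- short$rho
    }
    X <- homogeneous_mbll(A, long$rho, dpf, table, wavelengths)
    out$delta <- data.frame(time_s = long$time_s,
                            dhbo = X[, "dhbo"], dhbr = X[, "dhbr"])
    out$A <- A
  }
  class(out) <- "hb_recon"
  out
}

#' @export
print.hb_recon <- function(x, ...) {
  cat(sprintf("Hemoglobin reconstruction (%s), channel %s, %d timepoints\n",
              x$method, x$channel, nrow(x$delta)))
  if (!is.null(x$condition))
    cat(sprintf("  4x4 system condition number: %.3g%s\n", x$condition,
                if (isTRUE(x$flagged)) " [FLAGGED: ill-conditioned]" else ""))
  if (!is.null(x$K))
    cat(sprintf("  short-channel K: %s\n",
                paste(sprintf("%s nm: %.3f", names(x$K), x$K),
                      collapse = ", ")))
  print(coef(x))
  invisible(x)
}

#' Peak concentration-change amplitudes
#'
#' @param object an `hb_recon` fit.
#' @param ... unused.
#' @return Named vector: for each reconstructed component, the value of
#'   largest magnitude over the series (uM).
#' @export
coef.hb_recon <- function(object, ...) {
  d <- object$delta[, -1, drop = FALSE]
  vapply(d, function(v) v[which.max(abs(v))], numeric(1))
}

#' Attenuation implied by a reconstruction
#'
#' Pushes the estimated concentration changes back through the linear
#' forward model used in the inversion; with [residuals.hb_recon()] this
#' measures how much of the measured attenuation the fit explains.
#'
#' @param object an `hb_recon` fit.
#' @param ... unused.
#' @return Matrix of fitted attenuation, same shape as the inverted data.
#' @export
fitted.hb_recon <- function(object, ...) {
  if (object$method == "layered")
    return(as.matrix(object$delta[, -1]) %*% t(object$system))
  E <- .eps_matrix(object$table, object$wavelengths)
  as.matrix(object$delta[, c("dhbo", "dhbr")]) %*% t(E) *
    object$dpf * object$rho_long
}

#' @export
residuals.hb_recon <- function(object, ...) object$A - fitted(object)

#' @export
summary.hb_recon <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, peaks = coef(object),
                 resid_rms = sqrt(mean(res^2))), class = "summary.hb_recon")
}

#' @export
print.summary.hb_recon <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  attenuation residual RMS: %.3g\n", x$resid_rms))
  invisible(x)
}

#' Plot reconstructed hemoglobin time courses
#'
#' @param x an `hb_recon` fit.
#' @param truth optional `concentration_series` of the proposed changes,
#'   overlaid as dashed lines.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hb_recon <- function(x, truth = NULL, ...) {
  d <- x$delta
  cols <- setdiff(names(d), "time_s")
  graphics::matplot(d$time_s, as.matrix(d[, cols]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = expression(Delta * "[HbX] (uM)"),
                    main = sprintf("%s reconstruction", x$method), ...)
  if (!is.null(truth)) {
    tr <- delta_truth(truth)
    keep <- intersect(cols, names(tr))
    if (length(keep))
      graphics::matlines(tr$time_s, as.matrix(tr[, keep]), lty = 2)
  }
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Proposed concentration changes of a simulated series
#'
#' @param series a `concentration_series`.
#' @return data.frame `time_s`, `dhbo_U`, `dhbo_L`, `dhbr_U`, `dhbr_L`:
#'   deviations from the first-timepoint baselines, uM.
#' @export
delta_truth <- function(series) {
  data.frame(time_s = series$time_s,
             dhbo_U = series$hbo_U - series$hbo_U[1],
             dhbo_L = series$hbo_L - series$hbo_L[1],
             dhbr_U = series$hbr_U - series$hbr_U[1],
             dhbr_L = series$hbr_L - series$hbr_L[1])
}
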