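#' Define one optical layer
#'
#' A layer is described by its absorption coefficient, reduced scattering
#' coefficient, thickness and refractive index. Anisotropy is absorbed into
#' the reduced scattering coefficient \eqn{\mu_s' = \mu_s (1 - g)}, as usual
#' under the diffusion approximation.
#'
#' @param mua absorption coefficient, mm^-1 (>= 0).
#' @param musp reduced scattering coefficient, mm^-1 (> 0).
#' @param thickness layer thickness, mm (> 0); `Inf` for the terminal
#'   semi-infinite layer.
#' @param n refractive index (> 0), default 1.33.
#' @param label optional short name (e.g. "SC", "GM").
#' @return An object of class `optical_layer`.
#' @export
#' @examples
#' optical_layer(mua = 0.018, musp = 1.9, thickness = 10, label = "SC")
optical_layer <- function(mua, musp, thickness = Inf, n = 1.33, label = NA_character_) {
  stopifnot(is.numeric(mua), length(mua) == 1L, is.finite(mua), mua >= 0)
  if (!is.numeric(musp) || length(musp) != 1L || !is.finite(musp) || musp <= 0)
    stop("'musp' must be a single positive number (mm^-1)")
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
    stop("'thickness' must be positive (mm), or Inf for the last layer")
  if (!is.numeric(n) || n <= 0) stop("'n' must be positive")
  structure(list(mua = mua, musp = musp, thickness = thickness,
                 n = n, label = as.character(label)),
            class = "optical_layer")
}

#' Assemble a semi-infinite layered medium
#'
#' Layers are ordered from the surface inwards; the last layer must be
#' semi-infinite. The lateral expansion of the diffusion solution is
#' truncated in a cylinder of radius `cylinder_radius` (plus the
#' extrapolation length), which must comfortably exceed any source-detector
#' separation of interest.
#'
#' @param layers list of [optical_layer()] objects, outermost first.
#' @param cylinder_radius truncation radius of the lateral Bessel-root
#'   expansion, mm.
#' @param n_out refractive index of the medium above the surface (default 1,
#'   air).
#' @return An object of class `layered_medium` with derived diffusion
#'   coefficients `D = 1/(3 musp)` and isotropic-source depth
#'   `z0 = 1/musp[1]`.
#' @export
layered_medium <- function(layers, cylinder_radius = 150, n_out = 1.0) {
  if (inherits(layers, "optical_layer")) layers <- list(layers)
  if (!length(layers)) stop("need at least one layer")
  ok <- vapply(layers, inherits, logical(1), "optical_layer")
  if (!all(ok)) stop("'layers' must be a list of optical_layer objects")
  d <- vapply(layers, `[[`, numeric(1), "thickness")
  nl <- length(layers)
  if (is.finite(d[nl])) stop("the last layer must have infinite thickness")
  if (nl > 1L && any(!is.finite(d[-nl])))
    stop("only the last layer may be semi-infinite")
  if (!is.numeric(cylinder_radius) || cylinder_radius <= 0)
    stop("'cylinder_radius' must be positive (mm)")
  m <- structure(list(
    layers = layers,
    mua = vapply(layers, `[[`, numeric(1), "mua"),
    musp = vapply(layers, `[[`, numeric(1), "musp"),
    thickness = d,
    n = vapply(layers, `[[`, numeric(1), "n"),
    labels = vapply(layers, `[[`, character(1), "label"),
    cylinder_radius = cylinder_radius,
    n_out = n_out), class = "layered_medium")
  m$D <- 1 / (3 * m$musp)
  m$z0 <- 1 / m$musp[1]
  m
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("Semi-infinite layered medium: %d layer(s), R = %g mm\n",
              length(x$layers), x$cylinder_radius))
  df <- data.frame(layer = ifelse(is.na(x$labels), seq_along(x$mua), x$labels),
                   mua_per_mm = x$mua, musp_per_mm = x$musp,
                   d_mm = x$thickness, n = x$n)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Five-layer adult head model
#'
#' The default head model: scalp (SC), skull (SK), cerebrospinal fluid
#' (CSF), gray matter (GM) and a semi-infinite white-matter (WM)
#' compartment, with baseline absorption given at the hemoglobin isosbestic
#' wavelength (~800 nm). Reduced scattering follows from mus and g = 0.9.
#' Hemodynamic activity is modelled in the scalp (role U, upper) and the
#' gray matter (role L, lower); [roles_head_model()] reports their indices.
#'
#' @param cylinder_radius lateral truncation radius, mm.
#' @return A `layered_medium` with 5 layers.
#' @export
#' @examples
#' head_model()
head_model <- function(cylinder_radius = 150) {
  layered_medium(list(
    optical_layer(0.018, 19 * (1 - 0.9), 10, 1.33, "SC"),
    optical_layer(0.016, 16 * (1 - 0.9), 3, 1.33, "SK"),
    optical_layer(0.002, 10 * (1 - 0.9), 3, 1.33, "CSF"),
    optical_layer(0.036, 22 * (1 - 0.9), 2, 1.33, "GM"),
    optical_layer(0.014, 41 * (1 - 0.9), Inf, 1.33, "WM")),
    cylinder_radius = cylinder_radius)
}

#' Indices of the hemodynamically active layers
#'
#' @param medium a `layered_medium`.
#' @return Named integer vector `c(U = ..., L = ...)`: the scalp (upper) and
#'   gray-matter (lower) layer indices. For a 2-layer medium these are 1 and
#'   2; for the 5-layer head model, 1 (SC) and 4 (GM).
#' @export
roles_head_model <- function(medium) {
  nl <- length(medium$mua)
  if (nl == 2L) return(c(U = 1L, L = 2L))
  lab <- medium$labels
  u <- if (any(lab == "SC", na.rm = TRUE)) which(lab == "SC")[1] else 1L
  l <- if (any(lab == "GM", na.rm = TRUE)) which(lab == "GM")[1] else nl - 1L
  c(U = as.integer(u), L = as.integer(l))
}

#' Replace per-layer absorption coefficients
#'
#' @param medium a `layered_medium`.
#' @param mua replacement absorption vector (full length) or named subset
#'   via `idx`.
#' @param idx layer indices to replace when `mua` is shorter than the stack.
#' @return The modified medium.
#' @export
set_mua <- function(medium, mua, idx = seq_along(medium$mua)) {
  stopifnot(length(mua) == length(idx), all(mua >= 0))
  medium$mua[idx] <- mua
  for (k in seq_along(idx)) medium$layers[[idx[k]]]$mua <- mua[k]
  medium
}

#' Replace layer thicknesses
#'
#' @param medium a `layered_medium`.
#' @param thickness replacement thickness vector, mm.
#' @param idx layer indices to replace.
#' @return The modified medium.
#' @export
set_thickness <- function(medium, thickness, idx = seq_along(medium$thickness)) {
  stopifnot(length(thickness) == length(idx), all(thickness > 0))
  nl <- length(medium$thickness)
  if (any(idx == nl)) stop("cannot set the thickness of the terminal layer")
  medium$thickness[idx] <- thickness
  for (k in seq_along(idx)) medium$layers[[idx[k]]]$thickness <- thickness[k]
  medium
}

#' Merge a five-layer head into a two-layer medium
#'
#' For the two-layer reconstruction the scalp is kept as the extracranial
#' layer and everything beneath it (skull, CSF, gray and white matter) is
#' merged into one semi-infinite layer. The default policy assigns the
#' merged layer the gray-matter baseline properties; the alternative
#' `"weighted"` policy thickness-averages skull, CSF and gray matter.
#'
#' @param medium a 5-layer `layered_medium`, scalp first.
#' @param policy `"gm"` (default) or `"weighted"`.
#' @return A 2-layer `layered_medium`.
#' @export
two_layer_merge <- function(medium, policy = c("gm", "weighted")) {
  policy <- match.arg(policy)
  stopifnot(inherits(medium, "layered_medium"), length(medium$mua) >= 2L)
  roles <- roles_head_model(medium)
  scalp <- medium$layers[[1L]]
  if (policy == "gm") {
    g <- roles[["L"]]
    lower <- optical_layer(medium$mua[g], medium$musp[g], Inf,
                           medium$n[g], "merged")
  } else {
    mid <- setdiff(seq_len(length(medium$mua) - 1L), 1L)
    w <- medium$thickness[mid]
    lower <- optical_layer(sum(w * medium$mua[mid]) / sum(w),
                           sum(w * medium$musp[mid]) / sum(w),
                           Inf, medium$n[mid[1]], "merged")
  }
  layered_medium(list(scalp, lower), cylinder_radius = medium$cylinder_radius,
                 n_out = medium$n_out)
}
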