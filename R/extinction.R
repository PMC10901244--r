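#' Hemoglobin extinction table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the working
#' wavelengths. Internally everything is stored in natural-log basis with
#' units mm^-1 per micromolar, so that pathlengths from the forward model
#' (mm) combine with concentrations (uM) into natural-log attenuation.
#' Literature tables in decadic basis (cm^-1 per molar) are converted by
#' `ln(10) * 1e-7`.
#'
#' @param wavelengths wavelengths, nm.
#' @param eps_hbo,eps_hbr extinction coefficients of HbO / HbR.
#' @param basis `"ln"` if the inputs are already natural-log mm^-1 uM^-1,
#'   `"log10_cm_M"` for decadic cm^-1 M^-1 literature values.
#' @return Object of class `extinction_table`: data.frame with columns
#'   `wavelength_nm`, `eps_hbo`, `eps_hbr` (ln basis, mm^-1 uM^-1).
#' @export
#' @examples
#' extinction_table(c(690, 830), c(276, 974), c(2051.96, 693.04),
#'                  basis = "log10_cm_M")
extinction_table <- function(wavelengths, eps_hbo, eps_hbr,
                             basis = c("ln", "log10_cm_M")) {
  basis <- match.arg(basis)
  stopifnot(length(wavelengths) == length(eps_hbo),
            length(eps_hbo) == length(eps_hbr),
            all(eps_hbo > 0), all(eps_hbr > 0))
  k <- if (basis == "log10_cm_M") log(10) * 1e-7 else 1
  structure(data.frame(wavelength_nm = wavelengths,
                       eps_hbo = eps_hbo * k,
                       eps_hbr = eps_hbr * k),
            class = c("extinction_table", "data.frame"))
}

#' Bundled two-wavelength extinction table
#'
#' Compiled in-vivo hemoglobin spectra (Prahl/Gratzer) at 690 and 830 nm,
#' one wavelength on each side of the isosbestic point (~800 nm): decadic
#' molar extinctions 276 / 2051.96 (HbO / HbR at 690 nm) and 974 / 693.04
#' (at 830 nm) in cm^-1 M^-1, converted to natural-log mm^-1 uM^-1.
#'
#' @return An [extinction_table()].
#' @export
#' @examples
#' default_extinction_table()
default_extinction_table <- function() {
  extinction_table(c(690, 830), c(276, 974), c(2051.96, 693.04),
                   basis = "log10_cm_M")
}

.eps_matrix <- function(table, wavelengths = c(690, 830)) {
  idx <- match(wavelengths, table$wavelength_nm)
  if (anyNA(idx))
    stop("wavelength(s) ", paste(wavelengths[is.na(idx)], collapse = ", "),
         " nm not present in the extinction table")
  E <- cbind(table$eps_hbo[idx], table$eps_hbr[idx])
  dimnames(E) <- list(as.character(wavelengths), c("hbo", "hbr"))
  E
}

#' Baseline hemoglobin concentrations from an isosbestic absorption
#'
#' Solves the two-wavelength extinction system with the same absorption
#' value on both right-hand-side rows (the convention used when a baseline
#' is quoted at the ~800 nm isosbestic wavelength) for the baseline HbO and
#' HbR concentrations.
#'
#' @param mua_isosbestic absorption coefficient at the isosbestic
#'   wavelength, mm^-1 (>= 0).
#' @param table an [extinction_table()] holding 690 and 830 nm.
#' @param wavelengths the two working wavelengths, nm.
#' @return Named vector `c(hbo = , hbr = )` in uM.
#' @export
#' @examples
#' mua_to_conc(0.018)   # scalp baseline -> c(hbo = 58.78, hbr = 30.19)
mua_to_conc <- function(mua_isosbestic, table = default_extinction_table(),
                        wavelengths = c(690, 830)) {
  stopifnot(is.numeric(mua_isosbestic), mua_isosbestic >= 0)
  E <- .eps_matrix(table, wavelengths)
  if (abs(det(E)) < .Machine$double.eps * max(abs(E))^2)
    stop("extinction matrix is singular")
  x <- solve(E, rep(mua_isosbestic, 2L))
  c(hbo = unname(x[1]), hbr = unname(x[2]))
}

#' Absorption coefficient from hemoglobin concentrations
#'
#' \eqn{\mu_a(\lambda) = \epsilon_{HbO}(\lambda) [HbO] +
#' \epsilon_{HbR}(\lambda) [HbR]}; also applies to changes.
#'
#' @param hbo,hbr concentrations (or changes), uM.
#' @param wavelength wavelength, nm; must be in the table.
#' @param table an [extinction_table()].
#' @return Absorption coefficient, mm^-1 (vectorised over `hbo`/`hbr`).
#' @export
#' @examples
#' conc_to_mua(176.33, 45.29, 690)
conc_to_mua <- function(hbo, hbr, wavelength,
                        table = default_extinction_table()) {
  idx <- match(wavelength, table$wavelength_nm)
  if (is.na(idx)) stop("wavelength ", wavelength, " nm not in the table")
  table$eps_hbo[idx] * hbo + table$eps_hbr[idx] * hbr
}

#' Read an extinction table from a text file
#'
#' Expected format: a first header line `# basis=<ln|log10_cm_M>` followed
#' by a three-column table `wavelength_nm eps_hbo eps_hbr` with a column
#' header row (whitespace- or comma-separated).
#'
#' @param path file path.
#' @return An [extinction_table()].
#' @export
read_extinction_table <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("basis\\s*=\\s*(\\S+)", first))[[1]]
  if (length(m) < 2L)
    stop("missing '# basis=' declaration in ", path)
  basis <- m[2]
  sep <- if (grepl(",", readLines(path, n = 2L)[2])) "," else ""
  df <- utils::read.table(path, header = TRUE, skip = 1L, sep = sep)
  extinction_table(df[[1]], df[[2]], df[[3]], basis = basis)
}

#' Write an extinction table to a text file
#'
#' @param table an [extinction_table()] (ln basis).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extinction_table <- function(table, path) {
  writeLines("# basis=ln units=mm^-1.uM^-1", path)
  suppressWarnings(utils::write.table(
    table, path, append = TRUE, row.names = FALSE, quote = FALSE, sep = ","))
  invisible(path)
}
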