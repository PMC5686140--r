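# Circular dichroism utilities: mean residue ellipticity, helicity
# estimates, RC/PMG double-wavelength classification, thermal-melt sigmoid
# fits, isodichroic-point detection.

#' Construct a CD spectrum
#'
#' @param wavelength Strictly monotone wavelength grid, nm.
#' @param signal Signal values: differential absorbance (\code{type =
#'   "deltaA"}) or mean residue ellipticity in deg cm^2 dmol^-1
#'   (\code{type = "mre"}).
#' @param type Signal type tag.
#' @param meta Optional metadata list: path length \code{l} (cm),
#'   concentration \code{c} (mg/mL), molecular mass \code{M} (Da), residue
#'   count \code{n}. Required before MRE conversion.
#' @return Object of class \code{cd_spectrum}.
#' @export
cd_spectrum <- function(wavelength, signal, type = c("deltaA", "mre"),
                        meta = list()) {
  type <- match.arg(type)
  if (length(wavelength) != length(signal))
    stop("wavelength and signal must have equal length")
  d <- diff(wavelength)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavelength grid must be strictly monotone")
  structure(list(wavelength = wavelength, signal = signal, type = type,
                 meta = meta),
            class = "cd_spectrum")
}

#' Convert differential absorbance to mean residue ellipticity
#'
#' Pointwise \eqn{\Theta = 3300 \, M \, \Delta A / (l \, c \, n)} with l the
#' path length in cm, c the concentration in mg/mL, M the molecular mass in
#' Da and n the residue count. Metadata may be supplied in the spectrum or
#' as arguments.
#'
#' @param spectrum A \code{cd_spectrum} of type \code{deltaA}.
#' @param l,c,M,n Metadata overrides.
#' @return A \code{cd_spectrum} of type \code{mre}.
#' @export
to_mre <- function(spectrum, l = NULL, c = NULL, M = NULL, n = NULL) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  if (spectrum$type == "mre") return(spectrum)
  meta <- spectrum$meta
  l <- l %||% meta$l; c <- c %||% meta$c; M <- M %||% meta$M; n <- n %||% meta$n
  vals <- list(l = l, c = c, M = M, n = n)
  missing <- names(vals)[vapply(vals, is.null, logical(1))]
  if (length(missing))
    stop("missing metadata for MRE conversion: ",
         paste(missing, collapse = ", "))
  if (any(unlist(vals) <= 0)) stop("l, c, M and n must all be positive")
  cd_spectrum(spectrum$wavelength,
              3300 * M * spectrum$signal / (l * c * n),
              type = "mre", meta = utils::modifyList(meta, vals))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alpha-helical fraction from the 220-nm mean residue ellipticity
#'
#' The observed MRE is divided by the value expected for a fully helical
#' chain of n residues, for which the chain-length-corrected form
#' \code{MRE_helix = coef * (1 - finite_corr / n)} is used (defaults
#' -40000 and 2.5). Results outside \[0, 1\] are clipped with a warning.
#'
#' @param MRE_220 Observed mean residue ellipticity at 220 nm,
#'   deg cm^2 dmol^-1 (negative for helix).
#' @param n Residue count (> 2.5).
#' @param coef,finite_corr Helix-maximum model coefficients.
#' @return Helical fraction in \[0, 1\], with attribute \code{mre_helix_max}
#'   recording the 100%-helix value used.
#' @export
helicity_fraction <- function(MRE_220, n, coef = -40000, finite_corr = 2.5) {
  if (!is.finite(n) || n <= finite_corr)
    stop("n must exceed the finite-length correction (", finite_corr, ")")
  hmax <- coef * (1 - finite_corr / n)
  f <- MRE_220 / hmax
  if (f < 0 || f > 1) {
    warning(sprintf("helicity fraction %.3f outside [0,1]; clipped", f))
    f <- min(max(f, 0), 1)
  }
  attr(f, "mre_helix_max") <- hmax
  f
}

# Approximate double-wavelength reference centroids (MRE at 200 and 222 nm,
# deg cm^2 dmol^-1) for random-coil-like and premolten-globule-like IDPs,
# with typical spreads. These are round literature-scale values, not a
# recomputation of any published reference set; classification logic is
# exercised on synthetic points in the tests.
RC_PMG_CENTROIDS <- list(
  RC  = list(mre200 = -18900, mre222 = -1700, sd200 = 2800, sd222 = 700),
  PMG = list(mre200 = -10700, mre222 = -3900, sd200 = 1300, sd222 = 1100)
)

#' Random-coil versus premolten-globule classification from two wavelengths
#'
#' IDPs subdivide into random-coil-like (RC) and premolten-globule-like
#' (PMG) forms by their mean residue ellipticities at 200 and 222 nm. The
#' point is assigned to the nearest reference-class centroid (distances
#' standardized by each class's spread); points whose two distances differ
#' by less than \code{boundary_tol} (relative) are labelled "boundary".
#'
#' @param MRE_200,MRE_222 Mean residue ellipticities, deg cm^2 dmol^-1.
#' @param boundary_tol Relative distance difference below which the point
#'   is called boundary.
#' @return List with \code{class} ("RC-like", "PMG-like" or "boundary"),
#'   \code{coordinates} and the standardized \code{distances}.
#' @export
classify_rc_pmg <- function(MRE_200, MRE_222, boundary_tol = 0.05) {
  if (!is.finite(MRE_200) || !is.finite(MRE_222))
    stop("both ellipticity values are required")
  d <- vapply(RC_PMG_CENTROIDS, function(ct)
    sqrt(((MRE_200 - ct$mre200) / ct$sd200)^2 +
           ((MRE_222 - ct$mre222) / ct$sd222)^2), numeric(1))
  rel <- abs(d[1] - d[2]) / max(mean(d), 1e-12)
  cls <- if (rel < boundary_tol) "boundary"
         else if (d[["RC"]] < d[["PMG"]]) "RC-like" else "PMG-like"
  list(class = cls,
       coordinates = c(MRE_200 = MRE_200, MRE_222 = MRE_222),
       distances = d)
}

#' Fit a thermal melt with a four-parameter Boltzmann sigmoid
#'
#' \code{MRE(T) = A + (B - A) / (1 + exp((Tm - T)/s))}: folded/unfolded
#' baselines A and B, midpoint Tm (degrees C) and transition slope s.
#' Reports asymptotic standard errors and a fit-quality flag (\code{"poor"}
#' when R^2 < 0.9 or the midpoint falls outside the measured range).
#'
#' @param temperature Temperature grid, degrees C (at least 8 points).
#' @param signal MRE values at the monitored wavelength.
#' @return Object of class \code{melt_fit}: \code{Tm}, \code{slope},
#'   \code{A}, \code{B}, \code{se} (named vector), \code{r_squared},
#'   \code{quality}, \code{fitted}.
#' @export
melt_fit <- function(temperature, signal) {
  if (length(temperature) != length(signal))
    stop("temperature and signal must have equal length")
  if (length(temperature) < 8L)
    stop("at least 8 temperature points are required")
  df <- data.frame(T = temperature, y = signal)
  rng <- range(signal)
  if (diff(rng) < 1e-9 * max(abs(rng), 1))
    stop("melt curve is flat; no transition to fit")
  start <- list(A = signal[which.min(temperature)],
                B = signal[which.max(temperature)],
                Tm = stats::median(temperature), s = diff(range(temperature)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp((Tm - T) / s)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("melt fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  fitted <- stats::fitted(fit)
  r2 <- 1 - sum((signal - fitted)^2) / sum((signal - mean(signal))^2)
  in_range <- co[["Tm"]] >= min(temperature) && co[["Tm"]] <= max(temperature)
  if (!in_range)
    warning("fitted transition midpoint lies outside the measured range")
  structure(
    list(Tm = co[["Tm"]], slope = co[["s"]], A = co[["A"]], B = co[["B"]],
         se = se, r_squared = r2,
         quality = if (r2 < 0.9 || !in_range) "poor" else "good",
         fitted = fitted, temperature = temperature, signal = signal),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf(
    "<melt_fit> Tm = %.1f C (se %.2g), slope = %.2f, R^2 = %.4f [%s]\n",
    x$Tm, unname(x$se["Tm"]), x$slope, x$r_squared, x$quality))
  invisible(x)
}

#' Isodichroic-point detection across a family of spectra
#'
#' A family of spectra from a two-state transition crosses at a common
#' wavelength. The wavelength minimizing the across-spectra standard
#' deviation is reported as isodichroic when that minimum is below
#' \code{tol_frac} of the overall signal range; families with no common
#' crossing return none, and identical spectra are flagged degenerate.
#'
#' @param spectra List of at least 3 \code{cd_spectrum} objects (type mre)
#'   on a common wavelength grid.
#' @param tol_frac Detection threshold as a fraction of the signal range.
#' @return List with \code{wavelength} (NA when none), \code{min_sd},
#'   \code{detected} and \code{note}.
#' @export
isodichroic_point <- function(spectra, tol_frac = 0.05) {
  if (length(spectra) < 3L) stop("at least 3 spectra are required")
  wl <- spectra[[1]]$wavelength
  for (sp in spectra[-1])
    if (length(sp$wavelength) != length(wl) ||
        any(abs(sp$wavelength - wl) > 1e-9))
      stop("spectra are not on a common wavelength grid")
  mat <- vapply(spectra, function(sp) sp$signal, numeric(length(wl)))
  sds <- apply(mat, 1, stats::sd)
  rng <- diff(range(mat))
  if (rng < 1e-12 || all(sds < 1e-9 * max(abs(mat), 1)))
    return(list(wavelength = NA_real_, min_sd = min(sds), detected = FALSE,
                note = "degenerate: spectra are identical"))
  i <- which.min(sds)
  detected <- sds[i] < tol_frac * rng
  list(wavelength = if (detected) wl[i] else NA_real_,
       min_sd = sds[i], detected = detected,
       note = if (detected) "isodichroic point found"
              else "no common crossing")
}
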