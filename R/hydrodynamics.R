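# SEC hydrodynamics: Stokes-radius power laws for conformational states,
# compaction index, nearest-state classification, and SEC calibration.

# log10-linear Stokes-radius laws, Rs in Angstrom, MM in Dalton.
RS_LAWS <- list(
  standard = c(slope = 0.369, intercept = -0.254),  # globular SEC standards
  NF  = c(slope = 0.357, intercept = -0.204),       # natively folded
  U   = c(slope = 0.521, intercept = -0.649),       # urea-unfolded
  PMG = c(slope = 0.392, intercept = -0.210),       # premolten globule
  MG  = c(slope = 0.334, intercept = -0.053)        # molten globule
)

# Flory-type power law for the Stokes radius of an IDP, Rs = R0 * N^nu.
RS_IDP_COEF <- c(R0 = 2.49, nu = 0.509)

rs_power_law <- function(MM, law) 10^(law[["slope"]] * log10(MM) +
                                      law[["intercept"]])

#' Stokes radius of a globular SEC standard from molecular mass
#'
#' The calibration-standard law \code{log10(Rs) = 0.369 log10(MM) - 0.254}
#' (Rs in Angstrom, MM in Dalton).
#'
#' @param MM Molecular mass in Da.
#' @return Stokes radius in Angstrom.
#' @export
rs_standard <- function(MM) {
  if (any(!is.finite(MM)) || any(MM <= 0)) stop("MM must be positive")
  rs_power_law(MM, RS_LAWS$standard)
}

#' Expected Stokes radius for a conformational state
#'
#' Mass power laws for the natively folded (NF), molten globule (MG),
#' premolten globule (PMG) and fully unfolded (U) states, plus the folded
#' dimer (DimNF), which is the NF law evaluated at twice the mass.
#'
#' @param MM Molecular mass in Da (monomer mass for DimNF).
#' @param state One of "NF", "MG", "PMG", "U", "DimNF".
#' @return Expected Stokes radius in Angstrom.
#' @examples
#' expected_rs(15922, "NF")   # ~19.8
#' expected_rs(15922, "U")    # ~34.7
#' @export
expected_rs <- function(MM, state = c("NF", "MG", "PMG", "U", "DimNF")) {
  if (any(!is.finite(MM)) || any(MM <= 0)) stop("MM must be positive")
  state <- match.arg(state)
  if (state == "DimNF") rs_power_law(2 * MM, RS_LAWS$NF)
  else rs_power_law(MM, RS_LAWS[[state]])
}

#' Expected Stokes radius of an IDP from chain length
#'
#' Flory-type power law \code{Rs = 2.49 N^0.509} (Angstrom). Use the
#' residue count of the measured construct (including any vector-encoded
#' extension) when classifying SEC observations.
#'
#' @param N Residue count.
#' @return Stokes radius in Angstrom.
#' @export
rs_idp <- function(N) {
  if (any(!is.finite(N)) || any(N <= 0)) stop("N must be positive")
  RS_IDP_COEF[["R0"]] * N^RS_IDP_COEF[["nu"]]
}

#' Compaction index from observed Stokes radius
#'
#' \code{CI = (Rs_U - Rs_obs) / (Rs_U - Rs_NF)}: 1 when the protein is as
#' compact as a folded globule of its mass, 0 when as expanded as the
#' urea-unfolded state. Values outside \[0, 1\] are returned with a warning,
#' not clamped.
#'
#' @param Rs_obs Observed Stokes radius, Angstrom.
#' @param MM Molecular mass, Da.
#' @return Compaction index (dimensionless).
#' @export
compaction_index <- function(Rs_obs, MM) {
  if (!is.finite(Rs_obs) || Rs_obs <= 0) stop("Rs_obs must be positive")
  u <- expected_rs(MM, "U"); nf <- expected_rs(MM, "NF")
  if (abs(u - nf) < 1e-9)
    stop("degenerate state radii (Rs_U = Rs_NF); cannot form CI")
  ci <- (u - Rs_obs) / (u - nf)
  if (ci < 0 || ci > 1)
    warning(sprintf("compaction index %.3f outside [0,1]", ci))
  ci
}

#' Hydrodynamic state report (Table-style row)
#'
#' Computes, from an observed Stokes radius, the molecular mass and the
#' construct residue count, the expected radii of all conformational states,
#' the observed/expected ratios, the compaction index, and the nearest-state
#' call.
#'
#' @param MM Molecular mass, Da.
#' @param Rs_obs Observed Stokes radius, Angstrom.
#' @param N Residue count of the measured construct (echoed in the report
#'   and used for the IDP power law).
#' @param id Label.
#' @return Object of class \code{hydro_report}: a list with \code{expected}
#'   (named radii), \code{ratios}, \code{CI}, \code{nearest_state} and the
#'   inputs.
#' @examples
#' hydro_report(15922, 24.7, 143)
#' @export
hydro_report <- function(MM, Rs_obs, N, id = "protein") {
  states <- c("NF", "MG", "PMG", "U", "DimNF")
  expected <- vapply(states, expected_rs, numeric(1), MM = MM)
  expected <- c(expected, IDP = rs_idp(N))
  ratios <- Rs_obs / expected
  rep <- structure(
    list(id = id, MM = MM, Rs_obs = Rs_obs, N = N,
         expected = expected, ratios = ratios,
         CI = compaction_index(Rs_obs, MM)),
    class = "hydro_report")
  rep$nearest_state <- classify_state(rep)
  rep
}

#' Nearest conformational state from observed/expected ratios
#'
#' The state whose ratio Rs_obs/Rs_state is closest to 1. Ties are broken
#' toward the more compact state (smaller expected radius) and reported.
#'
#' @param report A [hydro_report()].
#' @return Character state label, with attribute \code{tie} when a tie was
#'   broken.
#' @export
classify_state <- function(report) {
  dev <- abs(report$ratios - 1)
  best <- which(dev <= min(dev) + 1e-12)
  tie <- length(best) > 1L
  if (tie) best <- best[which.min(report$expected[best])]
  out <- names(report$ratios)[best]
  if (tie) attr(out, "tie") <- TRUE
  out
}

#' @export
print.hydro_report <- function(x, digits = 1, ...) {
  cat(sprintf("<hydro_report> %s: MM = %.0f Da, N = %d, Rs_obs = %.1f A\n",
              x$id, x$MM, x$N, x$Rs_obs))
  cat("expected Rs (A): ",
      paste(sprintf("%s=%.1f", names(x$expected), x$expected),
            collapse = "  "), "\n")
  cat("ratios obs/exp:  ",
      paste(sprintf("%s=%.2f", names(x$ratios), x$ratios),
            collapse = "  "), "\n")
  cat(sprintf("CI = %.2f, nearest state: %s\n", x$CI, x$nearest_state))
  invisible(x)
}

#' @rdname hydro_report
#' @param x A \code{hydro_report}.
#' @export
as.data.frame.hydro_report <- function(x, ...) {
  data.frame(id = x$id, MM = x$MM, N = x$N, Rs_obs = x$Rs_obs,
             t(x$expected), t(stats::setNames(x$ratios,
                                              paste0("ratio_", names(x$ratios)))),
             CI = x$CI, nearest_state = x$nearest_state,
             stringsAsFactors = FALSE)
}

#' Calibrate a SEC column from standards
#'
#' Least-squares line of log10(Rs) against elution volume, where each
#' standard's Stokes radius comes from its molecular mass via
#' [rs_standard()].
#'
#' @param standards data.frame with columns \code{MM} (Da) and \code{Ve}
#'   (elution volume, mL); at least 3 rows.
#' @return Object of class \code{sec_calibration} with the fit, residuals
#'   and calibrated Ve range.
#' @export
calibrate_sec <- function(standards) {
  if (!all(c("MM", "Ve") %in% names(standards)))
    stop("standards must have columns MM and Ve")
  if (nrow(standards) < 3L) stop("at least 3 SEC standards are required")
  log_rs <- log10(rs_standard(standards$MM))
  fit <- stats::lm(log_rs ~ Ve, data = data.frame(log_rs, Ve = standards$Ve))
  structure(
    list(coefficients = stats::coef(fit),
         residuals = stats::resid(fit),
         sigma = summary(fit)$sigma,
         r_squared = summary(fit)$r.squared,
         ve_range = range(standards$Ve),
         standards = standards),
    class = "sec_calibration")
}

#' Stokes radius from elution volume via a SEC calibration
#'
#' @param cal A [calibrate_sec()] object.
#' @param Ve Elution volume(s), mL. Queries outside the calibrated range
#'   trigger an extrapolation warning.
#' @return Stokes radius in Angstrom.
#' @export
rs_from_elution <- function(cal, Ve) {
  if (!inherits(cal, "sec_calibration")) stop("cal must be a sec_calibration")
  if (any(Ve < cal$ve_range[1] | Ve > cal$ve_range[2]))
    warning("elution volume outside calibrated range; extrapolating")
  10^(cal$coefficients[[1]] + cal$coefficients[[2]] * Ve)
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "<sec_calibration> log10(Rs) = %.4f %+.4f Ve  (n = %d, R^2 = %.4f)\n",
    x$coefficients[[1]], x$coefficients[[2]], nrow(x$standards), x$r_squared))
  invisible(x)
}
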