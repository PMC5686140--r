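# SAXS analysis: scattering-curve container, Guinier fits, regularized
# indirect Fourier transform for P(r)/Dmax, Kratky/Porod diagnostics,
# I(0)-based molecular mass, and expected-size calculators.

#' Construct a scattering curve
#'
#' Container for a 1-D SAXS curve: momentum transfer q (Angstrom^-1, with
#' the convention q = 4 pi/lambda sin(theta)), intensity I (arbitrary
#' units), and per-point uncertainties. Curves lacking uncertainties get
#' uniform weights with a warning.
#'
#' @param q Strictly increasing positive momentum transfer, Angstrom^-1.
#' @param I Intensities.
#' @param sigma Optional per-point uncertainties (> 0).
#' @return Object of class \code{scattering_curve} (a list with \code{q},
#'   \code{I}, \code{sigma}).
#' @export
scattering_curve <- function(q, I, sigma = NULL) {
  if (length(q) != length(I)) stop("q and I must have equal length")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive and finite")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (is.null(sigma)) {
    warning("no uncertainties supplied; using uniform weights")
    sigma <- rep(stats::sd(I) * 0.01 + 1e-12, length(I))
  }
  if (length(sigma) != length(I) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be positive and match the curve length")
  structure(list(q = as.numeric(q), I = as.numeric(I),
                 sigma = as.numeric(sigma)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q = %.4g..%.4g A^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Convert momentum transfer between Angstrom^-1 and nm^-1
#'
#' @param curve A [scattering_curve()].
#' @param from,to Unit labels, "A" or "nm". 1 A^-1 = 10 nm^-1.
#' @return The curve with q rescaled.
#' @export
convert_q_units <- function(curve, from = c("nm", "A"), to = c("A", "nm")) {
  from <- match.arg(from); to <- match.arg(to)
  fac <- c(A = 1, nm = 0.1)
  curve$q <- curve$q * fac[[from]] / fac[[to]]
  curve
}

# -- Analytic model intensities (used by tests and generators) -------------

#' Analytic model scattering intensities
#'
#' \code{sphere_intensity} is the homogeneous-sphere form factor
#' \eqn{[3(\sin qR - qR\cos qR)/(qR)^3]^2}; \code{debye_coil_intensity} is
#' the Debye function of a Gaussian coil,
#' \eqn{2(e^{-x} - 1 + x)/x^2} with \eqn{x = q^2 R_g^2}. Both are
#' normalized to I(0) = 1.
#'
#' @param q Momentum transfer, Angstrom^-1.
#' @param R Sphere radius, Angstrom.
#' @param Rg Coil radius of gyration, Angstrom.
#' @return Intensity values.
#' @export
sphere_intensity <- function(q, R) {
  x <- q * R
  f <- ifelse(x < 1e-6, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  f^2
}

#' @rdname sphere_intensity
#' @export
debye_coil_intensity <- function(q, Rg) {
  x <- (q * Rg)^2
  ifelse(x < 1e-8, 1, 2 * (exp(-x) - 1 + x) / x^2)
}

# -- Guinier analysis ------------------------------------------------------

#' Guinier fit of the low-q region
#'
#' Weighted fit of \eqn{\ln I} against \eqn{q^2}
#' (\eqn{\ln I(q) = \ln I_0 - q^2 R_g^2/3}). The window starts at the
#' lowest usable q and expands while \eqn{q R_g \le} \code{qRg_max},
#' iterating window and fit until mutually consistent. Because
#' \eqn{\ln I} of real particles is not exactly linear over the whole
#' \eqn{q R_g \le 1.3} range, windows with at least 12 points include a
#' quadratic term in \eqn{q^2} that absorbs the leading curvature; Rg and
#' I(0) are always taken from the linear term, i.e. the \eqn{q \to 0}
#' limit of the Guinier law. This keeps the estimator essentially unbiased
#' for both compact and coil-like particles.
#'
#' @param curve A [scattering_curve()].
#' @param qRg_max Upper limit of q*Rg for points entering the fit.
#' @param curvature_correction Include the quadratic curvature term when
#'   the window allows it.
#' @return Object of class \code{guinier_fit} with \code{Rg}, \code{I0},
#'   \code{q_range}, \code{n_points}, \code{qRg_max_used} (largest q*Rg in
#'   the window), \code{chi2} and \code{residuals}.
#' @export
guinier_fit <- function(curve, qRg_max = 1.3, curvature_correction = TRUE) {
  stopifnot(inherits(curve, "scattering_curve"))
  usable <- which(curve$I > 0)
  if (length(usable) < 5L) stop("fewer than 5 usable points for Guinier fit")
  q <- curve$q[usable]; I <- curve$I[usable]; s <- curve$sigma[usable]
  ln_i <- log(I)
  w <- (I / s)^2          # var(ln I) ~ (sigma/I)^2
  lin_fit <- function(n_end) {
    idx <- seq_len(n_end)
    stats::lm(y ~ x, data = data.frame(y = ln_i[idx], x = q[idx]^2),
              weights = w[idx])
  }
  # self-consistent window under the q*Rg cap
  n_end <- 5L
  for (iter in 1:50) {
    fit <- lin_fit(n_end)
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) {
      if (n_end < length(q)) { n_end <- min(length(q), n_end * 2L); next }
      stop("non-Guinier curve: no intensity decay at low q")
    }
    rg <- sqrt(-3 * slope)
    new_end <- min(length(q), max(5L, findInterval(qRg_max / rg, q)))
    if (new_end == n_end) break
    n_end <- new_end
  }
  if (slope >= 0)
    stop("non-Guinier curve: no intensity decay at low q")
  # curvature-corrected refit: Rg from the linear (q -> 0) term
  if (curvature_correction && n_end >= 12L) {
    idx <- seq_len(n_end)
    fit2 <- stats::lm(y ~ x + I(x^2),
                      data = data.frame(y = ln_i[idx], x = q[idx]^2),
                      weights = w[idx])
    if (stats::coef(fit2)[[2]] < 0) fit <- fit2
  }
  slope <- stats::coef(fit)[[2]]
  rg <- sqrt(-3 * slope)
  if (!is.finite(rg) || rg * q[n_end] < 0.05)
    stop("non-Guinier curve: no intensity decay at low q")
  idx <- seq_len(n_end)
  chi2 <- sum(w[idx] * stats::resid(fit)^2) /
    max(1, n_end - length(stats::coef(fit)))
  structure(
    list(Rg = rg, I0 = exp(stats::coef(fit)[[1]]),
         q_range = c(q[1], q[n_end]), n_points = n_end,
         qRg_max_used = q[n_end] * rg, qRg_max = qRg_max,
         chi2 = chi2, residuals = stats::resid(fit)),
    class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.2f A, I0 = %.4g (%d pts, q = %.4g..%.4g, qRg <= %.2f)\n",
    x$Rg, x$I0, x$n_points, x$q_range[1], x$q_range[2], x$qRg_max_used))
  invisible(x)
}

# -- Indirect Fourier transform for P(r) -----------------------------------

# Design matrix: I(q) = 4 pi * integral_0^Dmax P(r) sinc(q r) dr with P
# expanded in sines vanishing at 0 and Dmax.
ift_design_matrix <- function(q, Dmax, n_basis, nr = 401L) {
  r <- seq(0, Dmax, length.out = nr)
  dr <- r[2] - r[1]
  tw <- rep(dr, nr); tw[c(1, nr)] <- dr / 2          # trapezoid weights
  sinc <- function(x) ifelse(abs(x) < 1e-9, 1, sin(x) / x)
  K <- outer(q, r, function(qq, rr) sinc(qq * rr))   # nq x nr
  B <- outer(r, seq_len(n_basis), function(rr, k) sin(k * pi * rr / Dmax))
  list(A = 4 * pi * (K %*% (tw * B)), r = r, B = B, tw = tw)
}

ift_solve <- function(A, I, w, lambda, penalty) {
  AtW <- t(A * w)
  ch <- AtW %*% A + lambda * penalty
  solve(ch, AtW %*% I)
}

#' Pair-distance distribution by regularized indirect Fourier transform
#'
#' Expands P(r) in a sine basis vanishing at r = 0 and r = Dmax and fits the
#' basis coefficients to the measured curve through the Fourier kernel
#' sin(qr)/(qr), with a smoothness penalty on the curvature of P(r). When
#' \code{lambda} is NULL the penalty weight is chosen automatically: the
#' strongest smoothing whose chi-square stays within 10% of the best
#' achievable over a log-spaced grid.
#'
#' @param curve A [scattering_curve()].
#' @param Dmax Assumed maximum particle dimension, Angstrom.
#' @param n_basis Number of sine basis functions; default
#'   \code{ceiling(Dmax * max(q) / pi) + 5}.
#' @param lambda Smoothness weight, or NULL for automatic selection.
#' @return Object of class \code{pofr}: \code{r}, \code{pr}, \code{Dmax},
#'   \code{Rg}, \code{I0}, \code{chi2} (reduced, against the input curve),
#'   \code{lambda}, \code{I_fit}.
#' @export
ift_pr <- function(curve, Dmax, n_basis = NULL, lambda = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (!is.finite(Dmax) || Dmax <= 0) stop("Dmax must be positive")
  q <- curve$q; I <- curve$I; s <- curve$sigma
  if (is.null(n_basis)) n_basis <- ceiling(Dmax * max(q) / pi) + 8L
  if (n_basis < 3L) n_basis <- 3L
  dm <- ift_design_matrix(q, Dmax, n_basis)
  w <- 1 / s^2
  # curvature penalty: integral P''(r)^2 dr is diagonal in the sine basis
  pen <- diag((seq_len(n_basis) * pi / Dmax)^4 * Dmax / 2, n_basis)
  AtWA <- t(dm$A * w) %*% dm$A
  base <- sum(diag(AtWA)) / sum(diag(pen))
  if (is.null(lambda)) {
    # strongest smoothing that does not degrade the fit: largest lambda
    # whose chi-square stays within 10% of the best achievable on a
    # log-spaced grid
    lgrid <- base * 10^seq(-12, 2, length.out = 43)
    nq <- length(q)
    chi <- vapply(lgrid, function(lam) {
      cj <- tryCatch(ift_solve(dm$A, I, w, lam, pen),
                     error = function(e) NULL)
      if (is.null(cj)) return(NA_real_)
      sum(w * (I - dm$A %*% cj)^2) / max(1, nq - 1)
    }, numeric(1))
    ok <- which(is.finite(chi))
    if (!length(ok)) stop("ill-conditioned basis; try fewer basis functions")
    chi_min <- min(chi[ok])
    eligible <- ok[chi[ok] <= 1.1 * chi_min + 1e-12]
    lambda <- max(lgrid[eligible])
  }
  cf <- tryCatch(ift_solve(dm$A, I, w, lambda, pen),
                 error = function(e)
                   stop("ill-conditioned basis; try fewer basis functions"))
  pr <- drop(dm$B %*% cf)
  I_fit <- drop(dm$A %*% cf)
  tw <- dm$tw
  m0 <- sum(tw * pr)
  rg2 <- sum(tw * dm$r^2 * pr) / (2 * m0)
  if (!is.finite(rg2) || rg2 <= 0)
    warning("P(r) has non-positive second moment; Rg undefined")
  structure(
    list(r = dm$r, pr = pr, Dmax = Dmax,
         Rg = if (is.finite(rg2) && rg2 > 0) sqrt(rg2) else NA_real_,
         I0 = 4 * pi * m0,
         chi2 = sum(((I - I_fit) / s)^2) / max(1, length(q) - 1),
         lambda = lambda, n_basis = n_basis, coefficients = drop(cf),
         I_fit = I_fit),
    class = "pofr")
}

#' @export
print.pofr <- function(x, ...) {
  cat(sprintf(
    "<pofr> Dmax = %.1f A, Rg = %.2f A, I0 = %.4g, chi2 = %.3g (lambda = %.3g)\n",
    x$Dmax, x$Rg, x$I0, x$chi2, x$lambda))
  invisible(x)
}

#' Automatic Dmax selection for the indirect transform
#'
#' Scans a Dmax grid and picks the smallest value whose real-space Rg agrees
#' with the Guinier Rg within \code{rg_tol}, whose P(r) is non-negative up
#' to a small tolerance, and whose fit quality is close to the best over the
#' grid; mirrors the practice of adjusting Dmax until the transform and
#' Guinier radii agree.
#'
#' @param curve A [scattering_curve()].
#' @param guinier Optional precomputed [guinier_fit()].
#' @param dmax_grid Candidate Dmax values; default 1.5-4.5 times the Guinier
#'   Rg in steps of 0.05 Rg.
#' @param rg_tol Relative Rg agreement required (default 2%).
#' @return The selected [ift_pr()] result, with attribute \code{scan} (the
#'   grid diagnostics).
#' @export
auto_dmax <- function(curve, guinier = NULL, dmax_grid = NULL, rg_tol = 0.02) {
  if (is.null(guinier)) guinier <- guinier_fit(curve)
  rg <- guinier$Rg
  if (is.null(dmax_grid)) dmax_grid <- seq(1.5, 4.5, by = 0.05) * rg
  fits <- lapply(dmax_grid, function(d)
    tryCatch(ift_pr(curve, d), error = function(e) NULL))
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]; dmax_grid <- dmax_grid[keep]
  if (!length(fits)) stop("indirect transform failed on every Dmax candidate")
  rg_ok <- vapply(fits, function(f)
    is.finite(f$Rg) && abs(f$Rg - rg) / rg <= rg_tol, logical(1))
  pos_ok <- vapply(fits, function(f)
    min(f$pr) >= -0.02 * max(abs(f$pr)), logical(1))
  chi2 <- vapply(fits, function(f) f$chi2, numeric(1))
  chi_ok <- chi2 <= 1.5 * min(chi2)
  eligible <- which(rg_ok & pos_ok & chi_ok)
  if (length(eligible)) {
    pick <- eligible[1L]   # smallest eligible Dmax
  } else {
    warning("no Dmax candidate met all criteria; returning best Rg match")
    pick <- which.min(abs(vapply(fits, function(f) f$Rg, numeric(1)) - rg))
  }
  out <- fits[[pick]]
  attr(out, "scan") <- data.frame(
    Dmax = dmax_grid, Rg = vapply(fits, function(f) f$Rg, numeric(1)),
    chi2 = chi2, rg_ok = rg_ok, pos_ok = pos_ok)
  out
}

# -- Shape diagnostics -----------------------------------------------------

#' Kratky transform
#'
#' @param curve A [scattering_curve()].
#' @return data.frame with \code{q} and \code{q2I} (= q^2 I).
#' @export
kratky <- function(curve) {
  stopifnot(inherits(curve, "scattering_curve"))
  data.frame(q = curve$q, q2I = curve$q^2 * curve$I)
}

#' Porod log-log slope diagnostic
#'
#' Rebins the high-q portion of the curve into geometric q bins, fits local
#' log-log slopes over sliding windows, and classifies the curve as
#' "globular-like" when a sustained slope at or below \code{slope_cut}
#' (Porod q^-4 behaviour, allowing for binning noise) is present, otherwise
#' "no sharp interface" (disordered chains level off at ~q^-2).
#'
#' @param curve A [scattering_curve()].
#' @param q_min Lower q bound for the diagnostic, Angstrom^-1.
#' @param bins_per_decade Geometric rebinning density.
#' @param window Number of consecutive bins per local slope fit.
#' @param slope_cut Detection threshold on the local slope.
#' @return List with \code{slopes} (data.frame of window centres and
#'   slopes), \code{min_slope} and \code{classification}.
#' @export
porod_loglog <- function(curve, q_min = 0.1, bins_per_decade = 15L,
                         window = 6L, slope_cut = -3.5) {
  stopifnot(inherits(curve, "scattering_curve"))
  sel <- curve$q >= q_min & curve$I > 0
  if (sum(sel) < 3 * window) {
    warning("insufficient high-q coverage for Porod diagnostic")
    return(list(slopes = data.frame(q = numeric(), slope = numeric()),
                min_slope = NA_real_, classification = "insufficient data"))
  }
  q <- curve$q[sel]; I <- curve$I[sel]
  edges <- 10^seq(log10(min(q)), log10(max(q)),
                  by = 1 / bins_per_decade)
  bin <- findInterval(q, edges, rightmost.closed = TRUE)
  qb <- tapply(q, bin, mean); ib <- tapply(I, bin, mean)
  ok <- is.finite(qb) & is.finite(ib) & ib > 0
  qb <- qb[ok]; ib <- ib[ok]
  nb <- length(qb)
  if (nb < window + 1)
    return(list(slopes = data.frame(q = numeric(), slope = numeric()),
                min_slope = NA_real_, classification = "insufficient data"))
  centres <- slopes <- numeric(nb - window + 1L)
  for (i in seq_along(slopes)) {
    idx <- i:(i + window - 1L)
    fit <- stats::lsfit(log10(qb[idx]), log10(ib[idx]))
    slopes[i] <- fit$coefficients[[2]]
    centres[i] <- exp(mean(log(qb[idx])))
  }
  min_slope <- min(slopes)
  list(slopes = data.frame(q = centres, slope = slopes),
       min_slope = min_slope,
       classification = if (min_slope <= slope_cut) "globular-like"
                        else "no sharp interface")
}

# -- Molecular mass and expected sizes -------------------------------------

#' Molecular mass from forward scattering, calibrated against a reference
#'
#' \code{MM = MM_ref * (I0/c) / (I0_ref/c_ref)}; the reference is typically
#' bovine serum albumin.
#'
#' @param I0 Forward intensity of the sample.
#' @param c Sample concentration, g/L.
#' @param reference_I0,reference_c,reference_MM Reference values (same units;
#'   MM in Da).
#' @return Molecular mass in Da.
#' @export
mm_from_i0 <- function(I0, c, reference_I0, reference_c, reference_MM) {
  vals <- c(I0, c, reference_I0, reference_c, reference_MM)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be positive")
  reference_MM * (I0 / c) / (reference_I0 / reference_c)
}

#' Expected radius of gyration for reference conformational models
#'
#' Closed-form expectations used to interpret a measured Rg:
#' \describe{
#'   \item{IDP_flory}{Flory power law \code{Rg = R0 N^nu} with IDP-pool
#'     coefficients R0 = 2.54 Angstrom, nu = 0.522.}
#'   \item{globular}{\code{Rg = sqrt(3/5) * 4.75 * N^0.29}.}
#'   \item{unfolded}{\code{log10(Rg) = 0.58 log10(N) + 0.80} (chemically
#'     denatured chains).}
#'   \item{from_Rs}{\code{Rg = sqrt(3/5) * Rs} for a globule of hydrodynamic
#'     radius \code{Rs}.}
#'   \item{sphere_from_volume}{radius of the equivalent sphere at 134
#'     cubic-Angstrom per residue, \code{(3 N 134 / 4 pi)^(1/3)}, returned
#'     together with its Rg = sqrt(3/5) * radius.}
#' }
#'
#' @param N Residue count (ignored for \code{from_Rs}).
#' @param model Model name (above).
#' @param Rs Stokes radius, required for \code{from_Rs}.
#' @param R0,nu Flory coefficients for \code{IDP_flory}.
#' @return Rg in Angstrom; for \code{sphere_from_volume} a named vector
#'   \code{c(radius =, Rg =)}.
#' @examples
#' expected_rg(143, "IDP_flory")   # 33.9
#' expected_rg(143, "globular")    # ~15.5
#' @export
expected_rg <- function(N, model = c("IDP_flory", "globular", "unfolded",
                                     "from_Rs", "sphere_from_volume"),
                        Rs = NULL, R0 = 2.54, nu = 0.522) {
  model <- match.arg(model)
  if (model != "from_Rs" && (!is.finite(N) || N <= 0))
    stop("N must be positive")
  switch(model,
    IDP_flory = R0 * N^nu,
    globular = sqrt(3 / 5) * 4.75 * N^0.29,
    unfolded = 10^(0.58 * log10(N) + 0.80),
    from_Rs = {
      if (is.null(Rs) || !is.finite(Rs) || Rs <= 0)
        stop("model 'from_Rs' requires a positive Rs")
      sqrt(3 / 5) * Rs
    },
    sphere_from_volume = {
      radius <- (3 * N * 134 / (4 * pi))^(1 / 3)
      c(radius = radius, Rg = sqrt(3 / 5) * radius)
    })
}
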