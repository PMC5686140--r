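# Synthetic-data generators. Every generator is deterministic under a
# fixed seed and embeds its ground truth in the returned object, so each
# analysis stage can be tested by a generate-then-recover round trip.

#' Generate a protein sequence with prescribed composition and kappa
#'
#' Residues are drawn to match the requested composition (largest-remainder
#' rounding to exact counts), then charged positions are rearranged by
#' simulated annealing (swaps that change the charge pattern only) until
#' the kappa patterning parameter is within \code{tol} of
#' \code{target_kappa} or the iteration cap is reached. If the target is
#' infeasible for the composition the best-achieved sequence is returned
#' with a warning.
#'
#' @param length Residue count.
#' @param composition Named fractions over the 20 standard residues
#'   (subsets allowed), summing to 1.
#' @param target_kappa Target kappa in \[0, 1\], or NULL for no annealing.
#' @param seed Integer seed.
#' @param tol Acceptable |kappa - target|.
#' @param max_iter Annealing iteration cap.
#' @param id Sequence identifier.
#' @return A [protein_sequence()] with attribute \code{achieved_kappa}.
#' @export
gen_sequence <- function(length, composition, target_kappa = NULL,
                         seed = 1L, tol = 0.01, max_iter = 20000L,
                         id = "synthetic") {
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition must sum to 1")
  if (!all(names(composition) %in% AA_STANDARD))
    stop("composition names must be standard one-letter codes")
  set.seed(seed)
  # largest-remainder rounding to exact residue counts
  raw <- composition * length
  counts <- floor(raw)
  short <- length - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  residues <- rep(names(composition), counts)
  residues <- sample(residues)
  charged <- residues %in% c("K", "R", "D", "E")
  if (!is.null(target_kappa)) {
    if (target_kappa < 0 || target_kappa > 1)
      stop("target_kappa must lie in [0, 1]")
    if (!any(charged))
      stop("kappa target requested but composition has no charged residues")
    kap_of <- function(res)
      kappa_patterning(protein_sequence(paste(res, collapse = ""), id = id))
    if (target_kappa >= 1 - 1e-9) {
      # the segregated block arrangement is the kappa = 1 construction
      chg <- ifelse(residues %in% c("K", "R"), 1L,
                    ifelse(residues %in% c("D", "E"), -1L, 0L))
      residues <- c(residues[chg > 0], residues[chg == 0], residues[chg < 0])
    }
    cur <- kap_of(residues)
    best <- residues; best_err <- abs(cur - target_kappa)
    it <- 0L
    while (best_err > tol && it < max_iter) {
      it <- it + 1L
      i <- sample(which(charged), 1L)
      j <- sample.int(length, 1L)
      if (residues[i] == residues[j]) next
      prop <- residues
      prop[c(i, j)] <- prop[c(j, i)]
      knew <- kap_of(prop)
      err_new <- abs(knew - target_kappa)
      temp <- 0.02 * (1 - it / max_iter) + 1e-5
      if (err_new < best_err ||
          stats::runif(1) < exp((best_err - err_new) / temp)) {
        residues <- prop
        charged <- residues %in% c("K", "R", "D", "E")
        if (err_new < best_err) { best <- prop; best_err <- err_new }
      }
    }
    residues <- best
    if (best_err > tol)
      warning(sprintf(
        "annealing stalled at kappa error %.4f (target %.3f); returning best",
        best_err, target_kappa))
  }
  out <- protein_sequence(paste(residues, collapse = ""), id = id)
  attr(out, "achieved_kappa") <-
    tryCatch(kappa_patterning(out), error = function(e) NA_real_)
  out
}

#' ASR1-like amino-acid composition
#'
#' Composition used as the default substrate for descriptor round-trip
#' tests: strongly Glu/Ala/His/Lys/Gly-biased as in small hydrophilic
#' stress proteins, with the charged fractions f+ = 0.136 and f- = 0.201.
#'
#' @return Named fractions summing to 1.
#' @export
asr1_like_composition <- function() {
  comp <- c(E = 0.161, A = 0.150, H = 0.120, K = 0.122, G = 0.094,
            D = 0.040, S = 0.055, V = 0.045, Y = 0.030, Q = 0.030,
            T = 0.030, L = 0.025, R = 0.014, P = 0.020, F = 0.015,
            M = 0.015, I = 0.012, N = 0.012, W = 0.005, C = 0.005)
  comp / sum(comp)
}

#' Generate a synthetic SAXS curve with known ground truth
#'
#' Supported models: a homogeneous sphere of radius \code{R}; a Gaussian
#' (Debye) coil of radius of gyration \code{Rg}; or a two-population
#' mixture of supplied component intensities. Gaussian noise with
#' \eqn{\sigma(q) = I(q)/\mathrm{snr} \cdot (1 + q/q_{max})} is added
#' (infinite snr gives a noiseless curve with nominal uncertainties).
#'
#' @param q Momentum transfer grid, Angstrom^-1.
#' @param model "sphere", "debye_coil" or "two_population".
#' @param pars Model parameters: \code{R} (sphere); \code{Rg} (coil);
#'   \code{I1}, \code{I2}, \code{w} and optionally \code{Rg1}, \code{Rg2}
#'   (mixture; intensities on the same q grid, weight w on component 1).
#' @param snr Signal-to-noise ratio at q = 0.
#' @param seed Integer seed.
#' @return A [scattering_curve()] with attribute \code{truth}.
#' @export
gen_saxs <- function(q, model = c("sphere", "debye_coil", "two_population"),
                     pars = list(), snr = 50, seed = 1L) {
  model <- match.arg(model)
  if (!is.finite(snr) && snr > 0) snr <- Inf
  if (snr <= 0) stop("snr must be positive")
  set.seed(seed)
  truth <- list(model = model)
  I <- switch(model,
    sphere = {
      truth$R <- pars$R; truth$Rg <- pars$R * sqrt(3 / 5)
      truth$Dmax <- 2 * pars$R
      sphere_intensity(q, pars$R)
    },
    debye_coil = {
      truth$Rg <- pars$Rg
      debye_coil_intensity(q, pars$Rg)
    },
    two_population = {
      I1 <- pars$I1 / pars$I1[1]; I2 <- pars$I2 / pars$I2[1]
      w <- pars$w %||% 0.5
      truth$w <- w; truth$Rg1 <- pars$Rg1; truth$Rg2 <- pars$Rg2
      w * I1 + (1 - w) * I2
    })
  if (is.finite(snr)) {
    sigma <- I / snr * (1 + q / max(q))
    sigma <- pmax(sigma, max(I) * 1e-8)
    I <- I + stats::rnorm(length(q), 0, sigma)
  } else {
    sigma <- pmax(I, max(I) * 1e-6) * 1e-4
  }
  out <- scattering_curve(q, I, sigma)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic SEC calibration table
#'
#' Globular standards log-spaced in mass; elution volumes follow an exact
#' log-linear law \code{Ve = a + b log10(Rs)} with optional relative
#' Gaussian noise on Ve.
#'
#' @param n_standards Number of standards (>= 3).
#' @param noise Relative sd of the Ve noise (0 = exact).
#' @param seed Integer seed.
#' @param mm_range Mass range of the standards, Da.
#' @param a,b True calibration coefficients (mL).
#' @return List with \code{standards} (data.frame MM, Ve) and \code{truth}.
#' @export
gen_sec_calibration <- function(n_standards = 6L, noise = 0, seed = 1L,
                                mm_range = c(1e4, 5e5), a = 25, b = -8) {
  if (n_standards < 3L) stop("need at least 3 standards")
  set.seed(seed)
  MM <- 10^seq(log10(mm_range[1]), log10(mm_range[2]),
               length.out = n_standards)
  ve <- a + b * log10(rs_standard(MM))
  if (noise > 0) ve <- ve * (1 + stats::rnorm(n_standards, 0, noise))
  list(standards = data.frame(MM = MM, Ve = ve),
       truth = list(a = a, b = b))
}

#' Generate a synthetic thermal melt curve
#'
#' Boltzmann sigmoid with additive Gaussian noise scaled to the transition
#' amplitude.
#'
#' @param Tm Midpoint, degrees C.
#' @param slope Transition slope s, degrees C.
#' @param A,B Folded and unfolded baselines (signal units).
#' @param temperature Temperature grid, degrees C.
#' @param noise_frac Noise sd as a fraction of |B - A|.
#' @param seed Integer seed.
#' @return data.frame with \code{temperature}, \code{signal}; attribute
#'   \code{truth}.
#' @export
gen_melt <- function(Tm = 51, slope = 5, A = -4000, B = 1000,
                     temperature = seq(20, 80, by = 1), noise_frac = 0.05,
                     seed = 1L) {
  set.seed(seed)
  y <- A + (B - A) / (1 + exp((Tm - temperature) / slope))
  if (noise_frac > 0)
    y <- y + stats::rnorm(length(y), 0, noise_frac * abs(B - A))
  out <- data.frame(temperature = temperature, signal = y)
  attr(out, "truth") <- list(Tm = Tm, slope = slope, A = A, B = B)
  out
}

#' Generate a two-state CD spectral family with a prescribed crossing
#'
#' Builds two basis spectra that cross exactly (and only) at
#' \code{crossing} and returns linear combinations at the requested
#' fractions with optional noise. The family is the canonical positive
#' control for isodichroic-point detection.
#'
#' @param fractions Mixing fractions of the second basis (one spectrum per
#'   value).
#' @param crossing Crossing wavelength, nm.
#' @param wavelength Wavelength grid, nm.
#' @param snr Signal-to-noise ratio (Inf = noiseless).
#' @param seed Integer seed.
#' @return List of \code{cd_spectrum} objects (type mre) with attribute
#'   \code{truth}.
#' @export
gen_cd_family <- function(fractions = seq(0, 1, length.out = 5),
                          crossing = 205,
                          wavelength = seq(190, 260, by = 0.5),
                          snr = Inf, seed = 1L) {
  set.seed(seed)
  coil <- -19000 * exp(-((wavelength - 198) / 9)^2) +
    2000 * exp(-((wavelength - 222) / 12)^2)
  # second basis differs from the first by a smooth signed difference that
  # vanishes only at the requested crossing wavelength, so the family has
  # exactly one common crossing
  d <- 40000 * (wavelength - crossing) / 70 *
    exp(-((wavelength - crossing) / 30)^2)
  other <- coil + d
  rng <- diff(range(c(coil, other)))
  out <- lapply(fractions, function(f) {
    y <- (1 - f) * coil + f * other
    if (is.finite(snr)) y <- y + stats::rnorm(length(y), 0, rng / snr)
    cd_spectrum(wavelength, y, type = "mre")
  })
  attr(out, "truth") <- list(crossing = crossing, fractions = fractions)
  out
}

#' Concatenate conformer pools
#'
#' Merges pools (e.g. a compact and an expanded sub-pool for
#' two-population experiments) preserving the class; the component labels
#' are recorded in attribute \code{component}.
#'
#' @param ... \code{conformer_pool} objects.
#' @return A \code{conformer_pool} with attribute \code{component}.
#' @export
merge_pools <- function(...) {
  pools <- list(...)
  out <- do.call(c, lapply(pools, unclass))
  comp <- rep(seq_along(pools), vapply(pools, length, integer(1)))
  structure(out, class = "conformer_pool",
            N = attr(pools[[1]], "N"), component = comp)
}
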