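# Coarse-grained conformer ensembles: self-avoiding C-alpha chain pools,
# Debye scattering curves, chi-square agreement, and genetic-algorithm
# sub-ensemble selection against a target curve.

#' Generate a pool of random-coil C-alpha conformers
#'
#' Chains are grown bead by bead with fixed virtual bond length (3.8
#' Angstrom between consecutive C-alpha positions), bond angles drawn from a
#' coil-like normal distribution, uniform dihedrals, and hard-sphere
#' excluded volume between beads at least three positions apart. Chains that
#' cannot be grown are regrown from scratch; persistent failure raises an
#' error suggesting a smaller exclusion radius. Deterministic under a fixed
#' seed.
#'
#' The bond-angle distribution is the dial that sets chain dimensions:
#' the default (mean 120 degrees, sd 25) reproduces Flory-like IDP
#' dimensions; stiffer angles give expanded chains, tighter angles compact
#' ones.
#'
#' @param N Residues (beads) per chain, at least 10.
#' @param n_conformers Number of chains.
#' @param seed Integer seed.
#' @param bond Bond length, Angstrom.
#' @param angle_mean,angle_sd Bond-angle distribution, degrees.
#' @param exclusion Hard-sphere excluded-volume radius, Angstrom.
#' @param max_attempts Regrow budget per chain.
#' @return Object of class \code{conformer_pool}: list of conformers, each
#'   with \code{xyz} (N x 3) and \code{Rg}; attributes record the
#'   generation parameters.
#' @export
generate_pool <- function(N, n_conformers, seed = 1L, bond = 3.8,
                          angle_mean = 120, angle_sd = 25,
                          exclusion = 4.0, max_attempts = 1000L) {
  if (!is.finite(N) || N < 10) stop("N must be at least 10")
  set.seed(seed)
  excl2 <- exclusion^2
  grow_chain <- function() {
    xyz <- matrix(0, N, 3)
    xyz[2, ] <- c(bond, 0, 0)
    i <- 3L
    while (i <= N) {
      placed <- FALSE
      for (try in 1:30) {
        theta <- stats::rnorm(1, angle_mean, angle_sd)
        theta <- min(max(theta, 60), 175) * pi / 180
        phi <- stats::runif(1, 0, 2 * pi)
        u <- xyz[i - 1, ] - xyz[i - 2, ]
        u <- u / sqrt(sum(u^2))
        # orthonormal frame around u
        a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        n1 <- a - sum(a * u) * u
        n1 <- n1 / sqrt(sum(n1^2))
        n2 <- c(u[2] * n1[3] - u[3] * n1[2],
                u[3] * n1[1] - u[1] * n1[3],
                u[1] * n1[2] - u[2] * n1[1])
        d <- cos(pi - theta) * u +
          sin(pi - theta) * (cos(phi) * n1 + sin(phi) * n2)
        cand <- xyz[i - 1, ] + bond * d
        if (i > 3L) {
          prev <- xyz[1:(i - 3L), , drop = FALSE]
          dd <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
            (prev[, 3] - cand[3])^2
          if (any(dd < excl2)) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) return(NULL)
      i <- i + 1L
    }
    xyz
  }
  pool <- vector("list", n_conformers)
  for (k in seq_len(n_conformers)) {
    xyz <- NULL
    for (attempt in seq_len(max_attempts)) {
      xyz <- grow_chain()
      if (!is.null(xyz)) break
    }
    if (is.null(xyz))
      stop("chain regrow failed repeatedly; try a smaller exclusion radius")
    pool[[k]] <- list(xyz = xyz, Rg = coords_rg(xyz))
  }
  structure(pool, class = "conformer_pool",
            N = N, bond = bond, angle_mean = angle_mean,
            angle_sd = angle_sd, exclusion = exclusion, seed = seed)
}

coords_rg <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(mean((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
              (xyz[, 3] - ctr[3])^2))
}

#' @export
print.conformer_pool <- function(x, ...) {
  rg <- pool_rg(x)
  cat(sprintf(
    "<conformer_pool> %d chains of %d beads; Rg %.1f +/- %.1f A\n",
    length(x), attr(x, "N"), mean(rg), stats::sd(rg)))
  invisible(x)
}

#' Radii of gyration of a conformer pool
#' @param pool A [generate_pool()] result.
#' @return Numeric vector of Rg, Angstrom.
#' @export
pool_rg <- function(pool) vapply(pool, function(cf) cf$Rg, numeric(1))

#' Debye scattering curve of a conformer
#'
#' Pairwise Debye sum \eqn{I(q) = f(q)^2 \sum_i \sum_j \sin(q r_{ij}) /
#' (q r_{ij})} with a Gaussian dummy-residue form factor
#' \eqn{f(q) = \exp(-q^2 \sigma_f^2 / 2)}; I(0) equals N^2. Distances are
#' binned (default 0.5 Angstrom) so the double sum collapses onto a
#' histogram, which is exact to well below the binning length scale.
#'
#' @param conformer A single conformer (list with \code{xyz}) or an N x 3
#'   coordinate matrix.
#' @param q Momentum transfer grid, Angstrom^-1 (positive).
#' @param sigma_f Form-factor width, Angstrom.
#' @param bin_width Distance-histogram bin width, Angstrom; set to 0 for
#'   the exact double sum.
#' @return Intensity vector over \code{q}.
#' @export
debye_curve <- function(conformer, q, sigma_f = 3.0, bin_width = 0.5) {
  xyz <- if (is.matrix(conformer)) conformer else conformer$xyz
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive")
  n <- nrow(xyz)
  ff <- exp(-q^2 * sigma_f^2 / 2)^2
  if (n == 1L) return(ff * 1)
  d <- as.numeric(stats::dist(xyz))
  sinc <- function(x) ifelse(abs(x) < 1e-9, 1, sin(x) / x)
  if (bin_width > 0) {
    bin <- pmax(1L, ceiling(d / bin_width))
    counts <- tabulate(bin)
    mids <- (seq_along(counts) - 0.5) * bin_width
    keep <- counts > 0
    S <- outer(q, mids[keep], function(qq, dd) sinc(qq * dd)) %*% counts[keep]
  } else {
    S <- outer(q, d, function(qq, dd) sinc(qq * dd)) %*% rep(1, length(d))
  }
  ff * (n + 2 * drop(S))
}

#' Scattering curves for every conformer in a pool
#'
#' @param pool A [generate_pool()] result.
#' @param q Momentum transfer grid.
#' @param ... Passed to [debye_curve()].
#' @return Matrix, \code{length(q)} rows by \code{length(pool)} columns.
#' @export
pool_curves <- function(pool, q, ...) {
  vapply(pool, debye_curve, numeric(length(q)), q = q, ...)
}

#' Reduced chi-square between a computed and a measured curve
#'
#' The computed curve is scaled by the closed-form least-squares factor
#' before comparison: \eqn{\chi^2 = \frac{1}{K-1} \sum_k ((\mu I_{calc} -
#' I_{exp}) / \sigma_k)^2}.
#'
#' @param I_calc Computed intensities on the target's q grid.
#' @param curve Target [scattering_curve()].
#' @return List with \code{chi2} and the scale \code{mu}.
#' @export
chi2_curve <- function(I_calc, curve) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (length(I_calc) != length(curve$q))
    stop("I_calc and target curve are on different q grids")
  if (length(I_calc) < 2L) stop("need at least 2 points for chi-square")
  w <- 1 / curve$sigma^2
  mu <- sum(w * I_calc * curve$I) / sum(w * I_calc^2)
  list(chi2 = sum(w * (mu * I_calc - curve$I)^2) / (length(I_calc) - 1),
       mu = mu)
}

#' Genetic-algorithm sub-ensemble selection against a scattering curve
#'
#' Selects a multiset of conformers (repetition allowed, size
#' \code{max_ensemble}) whose average curve best matches the target,
#' emulating ensemble-optimization selection: tournament selection,
#' single-point crossover, per-gene mutation and elitism over genomes of
#' conformer indices. The initial population is seeded with the best single
#' conformer replicated, so the selected ensemble can never fit worse than
#' the best individual conformer. Deterministic under a fixed seed.
#'
#' @param curves Pool curve matrix from [pool_curves()] (rows = q points,
#'   columns = conformers).
#' @param target Target [scattering_curve()] on the same q grid.
#' @param max_ensemble Sub-ensemble size (genome length).
#' @param generations,population,mutation_rate,tournament,elite,patience GA
#'   hyperparameters; \code{patience} is the number of generations without
#'   improvement tolerated before stopping.
#' @param pool_rg Optional conformer Rg vector, stored for distribution
#'   analysis.
#' @param seed Integer seed.
#' @return Object of class \code{ensemble_fit}: \code{selected} (conformer
#'   indices with multiplicity), \code{chi2}, \code{mu},
#'   \code{chi2_best_single}, \code{pool_rg}, \code{selected_rg},
#'   \code{history}, \code{converged}.
#' @export
ga_select <- function(curves, target, max_ensemble = 50L,
                      generations = 300L, population = 100L,
                      mutation_rate = 0.05, tournament = 3L, elite = 2L,
                      patience = 50L, pool_rg = NULL, seed = 1L) {
  stopifnot(inherits(target, "scattering_curve"))
  npool <- ncol(curves)
  if (npool < max_ensemble)
    stop("pool must contain at least max_ensemble conformers")
  if (nrow(curves) != length(target$q))
    stop("pool curves and target are on different q grids")
  set.seed(seed)
  w <- 1 / target$sigma^2
  Ie <- target$I
  sum_e <- sum(w * Ie^2)
  K <- length(Ie)
  chi2_of <- function(Ic) {
    mu <- sum(w * Ic * Ie) / sum(w * Ic^2)
    sum(w * (mu * Ic - Ie)^2) / (K - 1)
  }
  # best single conformer (vectorized over the pool)
  A <- colSums(curves * (w * Ie))
  B <- colSums(curves^2 * w)
  mu_all <- A / B
  chi2_single <- (sum_e - mu_all * A) / (K - 1)
  best_single <- which.min(chi2_single)

  genome_fit <- function(g) chi2_of(rowMeans(curves[, g, drop = FALSE]))
  pop <- matrix(sample.int(npool, max_ensemble * population, replace = TRUE),
                nrow = max_ensemble)
  pop[, 1] <- best_single
  fitness <- apply(pop, 2, genome_fit)
  best_chi2 <- Inf; best_genome <- pop[, which.min(fitness)]
  history <- numeric(0)
  stall <- 0L; converged <- FALSE
  for (gen in seq_len(generations)) {
    ord <- order(fitness)
    if (fitness[ord[1]] < best_chi2 - 1e-12) {
      best_chi2 <- fitness[ord[1]]
      best_genome <- pop[, ord[1]]
      stall <- 0L
    } else stall <- stall + 1L
    history <- c(history, best_chi2)
    if (best_chi2 < 1e-12 || stall >= patience) { converged <- TRUE; break }
    new_pop <- matrix(0L, max_ensemble, population)
    new_pop[, seq_len(elite)] <- pop[, ord[seq_len(elite)]]
    pick_parent <- function() {
      cand <- sample.int(population, tournament)
      cand[which.min(fitness[cand])]
    }
    for (j in (elite + 1L):population) {
      p1 <- pop[, pick_parent()]; p2 <- pop[, pick_parent()]
      cut <- sample.int(max_ensemble - 1L, 1L)
      child <- c(p1[seq_len(cut)], p2[(cut + 1L):max_ensemble])
      mut <- stats::runif(max_ensemble) < mutation_rate
      if (any(mut)) child[mut] <- sample.int(npool, sum(mut), replace = TRUE)
      new_pop[, j] <- child
    }
    pop <- new_pop
    fitness <- apply(pop, 2, genome_fit)
  }
  if (!converged)
    warning("GA stopped at the generation budget while still improving; ",
            "returning best ensemble so far")
  Ic <- rowMeans(curves[, best_genome, drop = FALSE])
  mu <- sum(w * Ic * Ie) / sum(w * Ic^2)
  structure(
    list(selected = sort(best_genome), chi2 = best_chi2, mu = mu,
         chi2_best_single = chi2_single[best_single],
         best_single = best_single,
         pool_rg = pool_rg,
         selected_rg = if (!is.null(pool_rg)) pool_rg[best_genome],
         I_fit = mu * Ic, history = history, converged = converged,
         max_ensemble = max_ensemble, seed = seed),
    class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf(
    "<ensemble_fit> chi2 = %.4g (best single %.4g), %d/%d distinct conformers%s\n",
    x$chi2, x$chi2_best_single, length(unique(x$selected)),
    x$max_ensemble, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Pool versus selected-ensemble Rg distributions
#'
#' Histograms the conformer-pool and selected sub-ensemble radii of
#' gyration on a common grid and flags bimodality of the selected
#' distribution: two local maxima (each at least \code{min_peak_frac} of
#' the tallest) separated by a valley at least 20% below both peaks.
#'
#' @param fit An [ga_select()] result carrying \code{pool_rg}.
#' @param bin_width Histogram bin width, Angstrom.
#' @param range_rg Histogram range, Angstrom; extended to the data if
#'   needed.
#' @param min_peak_frac Minimum relative height for a countable peak.
#' @return List with \code{breaks}, \code{pool_counts},
#'   \code{selected_counts}, \code{bimodal}, \code{peaks} (Rg at the
#'   selected-distribution peaks).
#' @export
rg_distribution <- function(fit, bin_width = 2.5, range_rg = c(15, 80),
                            min_peak_frac = 0.1) {
  if (is.null(fit$pool_rg))
    stop("fit carries no pool Rg values; pass pool_rg to ga_select()")
  all_rg <- c(fit$pool_rg, fit$selected_rg)
  lo <- min(range_rg[1], floor(min(all_rg)))
  hi <- max(range_rg[2], ceiling(max(all_rg)))
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  pc <- graphics::hist(fit$pool_rg, breaks = breaks, plot = FALSE)$counts
  sc <- graphics::hist(fit$selected_rg, breaks = breaks, plot = FALSE)$counts
  bi <- detect_bimodality(sc, min_peak_frac = min_peak_frac)
  mids <- breaks[-length(breaks)] + bin_width / 2
  list(breaks = breaks, mids = mids, pool_counts = pc, selected_counts = sc,
       bimodal = bi$bimodal, peaks = mids[bi$peaks])
}

# Two-peak detection on histogram counts: local maxima above a relative
# height floor, with a valley at least `valley_drop` below both peaks.
# Counts are lightly smoothed (3-bin running mean) so sampling raggedness
# does not masquerade as extra modes; among qualifying peak pairs the most
# prominent pair (largest smaller-peak height) is reported.
detect_bimodality <- function(counts, min_peak_frac = 0.1,
                              valley_drop = 0.2, smooth = TRUE) {
  n <- length(counts)
  if (n < 3 || max(counts) == 0) return(list(bimodal = FALSE, peaks = integer()))
  cs <- if (smooth && n >= 5) {
    as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  } else counts
  cs[is.na(cs)] <- counts[is.na(cs)]
  peaks <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) cs[i - 1] else -Inf
    right <- if (i < n) cs[i + 1] else -Inf
    cs[i] > left && cs[i] >= right
  }, logical(1)))
  peaks <- peaks[cs[peaks] >= min_peak_frac * max(cs)]
  if (length(peaks) < 2) return(list(bimodal = FALSE, peaks = peaks))
  best <- NULL; best_height <- -Inf
  for (a in seq_len(length(peaks) - 1)) for (b in (a + 1):length(peaks)) {
    i <- peaks[a]; j <- peaks[b]
    valley <- min(cs[i:j])
    low <- min(cs[i], cs[j])
    if (valley <= (1 - valley_drop) * low && low > best_height) {
      best_height <- low; best <- c(i, j)
    }
  }
  if (is.null(best)) list(bimodal = FALSE, peaks = peaks)
  else list(bimodal = TRUE, peaks = best)
}

#' Overlap of two histograms
#'
#' Intersection of the normalized histograms (1 = identical shapes); used
#' to check that independent selections produce similar Rg distributions.
#'
#' @param c1,c2 Count vectors on a common grid.
#' @return Overlap in \[0, 1\].
#' @export
histogram_overlap <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("count vectors differ in length")
  sum(pmin(c1 / sum(c1), c2 / sum(c2)))
}

#' Write a conformer pool as a multi-model C-alpha PDB file
#'
#' @param pool A [generate_pool()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pool_pdb <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(pool)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- pool[[m]]$xyz
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), seq_len(nrow(xyz)),
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model C-alpha PDB file back into a conformer pool
#'
#' @param path PDB file written by [write_pool_pdb()].
#' @return A \code{conformer_pool}.
#' @export
read_pool_pdb <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "MODEL")) cur <- character(0)
    else if (startsWith(ln, "ATOM")) cur <- c(cur, ln)
    else if (startsWith(ln, "ENDMDL")) {
      xyz <- cbind(as.numeric(substr(cur, 31, 38)),
                   as.numeric(substr(cur, 39, 46)),
                   as.numeric(substr(cur, 47, 54)))
      models[[length(models) + 1L]] <- list(xyz = xyz, Rg = coords_rg(xyz))
      cur <- NULL
    }
  }
  structure(models, class = "conformer_pool", N = nrow(models[[1]]$xyz))
}
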