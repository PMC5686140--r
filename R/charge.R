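# Sequence-level disorder descriptors: charged fractions, NCPR/FCR, the
# kappa charge-patterning parameter, diagram-of-states classification,
# charge-hydropathy analysis and compositional bias.

charge_vector <- function(seq, his_charged = FALSE) {
  chars <- seq_chars(seq)
  pos <- c("K", "R", if (his_charged) "H")
  ifelse(chars %in% pos, 1L, ifelse(chars %in% c("D", "E"), -1L, 0L))
}

#' Fractions of positively and negatively charged residues
#'
#' Lys and Arg count as positive, Asp and Glu as negative. Histidine is
#' treated as neutral at pH 7 by default; set \code{his_charged = TRUE} for
#' acidic-pH work.
#'
#' @param seq A [protein_sequence()] (or a plain string).
#' @param his_charged Count His as positively charged?
#' @return Named numeric vector \code{c(f_plus =, f_minus =)}.
#' @examples
#' charged_fractions(protein_sequence("EEEEEKKKKK"))
#' @export
charged_fractions <- function(seq, his_charged = FALSE) {
  seq <- as_protein_sequence(seq)
  ch <- charge_vector(seq, his_charged)
  c(f_plus = sum(ch > 0) / seq$n, f_minus = sum(ch < 0) / seq$n)
}

#' Net charge per residue and fraction of charged residues
#'
#' \code{NCPR = f_plus - f_minus}; \code{FCR = f_plus + f_minus}.
#'
#' @param f_plus,f_minus Fractions in \[0, 1\] with sum at most 1.
#' @return Named numeric vector \code{c(NCPR =, FCR =)}.
#' @export
ncpr_fcr <- function(f_plus, f_minus) {
  if (!is.finite(f_plus) || !is.finite(f_minus) ||
      f_plus < 0 || f_plus > 1 || f_minus < 0 || f_minus > 1 ||
      f_plus + f_minus > 1 + 1e-12)
    stop("f_plus and f_minus must lie in [0,1] with sum <= 1")
  c(NCPR = f_plus - f_minus, FCR = f_plus + f_minus)
}

# Per-blob charge asymmetry sigma = (f+ - f-)^2 / (f+ + f-); 0 for a
# chargeless blob.
charge_asymmetry <- function(f_plus, f_minus) {
  tot <- f_plus + f_minus
  ifelse(tot > 0, (f_plus - f_minus)^2 / tot, 0)
}

# Blob-level patterning statistic delta for one blob size: mean squared
# deviation of window asymmetry from the whole-sequence asymmetry.
# Overlapping full windows only (stride 1, no partial terminal blobs).
delta_g <- function(charges, g) {
  n <- length(charges)
  if (n < g) stop("sequence shorter than blob size ", g)
  pos <- as.numeric(charges > 0)
  neg <- as.numeric(charges < 0)
  cp <- c(0, cumsum(pos))
  cn <- c(0, cumsum(neg))
  idx <- seq_len(n - g + 1L)
  fp <- (cp[idx + g] - cp[idx]) / g
  fm <- (cn[idx + g] - cn[idx]) / g
  sig_seq <- charge_asymmetry(mean(pos), mean(neg))
  mean((charge_asymmetry(fp, fm) - sig_seq)^2)
}

# Maximally segregated permutation of a charge composition: all positives in
# one contiguous block, all negatives in another, neutrals grouped. The
# small set of canonical block orders is evaluated and the most segregated
# (largest delta) is used as the normalizer. Orders omitted here are
# equivalent to one of these under reversal or global charge-sign swap,
# both of which leave delta unchanged.
delta_max_g <- function(charges, g) {
  npos <- sum(charges > 0); nneg <- sum(charges < 0)
  nzero <- length(charges) - npos - nneg
  arrangements <- list(
    c(rep(1L, npos), rep(0L, nzero), rep(-1L, nneg)),  # pos-neu-neg
    c(rep(1L, npos), rep(-1L, nneg), rep(0L, nzero)),  # pos-neg-neu
    c(rep(0L, nzero), rep(1L, npos), rep(-1L, nneg)))  # neu-pos-neg
  max(vapply(arrangements, delta_g, numeric(1), g = g))
}

#' Kappa charge-patterning parameter
#'
#' Quantifies the linear mixing of opposite charges: 0 when positive and
#' negative residues are well mixed along the chain, 1 when they are fully
#' segregated. For each blob size \code{g}, window charge asymmetries are
#' compared with the whole-sequence asymmetry (statistic \eqn{\delta_g}) and
#' normalized by \eqn{\delta_{max,g}} of the maximally segregated permutation
#' of the same composition; the reported kappa is the mean over blob sizes,
#' clipped to \[0, 1\].
#'
#' @param seq A [protein_sequence()] (or string).
#' @param blob_sizes Integer window sizes; the conventional choice is 5 and 6.
#' @param his_charged Count His as positive?
#' @return Kappa value in \[0, 1\].
#' @examples
#' kappa_patterning(protein_sequence(strrep("EK", 25)))  # well mixed, ~0
#' kappa_patterning(protein_sequence(paste0(strrep("E", 25), strrep("K", 25))))
#' @export
kappa_patterning <- function(seq, blob_sizes = c(5L, 6L), his_charged = FALSE) {
  seq <- as_protein_sequence(seq)
  charges <- charge_vector(seq, his_charged)
  if (all(charges == 0L))
    stop("kappa undefined: sequence has no charged residues (FCR = 0)")
  if (seq$n < max(blob_sizes))
    stop("sequence shorter than largest blob size")
  kg <- vapply(blob_sizes, function(g) {
    dmax <- delta_max_g(charges, g)
    if (dmax == 0) return(0)   # e.g. homopolymer of one charge type
    delta_g(charges, g) / dmax
  }, numeric(1))
  min(max(mean(kg), 0), 1)
}

#' Diagram-of-states (phase diagram) region from charged fractions
#'
#' Classifies a sequence into the conformational regions of the
#' charged-fraction diagram of states: region 1 (low FCR; globule/tadpole),
#' region 2 (boundary band, 0.25 <= FCR <= 0.35), region 3 (high-FCR swollen
#' coils), regions 4 and 5 (strong negative resp. positive polyelectrolytes,
#' |NCPR| > 0.35). Band membership (regions 2-5) takes precedence over the
#' region-1 square so that boundary sequences are labelled with the band.
#'
#' @param f_plus,f_minus Charged fractions.
#' @return Integer region label 1-5.
#' @export
phase_diagram_region <- function(f_plus, f_minus) {
  v <- ncpr_fcr(f_plus, f_minus)
  ncpr <- v[["NCPR"]]; fcr <- v[["FCR"]]
  if (fcr >= 0.25 && fcr <= 0.35 && abs(ncpr) <= 0.35) return(2L)
  if (fcr > 0.35 && abs(ncpr) <= 0.35) return(3L)
  if (f_minus > 0.35 && ncpr < -0.35) return(4L)
  if (f_plus > 0.35 && ncpr > 0.35) return(5L)
  if (f_plus < 0.25 && f_minus < 0.25) return(1L)
  # remaining slivers along the |NCPR| = 0.35 diagonal: assign to the
  # nearest polyelectrolyte region
  if (ncpr < 0) 4L else 5L
}

#' Mean hydropathy on the rescaled 0-9 Kyte-Doolittle scale
#'
#' Mean over residues of (KD + 4.5), where KD is the Kyte-Doolittle value;
#' poly-Ile gives 9, poly-Arg gives 0. No windowing.
#'
#' @param seq A [protein_sequence()] (or string).
#' @return Mean hydropathy in \[0, 9\].
#' @export
hydropathy_mean <- function(seq) {
  seq <- as_protein_sequence(seq)
  mean(KD_SCALE[seq_chars(seq)] + 4.5)
}

#' Charge-hydropathy analysis
#'
#' Binary disorder predictor from mean net charge R and normalized mean
#' hydrophobicity H: a protein is predicted disordered when
#' \code{H < (R + 1.151) / 2.785}. H is the mean over 5-residue sliding
#' windows of the Kyte-Doolittle hydropathy rescaled to \[0, 1\]
#' (\code{(KD + 4.5)/9}); R is |NCPR|. The reported distance is the vertical
#' offset from the boundary, \code{H_boundary - H} (positive on the
#' disordered side).
#'
#' @param seq A [protein_sequence()] (or string).
#' @param window Sliding-window width for H (full windows only).
#' @return List with \code{CH_R}, \code{CH_H}, \code{CH_boundary},
#'   \code{CH_distance} and \code{is_disordered}.
#' @export
charge_hydropathy <- function(seq, window = 5L) {
  seq <- as_protein_sequence(seq)
  if (seq$n < window)
    stop("sequence shorter than the hydropathy window (", window, ")")
  kd01 <- (KD_SCALE[seq_chars(seq)] + 4.5) / 9
  cs <- c(0, cumsum(kd01))
  idx <- seq_len(seq$n - window + 1L)
  h <- mean((cs[idx + window] - cs[idx]) / window)
  f <- charged_fractions(seq)
  r <- abs(f[["f_plus"]] - f[["f_minus"]])
  boundary <- (r + 1.151) / 2.785
  list(CH_R = r, CH_H = h, CH_boundary = boundary,
       CH_distance = boundary - h, is_disordered = h < boundary)
}

#' Compositional deviation from a reference proteome
#'
#' For each residue type X, the signed relative deviation
#' \code{(CP_X - CSP_X) / CSP_X} of the sequence composition CP from the
#' reference composition CSP (by default the frozen Swiss-Prot average
#' frequencies shipped with the package). Residues are annotated as
#' disorder-promoting (A,G,R,D,H,Q,K,S,E,P) or order-promoting
#' (W,F,Y,I,M,L,V,C,T).
#'
#' @param seq A [protein_sequence()] (or string).
#' @param reference Named reference fractions for the 20 residues.
#' @return data.frame with columns \code{residue}, \code{cp}, \code{csp},
#'   \code{deviation}, \code{class}.
#' @export
composition_deviation <- function(seq, reference = SWISSPROT_FREQ) {
  seq <- as_protein_sequence(seq)
  counts <- table(factor(seq_chars(seq), levels = AA_STANDARD))
  cp <- as.numeric(counts) / seq$n
  csp <- reference[AA_STANDARD]
  if (any(!is.finite(csp)))
    stop("reference composition must cover all 20 standard residues")
  bad <- csp == 0 & cp > 0
  if (any(bad))
    stop("deviation undefined for residue(s) with zero reference fraction: ",
         paste(AA_STANDARD[bad], collapse = ","))
  data.frame(
    residue = AA_STANDARD,
    cp = cp,
    csp = as.numeric(csp),
    deviation = ifelse(csp > 0, (cp - csp) / csp, NA_real_),
    class = ifelse(AA_STANDARD %in% DISORDER_PROMOTING, "disorder-promoting",
                   ifelse(AA_STANDARD %in% ORDER_PROMOTING,
                          "order-promoting", "neutral")),
    stringsAsFactors = FALSE)
}

#' Isoelectric point (convenience estimate)
#'
#' Bisection on the Henderson-Hasselbalch net-charge sum with an EMBOSS-like
#' pKa set. pI estimates are strongly pKa-set dependent; this is a
#' convenience value, not a validated quantity.
#'
#' @param seq A [protein_sequence()] (or string).
#' @return Estimated pI.
#' @export
isoelectric_point <- function(seq) {
  seq <- as_protein_sequence(seq)
  counts <- table(factor(seq_chars(seq), levels = AA_STANDARD))
  net <- function(ph) {
    pos <- 1 / (1 + 10^(ph - PKA_SET$Nterm)) +
      counts[["K"]] / (1 + 10^(ph - PKA_SET$Kside)) +
      counts[["R"]] / (1 + 10^(ph - PKA_SET$Rside)) +
      counts[["H"]] / (1 + 10^(ph - PKA_SET$Hside))
    neg <- 1 / (1 + 10^(PKA_SET$Cterm - ph)) +
      counts[["D"]] / (1 + 10^(PKA_SET$Dside - ph)) +
      counts[["E"]] / (1 + 10^(PKA_SET$Eside - ph)) +
      counts[["C"]] / (1 + 10^(PKA_SET$Cside - ph)) +
      counts[["Y"]] / (1 + 10^(PKA_SET$Yside - ph))
    pos - neg
  }
  stats::uniroot(net, c(0, 14), tol = 1e-6)$root
}

#' Full sequence-descriptor report
#'
#' One row per sequence with the standard descriptor columns:
#' \code{id, N, f_plus, f_minus, NCPR, FCR, kappa, PDR, hydropathy,
#' CH_R, CH_H, CH_distance}. Kappa is NA for chargeless sequences.
#'
#' @param seqs A [protein_sequence()] or list of them.
#' @param his_charged Count His as positive?
#' @return data.frame, one row per sequence.
#' @export
seq_report <- function(seqs, his_charged = FALSE) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    f <- charged_fractions(s, his_charged)
    v <- ncpr_fcr(f[["f_plus"]], f[["f_minus"]])
    kap <- tryCatch(kappa_patterning(s, his_charged = his_charged),
                    error = function(e) NA_real_)
    ch <- charge_hydropathy(s)
    data.frame(
      id = s$id, N = s$n,
      f_plus = f[["f_plus"]], f_minus = f[["f_minus"]],
      NCPR = v[["NCPR"]], FCR = v[["FCR"]], kappa = kap,
      PDR = phase_diagram_region(f[["f_plus"]], f[["f_minus"]]),
      hydropathy = hydropathy_mean(s),
      CH_R = ch$CH_R, CH_H = ch$CH_H, CH_distance = ch$CH_distance,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
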