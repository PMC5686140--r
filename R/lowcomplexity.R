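# Entropy-based low-complexity segmentation (SEG-style trigger/extension).

#' Shannon complexity of a residue window
#'
#' Entropy of the window's residue composition in bits per position,
#' \eqn{-\sum (n_i/L) \log_2(n_i/L)}. A single-letter window has complexity
#' 0; a window of L distinct residues has complexity log2(L).
#'
#' @param window Character scalar, the residue window.
#' @return Complexity in bits per position.
#' @examples
#' window_complexity("AAAAAAGGGGGG")  # 1 bit
#' @export
window_complexity <- function(window) {
  if (length(window) != 1L || !nzchar(window))
    stop("window must be a non-empty string")
  n <- table(strsplit(toupper(window), "")[[1]])
  p <- as.numeric(n) / sum(n)
  -sum(p * log2(p))
}

# Entropies of all full windows of width w, vectorized over starts.
all_window_entropies <- function(chars, w) {
  n <- length(chars)
  starts <- seq_len(n - w + 1L)
  # per-letter cumulative counts -> window counts
  ent <- numeric(length(starts))
  counts <- matrix(0L, nrow = length(starts), ncol = 0L)
  for (aa in unique(chars)) {
    cs <- c(0L, cumsum(chars == aa))
    counts <- cbind(counts, cs[starts + w] - cs[starts])
  }
  p <- counts / w
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

#' Low-complexity segmentation of a protein sequence
#'
#' SEG-style two-threshold scan: windows of width \code{W} whose composition
#' entropy is at or below the trigger threshold \code{K1} seed segments; each
#' seed is extended to the maximal run of overlapping windows with entropy at
#' or below the extension threshold \code{K2}; overlapping extended runs are
#' merged. The optimal-subsequence refinement of the original algorithm is
#' not applied, so boundaries may differ from canonical SEG by a couple of
#' residues; segment counts are robust to this.
#'
#' @param seq A [protein_sequence()] (or string).
#' @param W Trigger window length (residues).
#' @param K1 Trigger complexity threshold (bits/position).
#' @param K2 Extension complexity threshold (bits/position).
#' @return data.frame with 1-based inclusive \code{start}, \code{end} and
#'   \code{min_complexity} (lowest window entropy inside the segment); zero
#'   rows if none. Sequences shorter than \code{W} give zero rows with a
#'   warning.
#' @export
seg_segments <- function(seq, W = 12L, K1 = 2.2, K2 = 2.5) {
  seq <- as_protein_sequence(seq)
  empty <- data.frame(start = integer(), end = integer(),
                      min_complexity = numeric())
  if (seq$n < W) {
    warning("sequence shorter than trigger window; no segments reported")
    return(empty)
  }
  chars <- seq_chars(seq)
  ent <- all_window_entropies(chars, W)
  trigger <- ent <= K1
  if (!any(trigger)) return(empty)
  extend <- ent <= K2
  # contiguous runs of extension windows
  r <- rle(extend)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  segs <- list()
  for (i in which(r$values)) {
    ws <- run_start[i]; we <- run_end[i]
    if (!any(trigger[ws:we])) next   # run must contain a trigger window
    segs[[length(segs) + 1L]] <-
      c(start = ws, end = we + W - 1L,
        min_complexity = min(ent[ws:we]))
  }
  if (!length(segs)) return(empty)
  out <- as.data.frame(do.call(rbind, segs))
  out <- out[order(out$start), , drop = FALSE]
  # merge residue-overlapping (or touching) segments
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) for (i in 2:nrow(out)) {
    j <- nrow(merged)
    if (out$start[i] <= merged$end[j] + 1L) {
      merged$end[j] <- max(merged$end[j], out$end[i])
      merged$min_complexity[j] <- min(merged$min_complexity[j],
                                      out$min_complexity[i])
    } else merged <- rbind(merged, out[i, ])
  }
  rownames(merged) <- NULL
  merged$start <- as.integer(merged$start)
  merged$end <- as.integer(merged$end)
  merged
}

#' Convert 1-based inclusive segments to BED (0-based half-open)
#'
#' @param segments data.frame from [seg_segments()].
#' @param name Sequence name for the BED chrom column.
#' @return data.frame with \code{chrom}, \code{start} (0-based),
#'   \code{end} (exclusive).
#' @export
segments_to_bed <- function(segments, name = "seq") {
  data.frame(chrom = name,
             start = segments$start - 1L,
             end = segments$end,
             stringsAsFactors = FALSE)
}
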