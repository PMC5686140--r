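# Shared fixtures: realistic synchrotron-like q grids and small sequence
# constructors used across test files.

dense_q <- function(n = 500, qmin = 0.003, qmax = 0.45) {
  seq(qmin, qmax, length.out = n)
}

poly_seq <- function(aa, n) protein_sequence(strrep(aa, n), id = paste0("poly", aa))

# direct (independent) window-entropy segmentation used as the SEG oracle
# on short sequences: plain scan over all windows, no shared code with the
# package implementation
seg_oracle <- function(seq_str, W = 12, K1 = 2.2, K2 = 2.5) {
  chars <- strsplit(seq_str, "")[[1]]
  n <- length(chars)
  if (n < W) return(data.frame(start = integer(), end = integer()))
  ent <- sapply(1:(n - W + 1), function(i) {
    p <- table(chars[i:(i + W - 1)]) / W
    -sum(p * log2(p))
  })
  ext <- ent <= K2
  segs <- list()
  i <- 1
  while (i <= length(ext)) {
    if (!ext[i]) { i <- i + 1; next }
    j <- i
    while (j < length(ext) && ext[j + 1]) j <- j + 1
    if (any(ent[i:j] <= K1))
      segs[[length(segs) + 1]] <- c(i, j + W - 1)
    i <- j + 1
  }
  if (!length(segs)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, segs)
  # merge overlapping/touching residue spans
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (k in 2:nrow(m)) {
    if (m[k, 1] <= out[nrow(out), 2] + 1) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[k, 2])
    } else out <- rbind(out, m[k, ])
  }
  data.frame(start = out[, 1], end = out[, 2])
}

random_protein <- function(n, seed) {
  set.seed(seed)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  protein_sequence(paste(sample(aas, n, replace = TRUE), collapse = ""),
                   id = paste0("rnd", seed))
}
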