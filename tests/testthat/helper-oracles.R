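# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive each quantity by the most direct route
# (explicit loops, exhaustive enumeration, fine grids) and share no code
# with the implementation under test.

KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

FP_ORACLE <- c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
               Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
               L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
               S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)

random_seq <- function(n, alphabet = names(KD_ORACLE)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- physchem oracles -------------------------------------------------

oracle_sliding_mean <- function(sequence, window, scale = KD_ORACLE) {
  r <- strsplit(sequence, "")[[1]]
  out <- numeric(0)
  for (s in 1:(length(r) - window + 1)) {
    acc <- 0
    for (j in 0:(window - 1)) acc <- acc + scale[[r[s + j]]]
    out <- c(out, acc / window)
  }
  out
}

# net charge by direct Henderson-Hasselbalch evaluation; constants copied
# from the published ProtParam/Bjellqvist convention, code path independent
oracle_charge <- function(sequence, ph) {
  r <- strsplit(sequence, "")[[1]]
  nt <- switch(r[1], A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70, 7.50)
  q <- 1 / (1 + 10^(ph - nt)) - 1 / (1 + 10^(3.55 - ph))
  side <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0, K = 10.0,
            R = 12.0)
  for (res in r) {
    if (res %in% c("K", "R", "H"))
      q <- q + 1 / (1 + 10^(ph - side[[res]]))
    if (res %in% c("D", "E", "C", "Y"))
      q <- q - 1 / (1 + 10^(side[[res]] - ph))
  }
  q
}

# fine-grid scan, vectorised over the grid from residue counts (the same
# direct Henderson-Hasselbalch arithmetic as oracle_charge, but tractable
# at step 1e-4)
oracle_pi_grid <- function(sequence, step = 1e-4) {
  r <- strsplit(sequence, "")[[1]]
  grid <- seq(0, 14, by = step)
  nt <- switch(r[1], A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70, 7.50)
  side <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0, K = 10.0,
            R = 12.0)
  qq <- 1 / (1 + 10^(grid - nt)) - 1 / (1 + 10^(3.55 - grid))
  for (res in c("K", "R", "H"))
    qq <- qq + sum(r == res) / (1 + 10^(grid - side[[res]]))
  for (res in c("D", "E", "C", "Y"))
    qq <- qq - sum(r == res) / (1 + 10^(side[[res]] - grid))
  grid[which.min(abs(qq))]
}

# --- helix oracles ----------------------------------------------------

oracle_moment <- function(window, scale = FP_ORACLE, delta = 100) {
  r <- strsplit(window, "")[[1]]
  cx <- 0; sx <- 0
  for (n in seq_along(r)) {
    a <- (n - 1) * delta * pi / 180
    cx <- cx + scale[[r[n]]] * cos(a)
    sx <- sx + scale[[r[n]]] * sin(a)
  }
  sqrt(cx^2 + sx^2) / length(r)
}

oracle_best_window <- function(sequence, width, scale = FP_ORACLE,
                               delta = 100) {
  n <- nchar(sequence)
  best_mu <- -Inf; best_s <- NA
  for (s in 1:(n - width + 1)) {
    mu <- oracle_moment(substr(sequence, s, s + width - 1), scale, delta)
    if (mu > best_mu + 1e-12) { best_mu <- mu; best_s <- s }
  }
  list(start = best_s, mu = best_mu)
}

oracle_tmh <- function(sequence, width, threshold, scale = KD_ORACLE) {
  r <- strsplit(sequence, "")[[1]]
  n <- length(r)
  means <- round(vapply(1:(n - width + 1), function(s)
    mean(vapply(r[s:(s + width - 1)], function(x) scale[[x]], numeric(1))),
    numeric(1)), 9)
  cand <- which(means >= threshold)
  sel <- integer(0)
  for (k in cand[order(-means[cand], cand)])
    if (all(abs(k - sel) >= width)) sel <- c(sel, k)
  sort(sel)
}

# --- motif scan oracle ------------------------------------------------

# exhaustive fixed-width identity scan + greedy left-to-right selection,
# for literal (non-degenerate) consensus patterns
oracle_scan_literal <- function(sequence, consensus, min_identity) {
  r <- strsplit(sequence, "")[[1]]
  p <- strsplit(consensus, "")[[1]]
  w <- length(p)
  if (length(r) < w) return(data.frame(start = integer(), identity = numeric()))
  cands <- data.frame(start = integer(), identity = numeric())
  for (s in 1:(length(r) - w + 1)) {
    id <- sum(r[s:(s + w - 1)] == p) / w
    if (id >= min_identity)
      cands <- rbind(cands, data.frame(start = s, identity = id))
  }
  kept <- data.frame(start = integer(), identity = numeric())
  covered_to <- 0
  for (i in seq_len(nrow(cands))) {
    if (cands$start[i] > covered_to) {
      kept <- rbind(kept, cands[i, ])
      covered_to <- cands$start[i] + w - 1
    }
  }
  kept
}

# --- misc -------------------------------------------------------------

# a proteome_set with given sequence lengths, deterministic content
lengths_proteome <- function(lens) {
  proteome_set(id = sprintf("p%03d", seq_along(lens)),
               sequence = vapply(lens, function(n)
                 paste(rep(c("A", "G", "K", "E", "S"),
                           length.out = n), collapse = ""), ""),
               source = "synthetic")
}
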