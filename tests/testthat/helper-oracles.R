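# Independent pure-R oracles used across the suite.  They share only the
# *specification* (scoring scheme, tie-break order) with the package, never
# its code paths.

# Optimal global alignment score, linear gaps, plain O(nm) matrix DP.
nw_score_oracle <- function(a, b, match, mismatch, gap) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- (0:n) * gap
  H[1, ] <- (0:m) * gap
  for (i in seq_len(n)) {
    s <- ifelse(A[i] == B, match, mismatch)
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(H[i, j] + s[j], H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
    }
  }
  H[n + 1, m + 1]
}

# Optimal global alignment score with affine gaps (gap of length g scores
# open + g * ext); three-state DP written independently of src/align.cpp.
gotoh_score_oracle <- function(a, b, match, mismatch, ext, open) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- open + (1:n) * ext
  if (m > 0) Y[1, 2:(m + 1)] <- open + (1:m) * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, X[i, j + 1] + ext,
                             Y[i, j + 1] + open + ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, X[i + 1, j] + open + ext,
                             Y[i + 1, j] + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Random DNA of given composition (independent of the package generator).
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Mutate a sequence with well-separated random edits; returns the edited
# sequence.  Edit positions are kept >= spacing apart so the optimal edit
# script is unambiguous.
mutate_seq <- function(seq, n_sub = 0, n_del = 0, n_ins = 0,
                       indel_len = 3, spacing = 60) {
  n_edit <- n_sub + n_del + n_ins
  L <- nchar(seq)
  repeat {
    pos <- sort(sample(seq(spacing, L - spacing), n_edit))
    if (n_edit < 2 || min(diff(pos)) >= spacing) break
  }
  kind <- sample(c(rep("S", n_sub), rep("D", n_del), rep("I", n_ins)))
  out <- seq
  for (i in rev(seq_len(n_edit))) {      # right to left keeps coordinates valid
    p <- pos[i]
    if (kind[i] == "S") {
      old <- substr(out, p, p)
      substr(out, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    } else if (kind[i] == "D") {
      out <- paste0(substr(out, 1, p - 1), substr(out, p + indel_len, nchar(out)))
    } else {
      out <- paste0(substr(out, 1, p - 1), rand_seq(indel_len),
                    substr(out, p, nchar(out)))
    }
  }
  out
}

# Brute-force flanking-repeat length: maximal m with
# genome[s+1..s+m] == genome[s+d+1..s+d+m], scanning every m explicitly.
repeat_len_oracle <- function(seq, s, d) {
  best <- 0L
  for (m in seq_len(nchar(seq) - s - d)) {
    if (substr(seq, s + 1, s + m) == substr(seq, s + d + 1, s + d + m))
      best <- m
    else break
  }
  best
}

# Welch test oracle: stats::t.test on raw samples.
welch_oracle <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
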