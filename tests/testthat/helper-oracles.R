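# Independent brute-force oracles.  These deliberately avoid the
# package's vectorized code paths: every window / pair / test statistic
# is computed one element at a time from first principles.

# position-by-position k-mer counter with an environment hash
naive_count_kmers <- function(seqs, k) {
  cnt <- new.env(parent = emptyenv())
  total <- 0L
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      total <- total + 1L
      cnt[[w]] <- (if (is.null(cnt[[w]])) 0L else cnt[[w]]) + 1L
    }
  }
  counts <- unlist(as.list(cnt))
  list(counts = counts[order(names(counts))], total_windows = total)
}

# character-by-character (A/U)AA scanner
naive_scan_cores <- function(seq) {
  n <- nchar(seq)
  starts <- integer(0)
  for (i in seq_len(max(0L, n - 2L))) {
    w <- substr(seq, i, i + 2L)
    if (w %in% c("AAA", "UAA")) starts <- c(starts, i - 1L)
  }
  starts
}

# all-ordered-pairs maximum separation with explicit footprints
naive_max_separation <- function(starts, seq_len_, footprint = 4L) {
  if (length(starts) < 2L) return(NA_integer_)
  best <- -Inf
  for (i in seq_along(starts)) for (j in seq_along(starts)) {
    if (starts[j] > starts[i]) {
      fpe <- min(starts[i] + footprint, seq_len_)
      best <- max(best, starts[j] - fpe)
    }
  }
  as.integer(best)
}

# Pearson chi-squared from expected counts, cell by cell
chi2_oracle <- function(a, ot, c_, bt) {
  obs <- matrix(c(a, ot - a, c_, bt - c_), 2, 2, byrow = TRUE)
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  chi2 <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- rs[i] * cs[j] / n
    chi2 <- chi2 + (obs[i, j] - e)^2 / e
  }
  unname(chi2)
}

# quaternion-based (Horn) optimal-superposition RMSD
horn_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  S <- t(Xc) %*% Yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(Xc^2) + sum(Yc^2) - 2 * lam) / nrow(X))
}

random_rna <- function(n, len, seed,
                       freqs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(names(freqs), len, TRUE, prob = freqs), collapse = ""),
    character(1))
}

# printed oligo sequences used as worked examples throughout
SRE4 <- "UUUGGGGGUUCAAUAAAAAUUUUCACUAUCCUAUUAACAGUUCCGCCGCUCC"
NRXN2 <- "CCCAAUUAACUAACUAACUAACUUUAAAA"
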