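# Independent oracles, deliberately coded as plain scalar loops so they share
# no code path with the vectorized implementations they check.

# Weir & Cockerham (1984) variance components, straight transcription.
# n, nAA, nAa, naa: per-population vectors; populations with n = 0 dropped.
wc_oracle <- function(n, nAA, nAa, naa) {
  keep <- which(n > 0)
  n <- n[keep]; nAA <- nAA[keep]; nAa <- nAa[keep]; naa <- naa[keep]
  r <- length(n)
  p <- numeric(r); h <- numeric(r)
  for (i in 1:r) {
    p[i] <- (2 * nAA[i] + nAa[i]) / (2 * n[i])
    h[i] <- nAa[i] / n[i]
  }
  nbar <- 0; for (i in 1:r) nbar <- nbar + n[i] / r
  sum_n2 <- 0; for (i in 1:r) sum_n2 <- sum_n2 + n[i]^2
  nc <- (r * nbar - sum_n2 / (r * nbar)) / (r - 1)
  pbar <- 0; for (i in 1:r) pbar <- pbar + n[i] * p[i] / (r * nbar)
  s2 <- 0; for (i in 1:r) s2 <- s2 + n[i] * (p[i] - pbar)^2 / ((r - 1) * nbar)
  hbar <- 0; for (i in 1:r) hbar <- hbar + n[i] * h[i] / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  theta <- if (a + b + cc == 0) NA_real_ else a / (a + b + cc)
  list(a = a, b = b, c = cc, theta = theta)
}

# Mann-Whitney U by pairwise double loop, one-tailed (candidates greater)
# exact p by full enumeration of group labelings.
mw_u_brute <- function(cand, bg) {
  U <- 0
  for (x in cand) for (y in bg) {
    if (x > y) U <- U + 1 else if (x == y) U <- U + 0.5
  }
  U
}

mw_exact_brute <- function(cand, bg) {
  U_obs <- mw_u_brute(cand, bg)
  all_v <- c(cand, bg)
  m <- length(cand)
  idx <- utils::combn(length(all_v), m)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    u <- mw_u_brute(all_v[idx[, j]], all_v[-idx[, j]])
    if (u >= U_obs - 1e-9) hits <- hits + 1
  }
  list(U = U_obs, p = hits / ncol(idx))
}

# random genotype-count configuration for estimator fuzzing
random_snp_counts <- function(r = sample(2:5, 1), n_max = 60) {
  n <- sample(2:n_max, r, replace = TRUE)
  nAA <- integer(r); nAa <- integer(r)
  for (i in 1:r) {
    g <- stats::rmultinom(1, n[i], prob = stats::runif(3))
    nAA[i] <- g[1]; nAa[i] <- g[2]
  }
  list(n = n, nAA = nAA, nAa = nAa, naa = n - nAA - nAa)
}

# small helper to build a panel data frame from per-population count vectors
make_panel <- function(ids, pops, nAA, nAa, naa) {
  # nAA etc: matrices SNP x population
  rows <- list()
  for (j in seq_along(pops)) {
    rows[[j]] <- data.frame(snp_id = ids, population = pops[j],
                            n_AA = nAA[, j], n_Aa = nAa[, j], n_aa = naa[, j],
                            stringsAsFactors = FALSE)
  }
  snp_panel(do.call(rbind, rows))
}
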