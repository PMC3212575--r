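#' Weir-Cockerham F_ST estimation
#'
#' Per-SNP estimation of Wright's fixation index F_ST with the unbiased
#' ANOVA estimator of Weir & Cockerham (1984) for a biallelic locus observed
#' in r population samples. The estimator partitions allele-frequency
#' variance into three components: `a` among populations, `b` among
#' individuals within populations, and `c` within individuals; theta =
#' a / (a + b + c) estimates F_ST.
#'
#' With per-sample size n_i, reference-allele frequency p_i and observed
#' heterozygote proportion h_i, and writing nbar, n_c, pbar, s2 and hbar for
#' the weighted means defined by Weir & Cockerham:
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'   \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right]}
#' \deqn{c = \bar h / 2}
#'
#' theta is undefined (NA, flagged) when a + b + c = 0, i.e. the SNP is
#' monomorphic for the same allele in every sample with no heterozygotes.
#' Negative theta estimates are retained, never clipped to zero: the lower
#' tail of the background distribution is used downstream for trimming.
#'
#' @name weir_cockerham
NULL

# Vectorized W&C core over aligned S x r matrices n (sample sizes, diploid
# individuals), p (reference allele frequency), h (observed het proportion).
# Populations with n = 0 are dropped per SNP (p and h must already be 0
# there). Returns per-SNP components and diagnostic flags.
wc_core <- function(n, p, h) {
  has <- n > 0
  r <- rowSums(has)
  n_tot <- rowSums(n)
  nbar <- n_tot / r
  # guard rows that will be flagged anyway
  safe <- r >= 2 & nbar > 1
  r_s <- ifelse(safe, r, 2)
  nbar_s <- ifelse(safe, nbar, 2)
  nc <- (r_s * nbar_s - rowSums(n^2) / (r_s * nbar_s)) / (r_s - 1)
  pbar <- rowSums(n * p) / (r_s * nbar_s)
  s2 <- rowSums(n * (p - pbar)^2) / ((r_s - 1) * nbar_s)
  hbar <- rowSums(n * h) / (r_s * nbar_s)
  inner <- pbar * (1 - pbar) - ((r_s - 1) / r_s) * s2
  a <- (nbar_s / nc) * (s2 - (inner - hbar / 4) / (nbar_s - 1))
  b <- (nbar_s / (nbar_s - 1)) * (inner - ((2 * nbar_s - 1) / (4 * nbar_s)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom != 0, a / denom, NA_real_)
  defined <- safe & denom != 0
  reason <- rep(NA_character_, length(r))
  reason[!safe & r < 2] <- "insufficient samples"
  reason[!safe & r >= 2] <- "degenerate sample size"
  reason[safe & denom == 0] <- "monomorphic everywhere"
  a[!safe] <- b[!safe] <- cc[!safe] <- theta[!safe] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta,
       defined = defined, reason = reason,
       nbar = nbar, nc = ifelse(safe, nc, NA_real_), pbar = pbar,
       s2 = s2, hbar = hbar, r = r)
}

#' Weir-Cockerham variance components for one SNP
#'
#' @param n numeric vector of diploid sample sizes per population (length r).
#' @param n_AA,n_Aa,n_aa genotype counts per population for a fixed
#'   reference allele A; each must satisfy `n_AA + n_Aa + n_aa == n`. Counts
#'   may be non-integer but must be non-negative.
#' @param hwe if `TRUE`, ignore the observed heterozygote counts and impute
#'   h_i = 2 p_i (1 - p_i) under Hardy-Weinberg equilibrium (use when only
#'   allele frequencies are available).
#' @return a list of class `wc_components` with elements `a`, `b`, `c`,
#'   `theta`, `defined` (logical), `reason` (why undefined, or NA), and the
#'   auxiliaries `nbar`, `nc`, `pbar`, `s2`, `hbar`, `r`.
#'   Populations with n_i = 0 are dropped; fewer than 2 remaining is an
#'   error, as is a mean sample size of at most one individual.
#' @examples
#' # two samples fixed for alternative alleles: theta = 1
#' wc_components(n = c(50, 50), n_AA = c(50, 0), n_Aa = c(0, 0), n_aa = c(0, 50))
#' @export
wc_components <- function(n, n_AA, n_Aa, n_aa, hwe = FALSE) {
  stopifnot(length(n) == length(n_AA), length(n) == length(n_Aa),
            length(n) == length(n_aa))
  if (any(n < 0) || any(n_AA < 0) || any(n_Aa < 0) || any(n_aa < 0)) {
    stop("genotype counts must be non-negative")
  }
  if (any(abs(n_AA + n_Aa + n_aa - n) > 1e-8)) {
    stop("genotype counts do not sum to n")
  }
  keep <- n > 0
  if (sum(keep) < 2L) stop("insufficient samples: fewer than 2 populations with data")
  n <- n[keep]; n_AA <- n_AA[keep]; n_Aa <- n_Aa[keep]; n_aa <- n_aa[keep]
  if (mean(n) <= 1) stop("degenerate sample size: mean sample size <= 1")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  h <- if (hwe) 2 * p * (1 - p) else n_Aa / n
  res <- wc_core(matrix(n, 1L), matrix(p, 1L), matrix(h, 1L))
  out <- lapply(res, function(v) v[[1L]])
  out$mode <- if (hwe) "hwe" else "genotype"
  class(out) <- "wc_components"
  out
}

#' @export
print.wc_components <- function(x, ...) {
  cat("Weir-Cockerham components (", x$r, " samples, mode=", x$mode, ")\n",
      sep = "")
  cat(sprintf("  a=%.6g  b=%.6g  c=%.6g  theta=%s\n", x$a, x$b, x$c,
              if (x$defined) sprintf("%.6g", x$theta) else paste0("undefined (", x$reason, ")")))
  invisible(x)
}

#' Per-SNP F_ST sweep over a panel
#'
#' Computes Weir-Cockerham components and theta for every SNP in a panel.
#'
#' @param panel a [snp_panel()].
#' @param hwe impute heterozygosity under HWE instead of using observed
#'   heterozygote counts (see [wc_components()]).
#' @return data frame with one row per SNP: `snp_id`, `a`, `b`, `c`,
#'   `theta`, `defined`, `reason`, `mode`. SNPs whose theta is undefined
#'   (monomorphic everywhere, or fewer than two samples with data) are
#'   flagged `defined = FALSE` and should be excluded from distributional
#'   analyses.
#' @export
panel_fst <- function(panel, hwe = FALSE) {
  if (nrow(panel) == 0L) {
    return(data.frame(snp_id = character(), a = numeric(), b = numeric(),
                      c = numeric(), theta = numeric(), defined = logical(),
                      reason = character(), mode = character(),
                      stringsAsFactors = FALSE))
  }
  m <- panel_matrices(panel)
  if (hwe) m$h <- 2 * m$p * (1 - m$p) * (m$n > 0)
  res <- wc_core(m$n, m$p, m$h)
  data.frame(snp_id = m$snp_id, a = res$a, b = res$b, c = res$c,
             theta = res$theta, defined = res$defined, reason = res$reason,
             mode = if (hwe) "hwe" else "genotype",
             stringsAsFactors = FALSE)
}

#' Multilocus ratio-of-averages F_ST
#'
#' The standard multilocus combination sum(a) / sum(a + b + c) over the
#' SNPs of a panel (defined components only). A utility for estimator
#' validation; the pipeline statistic is the per-SNP theta distribution.
#'
#' @inheritParams panel_fst
#' @return a single numeric estimate.
#' @export
fst_ratio_of_averages <- function(panel, hwe = FALSE) {
  tab <- panel_fst(panel, hwe = hwe)
  ok <- !is.na(tab$a)
  sum(tab$a[ok]) / sum(tab$a[ok] + tab$b[ok] + tab$c[ok])
}
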