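#' Specification of a synthetic HapMap-like panel
#'
#' Parameters of the Balding-Nichols generator used to emulate a
#' multi-population SNP genotype-count panel with known differentiation.
#' Background and candidate SNPs share the ancestral-frequency law but may
#' differ in their F parameter, which is the F_ST the estimator should
#' recover.
#'
#' @param n_background_snps number of background SNPs.
#' @param n_candidate_snps number of candidate SNPs.
#' @param n_populations number of population samples (default 3).
#' @param n_per_pop diploid individuals genotyped per population; a scalar
#'   or one value per population (default 90, HapMap-era panel size).
#' @param F_background Balding-Nichols differentiation parameter of
#'   background SNPs, in `[0, 1)`.
#' @param F_candidate differentiation parameter of candidate SNPs.
#' @param ancestral_maf_range interval in (0, 1) from which ancestral
#'   frequencies are drawn uniformly (default `c(0.05, 0.95)`).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_background_snps = 5000, n_candidate_snps = 150,
                       n_populations = 3, n_per_pop = 90,
                       F_background = 0.1, F_candidate = 0.1,
                       ancestral_maf_range = c(0.05, 0.95)) {
  stopifnot(n_background_snps >= 0, n_candidate_snps >= 0,
            n_background_snps + n_candidate_snps >= 1,
            n_populations >= 2,
            all(n_per_pop >= 1),
            length(n_per_pop) %in% c(1L, n_populations),
            F_background >= 0, F_background < 1,
            F_candidate >= 0, F_candidate < 1,
            length(ancestral_maf_range) == 2L,
            ancestral_maf_range[1L] > 0, ancestral_maf_range[2L] < 1,
            ancestral_maf_range[1L] <= ancestral_maf_range[2L])
  s <- list(n_background_snps = as.integer(n_background_snps),
            n_candidate_snps = as.integer(n_candidate_snps),
            n_populations = as.integer(n_populations),
            n_per_pop = rep_len(as.integer(n_per_pop), n_populations),
            F_background = F_background, F_candidate = F_candidate,
            ancestral_maf_range = ancestral_maf_range)
  class(s) <- "synth_spec"
  s
}

# Balding-Nichols population frequencies: p_i ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
# around ancestral p; point mass at p when F = 0. Vectorized over SNPs.
bn_pop_freq <- function(p_anc, F) {
  if (F == 0) return(p_anc)
  shape <- (1 - F) / F
  stats::rbeta(length(p_anc), p_anc * shape, (1 - p_anc) * shape)
}

# Exact trinomial genotype draw under HWE at frequency p for n diploids,
# via two conditional binomials; vectorized over SNPs.
hwe_genotype_counts <- function(n, p) {
  pAA <- p^2
  pAa <- 2 * p * (1 - p)
  n_AA <- stats::rbinom(length(p), n, pAA)
  rest <- n - n_AA
  cond <- ifelse(pAA < 1, pAa / (1 - pAA), 0)
  n_Aa <- stats::rbinom(length(p), rest, cond)
  data.frame(n_AA = n_AA, n_Aa = n_Aa, n_aa = rest - n_Aa)
}

#' Generate a Balding-Nichols genotype-count panel
#'
#' Per SNP, an ancestral frequency is drawn uniformly from
#' `ancestral_maf_range`; per population, an allele frequency is drawn from
#' the Balding-Nichols Beta distribution at the SNP class's F; genotype
#' counts are then trinomial under Hardy-Weinberg equilibrium. Candidate
#' SNPs are generated identically with `F_candidate`.
#'
#' @param spec a [synth_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return list: `panel` (a [snp_panel()]; background ids `bg_...`,
#'   candidate ids `cand_...`), `candidate_ids`, `spec`.
#' @export
balding_nichols_panel <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- c(sprintf("bg_%06d", seq_len(spec$n_background_snps)),
           sprintf("cand_%06d", seq_len(spec$n_candidate_snps)))
  Fs <- rep(c(spec$F_background, spec$F_candidate),
            c(spec$n_background_snps, spec$n_candidate_snps))
  p_anc <- stats::runif(length(ids), spec$ancestral_maf_range[1L],
                        spec$ancestral_maf_range[2L])
  rows <- vector("list", spec$n_populations)
  for (k in seq_len(spec$n_populations)) {
    p_k <- p_anc
    bg_idx <- Fs == spec$F_background
    # draw background and candidate blocks with their own F
    p_k[bg_idx] <- bn_pop_freq(p_anc[bg_idx], spec$F_background)
    p_k[!bg_idx] <- bn_pop_freq(p_anc[!bg_idx], spec$F_candidate)
    g <- hwe_genotype_counts(spec$n_per_pop[k], p_k)
    rows[[k]] <- data.frame(snp_id = ids, population = sprintf("pop%d", k),
                            g, stringsAsFactors = FALSE)
  }
  panel <- snp_panel(do.call(rbind, rows))
  list(panel = panel, candidate_ids = ids[startsWith(ids, "cand_")],
       spec = spec)
}

# fixed fixture vocabulary of non-height traits for synthetic LD tables
.ld_trait_vocab <- c("type 2 diabetes", "Crohn's disease", "LDL cholesterol",
                     "rheumatoid arthritis", "body mass index",
                     "blood pressure", "bone mineral density")

#' Generate a synthetic LD-confound table
#'
#' Assigns a random subset of candidates one LD row each linking them to a
#' variant for another trait, with r-squared drawn uniformly from
#' `r2_bounds`. With bounds above 0.8 and `fraction_confounded = 1` the LD
#' filter removes every candidate; with bounds at or below 0.8, none.
#'
#' @param candidate_ids character vector of candidate SNP ids.
#' @param fraction_confounded fraction of candidates given an LD row, in
#'   `[0, 1]`.
#' @param r2_bounds length-2 interval in `[0, 1]` for the r-squared draws.
#' @param populations population labels to sample from (default
#'   `c("pop1", "pop2", "pop3")`).
#' @param seed optional integer seed.
#' @return data frame with columns `candidate_snp`, `other_snp`,
#'   `population`, `r2`, `trait` (possibly empty).
#' @export
synth_ld_table <- function(candidate_ids, fraction_confounded, r2_bounds,
                           populations = c("pop1", "pop2", "pop3"),
                           seed = NULL) {
  stopifnot(fraction_confounded >= 0, fraction_confounded <= 1,
            length(r2_bounds) == 2L, r2_bounds[1L] >= 0, r2_bounds[2L] <= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- round(fraction_confounded * length(candidate_ids))
  if (k == 0L) {
    return(data.frame(candidate_snp = character(), other_snp = character(),
                      population = character(), r2 = numeric(),
                      trait = character(), stringsAsFactors = FALSE))
  }
  chosen <- sample(candidate_ids, k)
  data.frame(candidate_snp = chosen,
             other_snp = sprintf("gwas_%05d", seq_len(k)),
             population = sample(populations, k, replace = TRUE),
             r2 = stats::runif(k, r2_bounds[1L], r2_bounds[2L]),
             trait = sample(.ld_trait_vocab, k, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate synthetic per-population selection scores
#'
#' Background scores are i.i.d. standard normal per population. Candidate
#' scores are drawn so that the expected fraction landing above the
#' population's `1 - tail_fraction` normal quantile equals
#' `min(1, enrichment_factor * tail_fraction)`: with probability equal to
#' that target a candidate's score is drawn from the upper normal tail,
#' otherwise from the body.
#'
#' @param snp_ids all SNP ids to score (background scores; include the
#'   candidates).
#' @param candidate_ids character vector of candidate ids.
#' @param enrichment_factor multiplier on the null tail probability
#'   (1 = null; 0 = never in tail).
#' @param tail_fraction the tail used downstream (default 0.05).
#' @param populations population labels (default `c("pop1","pop2","pop3")`).
#' @param seed optional integer seed.
#' @return data frame with columns `snp_id`, `population`, `score`.
#' @export
synth_scores <- function(snp_ids, candidate_ids, enrichment_factor = 1,
                         tail_fraction = 0.05,
                         populations = c("pop1", "pop2", "pop3"),
                         seed = NULL) {
  stopifnot(enrichment_factor >= 0, tail_fraction > 0, tail_fraction < 0.5)
  if (!is.null(seed)) set.seed(seed)
  target <- min(1, enrichment_factor * tail_fraction)
  z_cut <- 1 - tail_fraction                 # CDF position of the tail edge
  is_cand <- snp_ids %in% candidate_ids
  rows <- lapply(populations, function(pp) {
    u <- stats::runif(length(snp_ids))
    # candidates: place in the upper tail with probability `target`
    in_tail <- stats::runif(length(snp_ids)) < target
    u[is_cand] <- ifelse(in_tail[is_cand],
                         stats::runif(sum(is_cand), z_cut, 1),
                         stats::runif(sum(is_cand), 0, z_cut))
    data.frame(snp_id = snp_ids, population = pp,
               score = stats::qnorm(u), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
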