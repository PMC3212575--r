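#' Pipeline configuration
#'
#' Thresholds of the candidate-vs-background comparison battery.
#'
#' @param maf_min minor-allele-frequency exclusion threshold (default 0.05):
#'   a SNP is dropped when its MAF is below this in every sample (see
#'   `maf_rule`).
#' @param tail_fraction tail used both for outlier trimming of the
#'   candidate set against the background F_ST distribution and for the
#'   selection-score enrichment check (default 0.05).
#' @param r2_threshold LD cutoff: a candidate linked to a variant for
#'   another trait with r-squared strictly above this in at least one
#'   population is treated as confounded (default 0.8).
#' @param alpha significance threshold for the one-tailed tests
#'   (default 0.05).
#' @param maf_rule `"all"` (default): exclude only when MAF < `maf_min` in
#'   every sample; `"any"`: exclude when below threshold in any sample.
#' @param score_transform `"signed"` (default) applies the top-tail rule to
#'   scores as given; `"abs"` to their absolute value.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_min = 0.05, tail_fraction = 0.05,
                            r2_threshold = 0.8, alpha = 0.05,
                            maf_rule = c("all", "any"),
                            score_transform = c("signed", "abs")) {
  stopifnot(tail_fraction > 0, tail_fraction < 0.5,
            maf_min >= 0, maf_min < 0.5,
            r2_threshold > 0, r2_threshold <= 1,
            alpha > 0, alpha < 1)
  cfg <- list(maf_min = maf_min, tail_fraction = tail_fraction,
              r2_threshold = r2_threshold, alpha = alpha,
              maf_rule = match.arg(maf_rule),
              score_transform = match.arg(score_transform))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Filter a panel the way the background was assembled
#'
#' Removes SNPs that are (in this order of reporting) unsampled in every
#' population, monomorphic in every population, or below the MAF threshold
#' in every population (a population without data cannot rescue a SNP).
#'
#' @param panel a [snp_panel()].
#' @param cfg a [pipeline_config()].
#' @return list: `panel` (the retained SNPs) and `log` (data frame
#'   `snp_id`, `rule` in `unsampled`/`monomorphic`/`maf` for the removed).
#' @export
filter_panel <- function(panel, cfg = pipeline_config()) {
  m <- panel_matrices(panel)
  has <- m$n > 0
  maf <- pmin(m$p, 1 - m$p)
  unsampled <- rowSums(has) == 0L
  poly <- has & maf > 0                     # sample is polymorphic
  mono_everywhere <- !unsampled & rowSums(poly) == 0L
  maf_ok <- has & maf >= cfg$maf_min
  if (cfg$maf_rule == "all") {
    maf_fail <- rowSums(maf_ok) == 0L       # below threshold in every sample
  } else {
    maf_fail <- rowSums(has & maf < cfg$maf_min) > 0L
  }
  rule <- rep(NA_character_, length(m$snp_id))
  rule[maf_fail] <- "maf"
  rule[mono_everywhere] <- "monomorphic"
  rule[unsampled] <- "unsampled"
  drop <- !is.na(rule)
  log <- data.frame(snp_id = m$snp_id[drop], rule = rule[drop],
                    stringsAsFactors = FALSE)
  kept <- panel[panel$snp_id %in% m$snp_id[!drop], , drop = FALSE]
  class(kept) <- c("snp_panel", "data.frame")
  list(panel = kept, log = log)
}

#' One-tailed Mann-Whitney test (candidates greater)
#'
#' U is the number of (candidate, background) pairs with the candidate
#' value larger, counting ties half. The one-tailed p-value (alternative:
#' candidates stochastically greater) is computed by exact enumeration of
#' all group labelings when `choose(m + n, m)` is at most `exact_limit`,
#' and otherwise by the normal approximation with tie correction and a
#' continuity correction of 1/2.
#'
#' @param candidate_values,background_values non-empty numeric vectors.
#' @param exact_limit enumeration cutoff on `choose(m + n, m)`
#'   (default 20000, covering e.g. both groups of size 8).
#' @return list: `U`, `p`, `method` ("exact" or "normal"), `n_candidate`,
#'   `n_background`.
#' @export
mann_whitney_one_tailed <- function(candidate_values, background_values,
                                    exact_limit = 20000) {
  m <- length(candidate_values)
  n <- length(background_values)
  if (m == 0L || n == 0L) stop("both value lists must be non-empty")
  if (anyNA(candidate_values) || anyNA(background_values)) {
    stop("NA values are not allowed")
  }
  all_v <- c(candidate_values, background_values)
  rk <- rank(all_v)
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  if (choose(m + n, m) <= exact_limit) {
    idx <- utils::combn(m + n, m)
    U_all <- colSums(matrix(rk[idx], nrow = m)) - m * (m + 1) / 2
    p <- mean(U_all >= U - 1e-9)
    method <- "exact"
  } else {
    N <- m + n
    ties <- table(all_v)
    mu <- m * n / 2
    sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {                      # all values tied
      p <- 1
    } else {
      z <- (U - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method, n_candidate = m, n_background = n)
}

#' Trim candidate outliers by background quantiles
#'
#' Removes candidates whose theta falls below the `tail_fraction` quantile
#' or above the `1 - tail_fraction` quantile of the background F_ST
#' distribution, leaving the "core set". Quantiles use the usual linear
#' interpolation between order statistics (`type = 7`).
#'
#' @param candidate_records data frame with columns `snp_id` and `theta`
#'   (e.g. a subset of [panel_fst()] output).
#' @param background_values numeric vector of background theta values
#'   (at least 20).
#' @param cfg a [pipeline_config()].
#' @return list: `core_set` (character snp_ids kept), `n_removed_top`,
#'   `n_removed_bottom`, `q_low`, `q_high`.
#' @export
trim_outliers <- function(candidate_records, background_values,
                          cfg = pipeline_config()) {
  if (length(background_values) < 20L) {
    stop("background too small for tail quantiles (need >= 20 values)")
  }
  q <- stats::quantile(background_values,
                       c(cfg$tail_fraction, 1 - cfg$tail_fraction),
                       names = FALSE, type = 7)
  lo <- candidate_records$theta < q[1L]
  hi <- candidate_records$theta > q[2L]
  list(core_set = candidate_records$snp_id[!lo & !hi],
       n_removed_top = sum(hi), n_removed_bottom = sum(lo),
       q_low = q[1L], q_high = q[2L])
}

#' Remove candidates confounded by LD with other-trait variants
#'
#' A candidate is removed when some LD-table row links it to a variant
#' associated with another trait at r-squared strictly greater than
#' `cfg$r2_threshold` in at least one population.
#'
#' @param candidate_ids character vector of candidate SNP ids.
#' @param ld_table data frame with columns `candidate_snp`, `other_snp`,
#'   `population`, `r2`, `trait`; may be empty or `NULL`.
#' @param cfg a [pipeline_config()].
#' @return list: `kept_ids`, `removed_ids`.
#' @export
ld_confound_filter <- function(candidate_ids, ld_table,
                               cfg = pipeline_config()) {
  if (is.null(ld_table) || nrow(ld_table) == 0L) {
    return(list(kept_ids = candidate_ids, removed_ids = character()))
  }
  if (any(ld_table$r2 < 0 | ld_table$r2 > 1 | !is.finite(ld_table$r2))) {
    stop("malformed r2 values outside [0, 1] in LD table")
  }
  confounded <- unique(ld_table$candidate_snp[ld_table$r2 > cfg$r2_threshold])
  removed <- intersect(candidate_ids, confounded)
  list(kept_ids = setdiff(candidate_ids, removed), removed_ids = removed)
}

#' Selection-score top-tail enrichment
#'
#' Per population, the threshold is the `1 - tail_fraction` quantile of
#' that population's background score distribution; candidates strictly
#' above it are counted and the observed proportion is compared with
#' `tail_fraction` by a two-sided exact binomial test. Candidates without a
#' score in a population are dropped there (and counted).
#'
#' @param scores data frame with columns `snp_id`, `population`, `score`
#'   (background = all rows; candidate rows identified by `candidate_ids`).
#' @param candidate_ids character vector of candidate SNP ids.
#' @param cfg a [pipeline_config()].
#' @return data frame, one row per population: `population`,
#'   `n_candidates_scored`, `n_in_tail`, `proportion`, `p_binomial`,
#'   `threshold`.
#' @export
tail_enrichment <- function(scores, candidate_ids, cfg = pipeline_config()) {
  if (cfg$score_transform == "abs") scores$score <- abs(scores$score)
  pops <- sort(unique(scores$population))
  rows <- lapply(pops, function(pp) {
    s <- scores[scores$population == pp, , drop = FALSE]
    thr <- stats::quantile(s$score, 1 - cfg$tail_fraction,
                           names = FALSE, type = 7)
    cand <- s$score[s$snp_id %in% candidate_ids]
    k <- length(cand)
    if (k == 0L) {
      return(data.frame(population = pp, n_candidates_scored = 0L,
                        n_in_tail = NA_integer_, proportion = NA_real_,
                        p_binomial = NA_real_, threshold = thr,
                        stringsAsFactors = FALSE))
    }
    x <- sum(cand > thr)
    bt <- stats::binom.test(x, k, p = cfg$tail_fraction,
                            alternative = "two.sided")
    data.frame(population = pp, n_candidates_scored = k, n_in_tail = x,
               proportion = x / k, p_binomial = bt$p.value, threshold = thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full candidate-vs-background comparison
#'
#' Orchestrates the pipeline: panel filtering, per-SNP Weir-Cockerham
#' F_ST, the one-tailed Mann-Whitney comparison of the full candidate set
#' against the genomic background, outlier trimming to the core set and
#' re-test, LD-confound removal and re-test, and per-population top-tail
#' enrichment of selection scores.
#'
#' @param panel a [snp_panel()] (populations already pooled as desired).
#' @param candidate_ids character vector of candidate SNP ids; candidates
#'   absent from the filtered panel are logged and skipped.
#' @param ld_table optional LD table for [ld_confound_filter()]; `NULL`
#'   for none.
#' @param scores optional score table for [tail_enrichment()]; `NULL`
#'   skips the enrichment stage.
#' @param cfg a [pipeline_config()].
#' @param hwe passed to [panel_fst()].
#' @return object of class `comparison_report`; see the elements in the
#'   print method and the field documentation of each stage.
#' @export
run_comparison <- function(panel, candidate_ids, ld_table = NULL,
                           scores = NULL, cfg = pipeline_config(),
                           hwe = FALSE) {
  flt <- filter_panel(panel, cfg)
  fst <- panel_fst(flt$panel, hwe = hwe)
  fst <- fst[fst$defined, , drop = FALSE]
  is_cand <- fst$snp_id %in% candidate_ids
  cand <- fst[is_cand, , drop = FALSE]
  bg <- fst$theta[!is_cand]
  missing_cand <- setdiff(candidate_ids, cand$snp_id)
  if (nrow(cand) == 0L) {
    stop("no candidate SNP survives filtering; ",
         length(missing_cand), " candidates were absent or removed")
  }
  test_full <- mann_whitney_one_tailed(cand$theta, bg)
  trim <- trim_outliers(cand, bg, cfg)
  core <- cand[cand$snp_id %in% trim$core_set, , drop = FALSE]
  test_core <- mann_whitney_one_tailed(core$theta, bg)
  ld <- ld_confound_filter(trim$core_set, ld_table, cfg)
  post_ld <- core[core$snp_id %in% ld$kept_ids, , drop = FALSE]
  test_post_ld <- if (nrow(post_ld) > 0L) {
    mann_whitney_one_tailed(post_ld$theta, bg)
  } else NULL
  enrich <- if (!is.null(scores)) tail_enrichment(scores, candidate_ids, cfg)
            else NULL
  rep <- list(
    cfg = cfg,
    n_background = length(bg),
    n_candidates_input = length(candidate_ids),
    n_candidates_used = nrow(cand),
    missing_candidates = missing_cand,
    filter_log = flt$log,
    median_candidates = stats::median(cand$theta),
    median_background = stats::median(bg),
    test_full = test_full,
    trim = trim,
    core_set = trim$core_set,
    median_core = stats::median(core$theta),
    test_core = test_core,
    ld_removed = ld$removed_ids,
    median_post_ld = if (nrow(post_ld) > 0L) stats::median(post_ld$theta) else NA_real_,
    test_post_ld = test_post_ld,
    enrichment = enrich
  )
  class(rep) <- "comparison_report"
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Candidate-set vs genomic-background comparison\n")
  cat(sprintf("  background SNPs: %d; candidates: %d used of %d supplied (%d missing)\n",
              x$n_background, x$n_candidates_used, x$n_candidates_input,
              length(x$missing_candidates)))
  cat(sprintf("  full set:    median %0.4g vs %0.4g; one-tailed Mann-Whitney p = %0.4g (%s)\n",
              x$median_candidates, x$median_background, x$test_full$p,
              x$test_full$method))
  cat(sprintf("  core set:    %d SNPs (%d removed top, %d bottom); median %0.4g; p = %0.4g\n",
              length(x$core_set), x$trim$n_removed_top,
              x$trim$n_removed_bottom, x$median_core, x$test_core$p))
  if (!is.null(x$test_post_ld)) {
    cat(sprintf("  post-LD set: %d removed by LD filter; median %0.4g; p = %0.4g\n",
                length(x$ld_removed), x$median_post_ld, x$test_post_ld$p))
  }
  if (!is.null(x$enrichment)) {
    cat("  score top-tail enrichment:\n")
    for (i in seq_len(nrow(x$enrichment))) {
      e <- x$enrichment[i, ]
      cat(sprintf("    %s: %s/%d in tail (%.1f%%), binomial p = %0.4g\n",
                  e$population,
                  ifelse(is.na(e$n_in_tail), "0", e$n_in_tail),
                  e$n_candidates_scored, 100 * e$proportion, e$p_binomial))
    }
  }
  invisible(x)
}
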