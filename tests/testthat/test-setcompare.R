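cfg_default <- pipeline_config()

test_that("filter_panel applies the three exclusion rules", {
  # MAF per sample for s_maf_all: 0.02/0.03/0.04 (excluded), s_maf_one has
  # one sample at 0.10 (kept); s_mono_part polymorphic in one sample (kept);
  # s_mono_all monomorphic everywhere (excluded); s_unsampled no data.
  n <- 100
  maf_counts <- function(maf) c(0, round(2 * n * maf), n - round(2 * n * maf))
  build <- function(id, per_pop) {
    do.call(rbind, lapply(1:3, function(k) {
      data.frame(snp_id = id, population = paste0("pop", k),
                 n_AA = per_pop[[k]][1], n_Aa = per_pop[[k]][2],
                 n_aa = per_pop[[k]][3], stringsAsFactors = FALSE)
    }))
  }
  panel <- snp_panel(rbind(
    build("s_maf_all", list(maf_counts(0.02), maf_counts(0.03), maf_counts(0.04))),
    build("s_maf_one", list(maf_counts(0.02), maf_counts(0.10), maf_counts(0.02))),
    build("s_mono_part", list(c(n, 0, 0), c(n, 0, 0), c(50, 30, 20))),
    build("s_mono_all", list(c(n, 0, 0), c(n, 0, 0), c(n, 0, 0))),
    build("s_unsampled", list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))),
    build("s_common", list(c(40, 40, 20), c(30, 50, 20), c(25, 50, 25)))
  ))
  res <- filter_panel(panel, cfg_default)
  kept <- unique(res$panel$snp_id)
  expect_setequal(kept, c("s_maf_one", "s_mono_part", "s_common"))
  expect_equal(res$log$rule[res$log$snp_id == "s_maf_all"], "maf")
  expect_equal(res$log$rule[res$log$snp_id == "s_mono_all"], "monomorphic")
  expect_equal(res$log$rule[res$log$snp_id == "s_unsampled"], "unsampled")
  # the strict "any sample below threshold" alternative drops s_maf_one too
  res_any <- filter_panel(panel, pipeline_config(maf_rule = "any"))
  expect_false("s_maf_one" %in% unique(res_any$panel$snp_id))
})

test_that("Mann-Whitney U and exact p match hand enumeration", {
  r <- mann_whitney_one_tailed(c(2, 3), c(0, 1))
  expect_equal(r$U, 4)
  expect_equal(r$p, 1 / 6)
  expect_identical(r$method, "exact")
  # wrong-direction shift: U = 0, p = 1
  r2 <- mann_whitney_one_tailed(c(1, 2), c(3, 4))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 1)
  # identical multisets: no shift, p at least ~0.5
  r3 <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_gte(r3$p, 0.5 - 1e-9)
  expect_error(mann_whitney_one_tailed(numeric(), c(1, 2)), "non-empty")
})

test_that("exact enumeration agrees with the brute-force oracle (ties included)", {
  set.seed(404)
  for (i in 1:40) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    vals <- sample(1:5, m + n, replace = TRUE)       # heavy ties
    cand <- vals[seq_len(m)]; bg <- vals[-seq_len(m)]
    got <- mann_whitney_one_tailed(cand, bg)
    ref <- mw_exact_brute(cand, bg)
    expect_equal(got$U, ref$U)
    expect_equal(got$p, ref$p)
  }
})

test_that("normal approximation tracks the exact p for moderate sizes", {
  set.seed(405)
  cand <- rnorm(8, 0.3); bg <- rnorm(8)
  exact <- mann_whitney_one_tailed(cand, bg)$p
  approx <- mann_whitney_one_tailed(cand, bg, exact_limit = 1)$p
  expect_equal(approx, exact, tolerance = 0.12)
  # and matches wilcox.test's tie-corrected normal path on large samples
  cand <- rnorm(60, 0.2); bg <- rnorm(300)
  got <- mann_whitney_one_tailed(cand, bg)
  ref <- stats::wilcox.test(cand, bg, alternative = "greater",
                            exact = FALSE, correct = TRUE)
  expect_identical(got$method, "normal")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("U and p are invariant under a common shift (rank statistic)", {
  set.seed(406)
  cand <- rnorm(20, 0.5); bg <- rnorm(100)
  a <- mann_whitney_one_tailed(cand, bg)
  b <- mann_whitney_one_tailed(cand + 3.7, bg + 3.7)
  expect_equal(a$U, b$U)
  expect_equal(a$p, b$p)
})

test_that("trim_outliers removes candidates outside background tail quantiles", {
  bg <- seq(0.01, 1, by = 0.01)
  cand <- data.frame(snp_id = c("a", "b", "c"), theta = c(0.001, 0.5, 2.0),
                     stringsAsFactors = FALSE)
  res <- trim_outliers(cand, bg, cfg_default)
  expect_equal(res$core_set, "b")
  expect_equal(res$n_removed_top, 1)
  expect_equal(res$n_removed_bottom, 1)
  # wide tails keep everything
  res2 <- trim_outliers(data.frame(snp_id = "b", theta = 0.5), bg, cfg_default)
  expect_equal(res2$core_set, "b")
  expect_error(trim_outliers(cand, bg[1:10], cfg_default), "background too small")
})

test_that("trimmed fraction converges to twice the tail fraction under exchangeability", {
  set.seed(407)
  n_rep <- 200; n_cand <- 100; n_bg <- 2000
  removed <- replicate(n_rep, {
    bg <- rnorm(n_bg)
    cand <- data.frame(snp_id = as.character(1:n_cand), theta = rnorm(n_cand))
    r <- trim_outliers(cand, bg, cfg_default)
    (r$n_removed_top + r$n_removed_bottom) / n_cand
  })
  se <- sqrt(0.1 * 0.9 / (n_rep * n_cand))
  expect_lt(abs(mean(removed) - 0.1), 3 * se)
})

test_that("LD filter removes only candidates with r2 strictly above threshold", {
  cand <- c("c1", "c2", "c3", "c4")
  ld <- data.frame(candidate_snp = c("c1", "c2", "c9"),
                   other_snp = c("g1", "g2", "g3"),
                   population = c("pop1", "pop2", "pop1"),
                   r2 = c(0.85, 0.80, 0.99),
                   trait = c("LDL cholesterol", "body mass index", "T2D"),
                   stringsAsFactors = FALSE)
  res <- ld_confound_filter(cand, ld, cfg_default)
  expect_equal(res$removed_ids, "c1")              # 0.80 exactly is kept
  expect_setequal(res$kept_ids, c("c2", "c3", "c4"))
  # empty table keeps everything
  res2 <- ld_confound_filter(cand, NULL, cfg_default)
  expect_equal(res2$kept_ids, cand)
  ld$r2[1] <- 1.3
  expect_error(ld_confound_filter(cand, ld, cfg_default), "malformed r2")
})

test_that("tail_enrichment counts top-tail candidates with an exact binomial test", {
  # deterministic construction: background 1..100 per population, candidates
  # sit at chosen ranks
  bg_ids <- sprintf("b%03d", 1:95)
  cand_ids <- sprintf("c%03d", 1:5)
  scores <- data.frame(snp_id = c(bg_ids, cand_ids), population = "pop1",
                       score = c(seq(0, 0.94, length.out = 95),
                                 c(0.995, 0.99, 0.1, 0.2, 0.3)),
                       stringsAsFactors = FALSE)
  res <- tail_enrichment(scores, cand_ids, cfg_default)
  expect_equal(res$n_candidates_scored, 5)
  expect_equal(res$n_in_tail, 2)
  expect_equal(res$p_binomial,
               stats::binom.test(2, 5, 0.05)$p.value)
  # exactly-null proportion gives p = 1
  set.seed(408)
  sc2 <- data.frame(snp_id = sprintf("x%04d", 1:2000), population = "pop1",
                    score = rnorm(2000), stringsAsFactors = FALSE)
  thr <- stats::quantile(sc2$score, 0.95, names = FALSE)
  in_tail <- sc2$snp_id[sc2$score > thr]
  cand <- c(in_tail[1:5], setdiff(sc2$snp_id, in_tail)[1:95])
  res2 <- tail_enrichment(sc2, cand, cfg_default)
  expect_equal(res2$n_in_tail, 5)
  expect_equal(res2$proportion, 0.05)
  expect_equal(res2$p_binomial, 1)
  # a population with no scored candidates is reported absent, not an error
  res3 <- tail_enrichment(sc2, c("absent1", "absent2"), cfg_default)
  expect_equal(res3$n_candidates_scored, 0)
  expect_true(is.na(res3$proportion))
})

test_that("run_comparison wires the stages together with consistent bookkeeping", {
  spec <- synth_spec(n_background_snps = 800, n_candidate_snps = 60,
                     n_per_pop = 60, F_background = 0.08, F_candidate = 0.2)
  gen <- balding_nichols_panel(spec, seed = 42)
  set.seed(43)
  ld <- synth_ld_table(gen$candidate_ids, 0.1, c(0.81, 0.99))
  scores <- synth_scores(unique(gen$panel$snp_id), gen$candidate_ids,
                         enrichment_factor = 1)
  rep <- run_comparison(gen$panel, gen$candidate_ids, ld_table = ld,
                        scores = scores)
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$n_candidates_used,
               length(rep$core_set) + rep$trim$n_removed_top +
                 rep$trim$n_removed_bottom)
  expect_true(all(rep$core_set %in% gen$candidate_ids))
  expect_true(all(rep$ld_removed %in% rep$core_set))
  expect_equal(rep$n_candidates_input, 60)
  expect_equal(nrow(rep$enrichment), 3)
  # strongly spiked candidates: shift detected
  expect_gt(rep$median_candidates, rep$median_background)
  expect_lt(rep$test_full$p, 0.05)
  # candidates absent from the panel (or removed by filtering) are logged,
  # not fatal
  rep2 <- run_comparison(gen$panel, c(gen$candidate_ids, "rs_not_there"))
  expect_true("rs_not_there" %in% rep2$missing_candidates)
  expect_true(all(setdiff(rep2$missing_candidates, "rs_not_there") %in%
                    c(rep2$filter_log$snp_id, gen$candidate_ids)))
  # no surviving candidate is an error
  expect_error(run_comparison(gen$panel, c("nope1", "nope2")),
               "no candidate SNP survives")
  # report printing and JSON serialization work
  expect_output(print(rep), "Mann-Whitney")
  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$n_candidates_used, rep$n_candidates_used)
})
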