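#' Simulation parameters for the polygenic-selection model
#'
#' Constructs the parameter set of the forward-in-time model: several
#' diploid populations of constant size evolve independently under a
#' Wright-Fisher scheme with recombination. Each individual carries
#' `n_loci_selected + n_loci_neutral` biallelic markers; the first block
#' contributes additively and codominantly to a phenotype, the second block
#' is neutral. Selection is viability selection through a Gaussian fitness
#' function of the beneficial-allele count m:
#' \deqn{w(m) = \exp\left(-\frac{(m-\mu)^2 x^2}{2s}\right)}
#' where x is the per-allele phenotypic effect, mu the beneficial-allele
#' count that maximizes fitness and s the selection strength (larger s =
#' weaker selection). Setting `effect_x = 0` switches selection off and the
#' model reduces to neutral Wright-Fisher drift.
#'
#' @param n_individuals diploid individuals per population (default 10000).
#' @param n_loci_selected number of trait loci (default 10).
#' @param n_loci_neutral number of neutral loci (default 10).
#' @param effect_x per-allele phenotypic effect x (default 5).
#' @param optimum_mu beneficial-allele count mu maximizing fitness
#'   (default 10; must lie in `[0, 2 * n_loci_selected]`).
#' @param strength_s selection-strength parameter s > 0 (default 10).
#' @param init_freq initial beneficial-allele frequency at every locus
#'   (default 0.5).
#' @param n_populations number of independently evolving populations
#'   (default 3).
#' @param n_generations generations to simulate (default 200; the
#'   allele-frequency split under the default selection regime is well
#'   developed by then at N in the thousands).
#' @param recomb_rate per-adjacent-locus recombination probability per
#'   meiosis, in `[0, 0.5]`; 0.5 = free recombination (default).
#' @param exact_init if `TRUE`, initialize each locus at exactly
#'   `round(2 N init_freq)` beneficial alleles, randomly placed; otherwise
#'   (default) draw each allele Bernoulli(`init_freq`).
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 10000,
                       n_loci_selected = 10,
                       n_loci_neutral = 10,
                       effect_x = 5,
                       optimum_mu = 10,
                       strength_s = 10,
                       init_freq = 0.5,
                       n_populations = 3,
                       n_generations = 200,
                       recomb_rate = 0.5,
                       exact_init = FALSE) {
  stopifnot(n_individuals >= 2,
            n_loci_selected >= 0, n_loci_neutral >= 0,
            n_loci_selected + n_loci_neutral >= 1,
            optimum_mu >= 0, optimum_mu <= 2 * n_loci_selected,
            effect_x >= 0, strength_s > 0,
            init_freq >= 0, init_freq <= 1,
            n_populations >= 1, n_generations >= 0,
            recomb_rate >= 0, recomb_rate <= 0.5)
  p <- list(n_individuals = as.integer(n_individuals),
            n_loci_selected = as.integer(n_loci_selected),
            n_loci_neutral = as.integer(n_loci_neutral),
            effect_x = effect_x, optimum_mu = optimum_mu,
            strength_s = strength_s, init_freq = init_freq,
            n_populations = as.integer(n_populations),
            n_generations = as.integer(n_generations),
            recomb_rate = recomb_rate, exact_init = isTRUE(exact_init))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Wright-Fisher polygenic-selection parameters\n")
  cat(sprintf("  N=%d diploids x %d populations, %d+%d loci (selected+neutral)\n",
              x$n_individuals, x$n_populations, x$n_loci_selected, x$n_loci_neutral))
  cat(sprintf("  fitness exp(-(m-%g)^2 %g^2 / (2*%g)), init freq %g\n",
              x$optimum_mu, x$effect_x, x$strength_s, x$init_freq))
  cat(sprintf("  %d generations, recombination rate %g\n",
              x$n_generations, x$recomb_rate))
  invisible(x)
}

#' Gaussian stabilizing-selection fitness
#'
#' Relative viability of an individual carrying `m` beneficial alleles:
#' `exp(-(m - mu)^2 x^2 / (2 s))`. Maximal (= 1) at `m = mu` and symmetric
#' about it.
#'
#' @param m beneficial-allele count(s), in `[0, 2 * n_loci_selected]`.
#' @param params a [sim_params()] object.
#' @return numeric vector of relative viabilities in (0, 1].
#' @export
fitness <- function(m, params) {
  exp(-(m - params$optimum_mu)^2 * params$effect_x^2 / (2 * params$strength_s))
}

#' Initialize a population
#'
#' Haplotypes are stored as a `2N x L` 0/1 matrix; individual `i` owns rows
#' `i` and `N + i`. Each allele is drawn Bernoulli(`init_freq`) (or placed
#' by exact count when `params$exact_init`).
#'
#' @param params a [sim_params()] object.
#' @return list of class `wf_population` with elements `haplotypes` and
#'   `generation` (= 0).
#' @export
init_population <- function(params) {
  L <- params$n_loci_selected + params$n_loci_neutral
  n_hap <- 2L * params$n_individuals
  if (params$exact_init) {
    k <- round(n_hap * params$init_freq)
    hap <- vapply(seq_len(L), function(l) {
      v <- integer(n_hap); v[sample.int(n_hap, k)] <- 1L; v
    }, integer(n_hap))
  } else {
    hap <- matrix(as.integer(stats::runif(n_hap * L) < params$init_freq),
                  nrow = n_hap, ncol = L)
  }
  structure(list(haplotypes = hap, generation = 0L), class = "wf_population")
}

# One recombinant gamete per row of `parents` (indices into 1..N).
# Meiosis: start on a uniformly chosen parental haplotype and switch source
# haplotype between adjacent loci with probability recomb_rate.
make_gametes <- function(hap, parents, params) {
  N <- params$n_individuals
  L <- ncol(hap)
  G <- length(parents)
  hapA <- hap[parents, , drop = FALSE]
  hapB <- hap[N + parents, , drop = FALSE]
  src <- matrix(0L, nrow = G, ncol = L)
  cur <- as.integer(stats::runif(G) < 0.5)
  src[, 1L] <- cur
  if (L > 1L) {
    for (l in 2:L) {
      flip <- stats::runif(G) < params$recomb_rate
      cur <- ifelse(flip, 1L - cur, cur)
      src[, l] <- cur
    }
  }
  hapA * (1L - src) + hapB * src
}

#' Advance a population by one generation
#'
#' Each of the N offspring draws two parents independently with probability
#' proportional to viability (fitness of the parental beneficial-allele
#' count, rescaled by its maximum so that only relative fitness matters and
#' strong selection cannot underflow); each parent transmits one recombinant
#' gamete. Population size is constant; generation is incremented.
#'
#' @param pop a `wf_population`.
#' @param params the [sim_params()] the population was built with.
#' @return the next `wf_population`.
#' @export
next_generation <- function(pop, params) {
  N <- params$n_individuals
  hap <- pop$haplotypes
  sel <- seq_len(params$n_loci_selected)
  if (params$n_loci_selected > 0L && params$effect_x > 0) {
    m <- rowSums(hap[seq_len(N), sel, drop = FALSE] +
                 hap[N + seq_len(N), sel, drop = FALSE])
    w <- fitness(m, params)
    wmax <- max(w)
    if (wmax == 0) stop("degenerate fitness: all parental viabilities underflow to 0")
    w <- w / wmax
  } else {
    w <- rep(1, N)
  }
  parents <- sample.int(N, 2L * N, replace = TRUE, prob = w)
  gam <- make_gametes(hap, parents, params)
  structure(list(haplotypes = gam, generation = pop$generation + 1L),
            class = "wf_population")
}

#' Beneficial-allele frequencies of a population
#' @param pop a `wf_population`.
#' @return numeric vector of per-locus allele-1 frequencies.
#' @export
allele_frequencies <- function(pop) colMeans(pop$haplotypes)

#' Run the full multi-population simulation
#'
#' Simulates `n_populations` independent populations for `n_generations`
#' generations, recording per-locus beneficial-allele frequencies every
#' generation. Each population consumes its own RNG substream derived from
#' `seed` (population k uses `seed + k - 1`), so runs are reproducible and
#' populations independent.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; `NULL` uses the current RNG state (populations
#'   then share one stream, still independent draws).
#' @param keep_final if `TRUE` (default) the final `wf_population` objects
#'   are kept for downstream genotype sampling ([sim_fst_summary()]).
#' @return list of class `sim_result`: `frequencies` (array
#'   `n_populations x L x (n_generations + 1)`), `locus_class` (character,
#'   "selected"/"neutral"), `params`, `seed`, and `final_populations`.
#' @export
run_simulation <- function(params, seed = NULL, keep_final = TRUE) {
  L <- params$n_loci_selected + params$n_loci_neutral
  freqs <- array(NA_real_,
                 dim = c(params$n_populations, L, params$n_generations + 1L),
                 dimnames = list(paste0("pop", seq_len(params$n_populations)),
                                 NULL, NULL))
  finals <- vector("list", params$n_populations)
  for (k in seq_len(params$n_populations)) {
    if (!is.null(seed)) set.seed(seed + k - 1L)
    pop <- init_population(params)
    freqs[k, , 1L] <- allele_frequencies(pop)
    g <- 0L
    while (g < params$n_generations) {
      pop <- next_generation(pop, params)
      g <- g + 1L
      freqs[k, , g + 1L] <- allele_frequencies(pop)
    }
    if (keep_final) finals[[k]] <- pop
  }
  structure(list(frequencies = freqs,
                 locus_class = rep(c("selected", "neutral"),
                                   c(params$n_loci_selected, params$n_loci_neutral)),
                 params = params, seed = seed,
                 final_populations = if (keep_final) finals else NULL),
            class = "sim_result")
}

#' Trajectories as a long data frame
#'
#' @param result a `sim_result`.
#' @return data frame with columns `population`, `locus`, `locus_class`,
#'   `generation`, `frequency`; one row per cell, suitable for TSV export
#'   or plotting.
#' @export
trajectory_df <- function(result) {
  d <- dim(result$frequencies)
  out <- expand.grid(population = paste0("pop", seq_len(d[1L])),
                     locus = seq_len(d[2L]),
                     generation = 0:(d[3L] - 1L),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$locus_class <- result$locus_class[out$locus]
  out$frequency <- as.vector(result$frequencies)
  out[, c("population", "locus", "locus_class", "generation", "frequency")]
}

#' Sample the final generation into a genotype-count panel
#'
#' Draws a random sample of individuals from each population's final
#' generation, forms diploid genotypes and returns a [snp_panel()] (one
#' "SNP" per locus; the beneficial allele is the reference allele A).
#'
#' @param result a `sim_result` run with `keep_final = TRUE`.
#' @param sample_size diploid individuals to sample per population; at most
#'   `n_individuals`.
#' @return a `snp_panel` with SNP ids `locus_01`, ... and an attribute
#'   `locus_class`.
#' @export
sim_panel <- function(result, sample_size) {
  if (is.null(result$final_populations)) {
    stop("simulation was run with keep_final = FALSE")
  }
  params <- result$params
  stopifnot(sample_size >= 1, sample_size <= params$n_individuals)
  L <- params$n_loci_selected + params$n_loci_neutral
  ids <- sprintf("locus_%02d", seq_len(L))
  rows <- vector("list", params$n_populations)
  for (k in seq_len(params$n_populations)) {
    hap <- result$final_populations[[k]]$haplotypes
    N <- params$n_individuals
    idx <- sample.int(N, sample_size)
    geno <- hap[idx, , drop = FALSE] + hap[N + idx, , drop = FALSE]
    rows[[k]] <- data.frame(snp_id = ids,
                            population = sprintf("pop%d", k),
                            n_AA = colSums(geno == 2L),
                            n_Aa = colSums(geno == 1L),
                            n_aa = colSums(geno == 0L),
                            stringsAsFactors = FALSE)
  }
  panel <- snp_panel(do.call(rbind, rows))
  attr(panel, "locus_class") <- result$locus_class
  panel
}

#' Mean F_ST of selected vs neutral loci in a simulation
#'
#' Samples `sample_size` individuals per population from the final
#' generation, estimates per-locus Weir-Cockerham theta and averages it
#' within the selected and the neutral locus sets. Under polygenic
#' stabilizing selection the selected set is expected to show the larger
#' mean differentiation.
#'
#' @inheritParams sim_panel
#' @return list: `per_locus` (the [panel_fst()] table plus `locus_class`),
#'   `mean_theta_selected`, `mean_theta_neutral` (means over loci with
#'   defined theta; `NaN` if none).
#' @export
sim_fst_summary <- function(result, sample_size) {
  panel <- sim_panel(result, sample_size)
  tab <- panel_fst(panel)
  cls <- attr(panel, "locus_class")[as.integer(sub("locus_", "", tab$snp_id))]
  tab$locus_class <- cls
  ok <- tab$defined
  list(per_locus = tab,
       mean_theta_selected = mean(tab$theta[ok & cls == "selected"]),
       mean_theta_neutral = mean(tab$theta[ok & cls == "neutral"]))
}
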