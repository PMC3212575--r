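#' SNP panel of per-population genotype counts
#'
#' A `snp_panel` is a long-format data frame with one row per SNP x
#' population and columns `snp_id`, `population`, `n_AA`, `n_Aa`, `n_aa`,
#' where `A` is an arbitrary but fixed reference allele per SNP. Counts may
#' be non-integer (e.g. expected counts); they must be non-negative and
#' finite. Every SNP must carry a row for every population in the panel.
#'
#' @param x data frame with columns `snp_id`, `population`, `n_AA`, `n_Aa`,
#'   `n_aa`. Extra columns are preserved.
#' @return `x` with class `snp_panel` prepended, rows ordered by SNP then
#'   population.
#' @export
snp_panel <- function(x) {
  required <- c("snp_id", "population", "n_AA", "n_Aa", "n_aa")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$snp_id <- as.character(x$snp_id)
  x$population <- as.character(x$population)
  for (col in c("n_AA", "n_Aa", "n_aa")) {
    v <- x[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("column ", col, " must be non-negative and finite")
    }
  }
  if (anyDuplicated(x[, c("snp_id", "population")])) {
    stop("duplicate (snp_id, population) rows in panel")
  }
  pops <- sort(unique(x$population))
  tab <- table(x$snp_id)
  if (any(tab != length(pops))) {
    bad <- names(tab)[tab != length(pops)][1L]
    stop("SNP ", bad, " does not have a row for every population")
  }
  x <- x[order(x$snp_id, x$population), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("snp_panel", "data.frame")
  x
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", length(unique(x$snp_id)), " SNPs x ",
      length(unique(x$population)), " populations (",
      paste(sort(unique(x$population)), collapse = ", "), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Population labels of a panel
#' @param panel a `snp_panel`
#' @return character vector of population labels, sorted
#' @export
panel_populations <- function(panel) sort(unique(panel$population))

# Reshape a panel into aligned SNP x population matrices of sample sizes,
# reference-allele frequencies and observed heterozygote proportions.
# Populations with n = 0 get p = h = 0 (they carry zero weight downstream).
panel_matrices <- function(panel) {
  pops <- panel_populations(panel)
  snps <- unique(panel$snp_id)          # panel is ordered snp-major
  S <- length(snps)
  r <- length(pops)
  # ordered snp-major, population-minor by construction in snp_panel()
  n <- matrix(panel$n_AA + panel$n_Aa + panel$n_aa, nrow = S, ncol = r, byrow = TRUE)
  p_num <- matrix(2 * panel$n_AA + panel$n_Aa, nrow = S, ncol = r, byrow = TRUE)
  h_num <- matrix(panel$n_Aa, nrow = S, ncol = r, byrow = TRUE)
  p <- ifelse(n > 0, p_num / (2 * n), 0)
  h <- ifelse(n > 0, h_num / n, 0)
  dimnames(n) <- dimnames(p) <- dimnames(h) <- list(snps, pops)
  list(snp_id = snps, populations = pops, n = n, p = p, h = h)
}

#' Pool population samples of a panel
#'
#' Sums genotype counts within groups of populations, e.g. merging the CHB
#' and JPT HapMap samples into a single East-Asian sample before F_ST
#' estimation.
#'
#' @param panel a `snp_panel`
#' @param groups named character vector mapping every population label in
#'   the panel to its merged label, e.g.
#'   `c(CEU = "CEU", YRI = "YRI", CHB = "ASN", JPT = "ASN")`.
#' @return a `snp_panel` over the merged population labels.
#' @export
pool_samples <- function(panel, groups) {
  pops <- panel_populations(panel)
  unknown <- setdiff(names(groups), pops)
  if (length(unknown) > 0L) {
    stop("group mapping references unknown population(s): ",
         paste(unknown, collapse = ", "))
  }
  unmapped <- setdiff(pops, names(groups))
  if (length(unmapped) > 0L) {
    stop("population(s) not mapped: ", paste(unmapped, collapse = ", "))
  }
  merged <- unname(groups[panel$population])
  agg <- stats::aggregate(
    panel[, c("n_AA", "n_Aa", "n_aa")],
    by = list(snp_id = panel$snp_id, population = merged),
    FUN = sum
  )
  snp_panel(agg)
}
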