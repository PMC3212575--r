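#' Read a genotype-count panel from TSV
#'
#' Two dialects are accepted. `genotype`: columns `snp_id`, `population`,
#' `n_AA`, `n_Aa`, `n_aa`. `frequency`: columns `snp_id`, `population`,
#' `n`, `p_ref`; heterozygote counts are imputed under Hardy-Weinberg
#' equilibrium as `n * 2 p (1 - p)` (use `hwe = TRUE` downstream for
#' consistency). Malformed rows are rejected with their line numbers.
#'
#' @param path TSV file with a header; lines starting `#` are ignored.
#' @param dialect `"genotype"` (default) or `"frequency"`.
#' @return a [snp_panel()].
#' @export
read_panel <- function(path, dialect = c("genotype", "frequency")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (dialect == "genotype") {
    need <- c("snp_id", "population", "n_AA", "n_Aa", "n_aa")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0L) {
      stop("panel file missing column(s): ", paste(miss, collapse = ", "))
    }
    bad <- which(x$n_AA < 0 | x$n_Aa < 0 | x$n_aa < 0)
    if (length(bad) > 0L) {
      stop("negative genotype counts at data line(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  } else {
    need <- c("snp_id", "population", "n", "p_ref")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0L) {
      stop("panel file missing column(s): ", paste(miss, collapse = ", "))
    }
    bad <- which(x$n < 0 | x$p_ref < 0 | x$p_ref > 1)
    if (length(bad) > 0L) {
      stop("invalid n or p_ref at data line(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    h <- 2 * x$p_ref * (1 - x$p_ref)
    x <- data.frame(snp_id = x$snp_id, population = x$population,
                    n_AA = x$n * x$p_ref^2,        # HWE expected counts
                    n_Aa = x$n * h,
                    n_aa = x$n * (1 - x$p_ref)^2,
                    stringsAsFactors = FALSE)
  }
  if (anyDuplicated(x[, c("snp_id", "population")])) {
    d <- which(duplicated(x[, c("snp_id", "population")]))[1L]
    stop("duplicate (snp_id, population) row at data line ", d)
  }
  snp_panel(x)
}

#' Write a panel as genotype-dialect TSV
#' @param panel a [snp_panel()].
#' @param path output path.
#' @param header optional named character vector written as `# key: value`
#'   comment lines (e.g. seed, config hash).
#' @export
write_panel <- function(panel, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header), header), con)
  }
  utils::write.table(as.data.frame(panel)[, c("snp_id", "population",
                                              "n_AA", "n_Aa", "n_aa")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a candidate-SNP id list (one id per line)
#' @param path file path.
#' @return character vector of ids.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  x <- trimws(x[!startsWith(trimws(x), "#")])
  x[nzchar(x)]
}

#' @rdname read_candidates
#' @param ids character vector of SNP ids.
#' @export
write_candidates <- function(ids, path) writeLines(ids, path)

#' Read an LD table TSV
#'
#' Columns `candidate_snp`, `other_snp`, `population`, `r2`, `trait`.
#' @param path file path.
#' @return data frame.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE,
                         quote = "")
  need <- c("candidate_snp", "other_snp", "population", "r2", "trait")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("LD table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(x$r2) | x$r2 < 0 | x$r2 > 1)
  if (length(bad) > 0L) {
    stop("malformed r2 at data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  x
}

#' Read a per-population score TSV (columns snp_id, population, score)
#' @param path file path.
#' @return data frame.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("snp_id", "population", "score")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("score table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(x$score))
  if (length(bad) > 0L) {
    stop("non-finite score at data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  x
}

#' Serialize a comparison report to JSON
#' @param report a `comparison_report` from [run_comparison()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$cfg <- unclass(out$cfg)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}
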