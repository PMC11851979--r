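#' Build the long summary table and the wide decision table
#'
#' Collects [find_mssr()] results into the two standard outputs: a long
#' "table 1"-style data.frame with one row per (condition, sample size)
#' holding the ratio percentiles and outperformance proportion, and a
#' wide "table 2"-style data.frame with one row per condition holding the
#' design factor codes, Rt2 and the two MSSR decisions.
#'
#' @param results list of `mssr_result` objects.
#' @return list with data.frames `table1` (columns `condition_id`, `n`,
#'   `lp`, `up`, `above`) and `table2` (columns `condition_id`,
#'   `complexity`, `linear_level`, `nonlinear_level`, `error_coef`,
#'   `n_iv`, `rt2`, `mssr_stability`, `mssr_outperform`; `NA` MSSR =
#'   unattainable).
#' @export
build_tables <- function(results) {
  stopifnot(length(results) >= 1)
  grid <- condition_grid()
  t1 <- do.call(rbind, lapply(results, function(res) {
    do.call(rbind, lapply(res$summaries, function(s)
      data.frame(condition_id = s$condition_id, n = s$n,
                 lp = s$lp, up = s$up, above = s$above)))
  }))
  rownames(t1) <- NULL
  t2 <- do.call(rbind, lapply(results, function(res) {
    g <- grid[grid$condition_id == res$condition_id, ]
    data.frame(g, rt2 = res$rt2,
               mssr_stability = res$mssr_stability,
               mssr_outperform = res$mssr_outperform)
  }))
  rownames(t2) <- NULL
  list(table1 = t1[order(t1$condition_id, t1$n), ],
       table2 = t2[order(t2$condition_id), ])
}

# Encode unattainable decisions as the literal 'X' for serialization.
format_table2 <- function(table2) {
  table2$mssr_stability <- ifelse(is.na(table2$mssr_stability), "X",
                                  as.character(table2$mssr_stability))
  table2$mssr_outperform <- ifelse(is.na(table2$mssr_outperform), "X",
                                   as.character(table2$mssr_outperform))
  table2
}

parse_mssr_column <- function(x) {
  x <- as.character(x)
  x[x %in% c("X", "x")] <- NA
  as.integer(x)
}

#' Read and write the decision tables
#'
#' CSV round-trip for the two table formats. Unattainable decisions are
#' serialized as the literal `X` and parsed back to `NA`.
#'
#' @param table1,table2 data.frames as produced by [build_tables()].
#' @param path file path.
#' @return the written path (write) or the parsed data.frame (read).
#' @export
write_table1 <- function(table1, path) {
  utils::write.csv(table1, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table1
#' @export
read_table1 <- function(path) {
  utils::read.csv(path)
}

#' @rdname write_table1
#' @export
write_table2 <- function(table2, path) {
  utils::write.csv(format_table2(table2), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_table1
#' @export
read_table2 <- function(path) {
  df <- utils::read.csv(path)
  df$mssr_stability <- parse_mssr_column(df$mssr_stability)
  df$mssr_outperform <- parse_mssr_column(df$mssr_outperform)
  df
}

#' Reference summary tables from the full-scale simulation study
#'
#' Transcriptions of the published results of the full-scale run (1000
#' replications per condition on the complete 81-combination grid),
#' bundled for decision replay and meta-analysis:
#' `reference_table1()` returns the published per-sample-size summary
#' columns for the five example conditions (1, 19, 26, 38, 98);
#' `reference_table2()` returns the full 108-condition decision table
#' (factor codes, Rt2, and the MSSR under each criterion, `NA` =
#' unattainable).
#'
#' @return a data.frame (see [build_tables()] for the schemas).
#' @export
reference_table1 <- function() {
  read_table1(system.file("extdata", "table1_reference.csv",
                          package = "mssrnn", mustWork = TRUE))
}

#' @rdname reference_table1
#' @export
reference_table2 <- function() {
  read_table2(system.file("extdata", "table2_reference.csv",
                          package = "mssrnn", mustWork = TRUE))
}

mssr_column <- function(criterion = c("stability", "outperform")) {
  paste0("mssr_", match.arg(criterion))
}

#' Count conditions with an attainable MSSR
#'
#' @param table2 a wide decision table (see [build_tables()]).
#' @param criterion `"stability"` or `"outperform"`.
#' @return integer: number of rows whose MSSR for the criterion is
#'   numeric (not unattainable).
#' @export
#' @examples
#' count_attainable(reference_table2(), "outperform") # 89
count_attainable <- function(table2, criterion = c("stability",
                                                   "outperform")) {
  sum(!is.na(table2[[mssr_column(criterion)]]))
}

#' Correlation meta-analysis of MSSR against the design factors
#'
#' Correlates the MSSR under one criterion with each design factor —
#' error level, number of IVs, linear coefficient level, complexity,
#' nonlinear coefficient level — plus Rt2. Conditions with an
#' unattainable MSSR for the criterion are excluded. The default is
#' Spearman rank correlation (Pearson correlation of average ranks, ties
#' averaged), which is invariant to monotone recoding of the heavily
#' tied ordinal factor codes. `method = "pearson"` computes product-moment
#' correlations on the raw values instead; this is the convention that
#' reproduces the published stability-criterion meta-analysis exactly
#' (the reference report labels those coefficients as rank correlations,
#' but their printed values match Pearson on raw values to the fourth
#' decimal). Two-sided p-values use the t approximation and are reported
#' for reference only: with at most 108 conditions these tests are
#' descriptive, not confirmatory.
#'
#' @param table2 a wide decision table.
#' @param criterion `"stability"` or `"outperform"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with columns `factor`, `rho`, `p_value`, `n_used`.
#'   A factor that is constant over the usable rows has undefined
#'   correlation and is reported with `rho = NA`.
#' @export
#' @examples
#' spearman_factor_analysis(reference_table2(), "stability")
#' spearman_factor_analysis(reference_table2(), "stability", "pearson")
spearman_factor_analysis <- function(table2,
                                     criterion = c("stability",
                                                   "outperform"),
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  col <- mssr_column(criterion)
  keep <- !is.na(table2[[col]])
  if (sum(keep) < 3)
    stop("need at least 3 conditions with an attainable MSSR", call. = FALSE)
  mssr <- table2[[col]][keep]
  factors <- c(error_coef = "error_coef", n_iv = "n_iv",
               linear_level = "linear_level", complexity = "complexity",
               nonlinear_level = "nonlinear_level", rt2 = "rt2")
  rows <- lapply(names(factors), function(f) {
    x <- table2[[factors[[f]]]][keep]
    if (length(unique(x)) < 2) {
      return(data.frame(factor = f, rho = NA_real_, p_value = NA_real_,
                        n_used = sum(keep)))
    }
    rho <- stats::cor(mssr, x, method = method)
    nn <- sum(keep)
    tt <- rho * sqrt((nn - 2) / (1 - rho^2))
    data.frame(factor = f, rho = rho,
               p_value = 2 * stats::pt(-abs(tt), df = nn - 2),
               n_used = nn)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
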