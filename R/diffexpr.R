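#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p value.  Implemented from the defining formulas; the test
#' suite checks agreement with the reference implementation in stats to
#' 1e-10.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop_("welch_t needs at least 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t_stat = 0, df = length(x) +
                                          length(y) - 2, p_value = 1))
    stop_("both groups have zero variance; t statistic undefined")
  }
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Bonferroni multiple-testing correction
#'
#' @param p_values Raw p values.
#' @param m Size of the test family; must be at least the number of tests.
#' @return Adjusted p values, `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop_("m must be a single integer >= 1")
  if (m < length(p_values))
    stop_("family size m (%d) smaller than number of tests (%d)",
          m, length(p_values))
  pmin(1, p_values * m)
}

#' Per-probe differential expression versus a control cohort
#'
#' For every (probe, disease cohort) pair, Welch-tests the relative
#' expression levels of the disease group against the control group and
#' Bonferroni-corrects over the full family (probes x disease cohorts, the
#' most conservative family).  A probe is called `up`/`down` by the sign of
#' the group-mean difference of relative expression when the adjusted p is
#' below `alpha`, `ns` otherwise.
#'
#' @param expr An `expression_matrix`.
#' @param control_label Control group label (default `"CTRL"`).
#' @param alpha Significance level after correction (default 0.05).
#' @return Data frame (class `diff_table`) with columns `probe_id`,
#'   `disease_label`, `fold_direction`, `fold_ratio` (case mean / control
#'   mean), `t_stat`, `p_raw`, `p_adjusted`.
#' @export
differential_table <- function(expr, control_label = "CTRL", alpha = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!control_label %in% expr$groups)
    stop_("control label %s not present", sQuote(control_label))
  diseases <- setdiff(unique(expr$groups), control_label)
  sizes <- table(expr$groups)
  small <- diseases[sizes[diseases] < 2L]
  if (length(small) > 0L) {
    warning(sprintf("skipping group(s) with <2 subjects: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    diseases <- setdiff(diseases, small)
  }
  ctrl_rows <- group_rows(expr, control_label)
  probes <- colnames(expr$levels)
  m <- length(probes) * length(diseases)
  res <- do.call(rbind, lapply(diseases, function(d) {
    case_rows <- group_rows(expr, d)
    do.call(rbind, lapply(probes, function(p) {
      xc <- expr$levels[case_rows, p]; x0 <- expr$levels[ctrl_rows, p]
      w <- welch_t(xc, x0)
      data.frame(probe_id = p, disease_label = d,
                 fold_ratio = mean(xc, na.rm = TRUE) / mean(x0, na.rm = TRUE),
                 t_stat = w$t_stat, p_raw = w$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
  res$p_adjusted <- bonferroni(res$p_raw, m)
  res$fold_direction <- ifelse(res$p_adjusted < alpha,
                               ifelse(res$fold_ratio > 1, "up", "down"),
                               "ns")
  res <- res[, c("probe_id", "disease_label", "fold_direction",
                 "fold_ratio", "t_stat", "p_raw", "p_adjusted")]
  class(res) <- c("diff_table", "data.frame")
  attr(res, "m") <- m
  attr(res, "alpha") <- alpha
  res
}

#' Write a differential-expression table as TSV
#'
#' Long-format TSV (probe, disease, direction in {up, down, ns}, fold
#' ratio, adjusted p), the tabular equivalent of a red/green
#' over/under-expression heatmap.
#'
#' @param tbl A `diff_table`.
#' @param path Output path.
#' @export
write_differential_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "diff_table"))
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tbl)
}
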