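#' Separation count of a candidate ratio
#'
#' Number of case values strictly greater than the maximum of the control
#' values — the number of cases a control-max threshold on this quantity
#' would capture.
#'
#' @param case_values,control_values Numeric vectors (controls nonempty).
#' @return Nonnegative integer.
#' @export
separation_count <- function(case_values, control_values) {
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) == 0L)
    stop_("empty control group: threshold undefined")
  sum(case_values > max(control_values), na.rm = TRUE)
}

# All ordered probe pairs of an expression matrix.  Returns the subjects x
# pairs matrix of log2 ratio values plus the pair index.  A/B and B/A are
# distinct candidates (they separate in opposite directions); A/A excluded.
all_log2_ratios <- function(expr) {
  L <- log2(expr$levels)
  p <- ncol(L)
  pairs <- expand.grid(den = seq_len(p), num = seq_len(p))[, c("num", "den")]
  pairs <- pairs[pairs$num != pairs$den, , drop = FALSE]
  m <- L[, pairs$num, drop = FALSE] - L[, pairs$den, drop = FALSE]
  probes <- colnames(L)
  colnames(m) <- paste(probes[pairs$num], probes[pairs$den], sep = "/")
  list(values = m,
       numerator = probes[pairs$num], denominator = probes[pairs$den])
}

#' Resampled search for discriminatory two-gene ratios
#'
#' In each of `reps` repetitions, 80% of the case group and 80% of the
#' control group are drawn without replacement (stratified), every ordered
#' two-gene ratio is ranked by its separation count on the subsample, and
#' the `top_k` separating ratios are retained.  Retention counts across
#' repetitions give each candidate's selection frequency; candidates are
#' returned ranked by selection frequency, then full-data separation count,
#' then lexicographic probe-pair order — fully deterministic for a fixed
#' seed.
#'
#' @param expr An `expression_matrix`.
#' @param case_label Case group label(s); a vector denotes a union cohort
#'   (e.g. `c("CD","UC")` for IBD).
#' @param control_label Control group label(s).
#' @param resample_frac Fraction of each group drawn per repetition.
#' @param reps Number of repetitions.
#' @param top_k Ratios retained per repetition.
#' @param seed Integer seed (required).
#' @return Data frame of class `ratio_candidates`: `numerator`,
#'   `denominator`, `selection_frequency`, `separation_count` (on the full
#'   data).
#' @export
search_candidates <- function(expr, case_label, control_label,
                              resample_frac = 0.80, reps = 200L,
                              top_k = 500L, seed) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (missing(seed)) stop_("a seed is required (no silent nondeterminism)")
  case_rows <- group_rows(expr, case_label)
  ctrl_rows <- group_rows(expr, control_label)
  if (length(case_rows) < 5L || length(ctrl_rows) < 5L)
    stop_("need at least 5 subjects per group (case %d, control %d)",
          length(case_rows), length(ctrl_rows))
  n_case_s <- ceiling(resample_frac * length(case_rows))
  n_ctrl_s <- ceiling(resample_frac * length(ctrl_rows))
  if (n_case_s < 2L || n_ctrl_s < 2L)
    stop_("groups too small for resampling at fraction %g", resample_frac)
  rat <- all_log2_ratios(expr)
  nr <- ncol(rat$values)
  tally <- integer(nr)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      cs <- sample(case_rows, n_case_s)
      ks <- sample(ctrl_rows, n_ctrl_s)
      cmax <- col_max(rat$values[ks, , drop = FALSE])
      sep <- colSums(rat$values[cs, , drop = FALSE] >
                       rep(cmax, each = n_case_s), na.rm = TRUE)
      top <- utils::head(order(sep, decreasing = TRUE), top_k)
      top <- top[sep[top] > 0L]  # only ratios that actually separate
      tally[top] <- tally[top] + 1L
    }
  })
  keep <- which(tally > 0L)
  cmax_full <- col_max(rat$values[ctrl_rows, keep, drop = FALSE])
  sep_full <- colSums(rat$values[case_rows, keep, drop = FALSE] >
                        rep(cmax_full, each = length(case_rows)),
                      na.rm = TRUE)
  out <- data.frame(numerator = rat$numerator[keep],
                    denominator = rat$denominator[keep],
                    selection_frequency = tally[keep] / reps,
                    separation_count = as.integer(sep_full),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$selection_frequency, -out$separation_count,
                   out$numerator, out$denominator), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ratio_candidates", "data.frame")
  out
}

#' Assemble a minimal ratio panel by greedy case coverage
#'
#' Greedy forward selection on the full training data: each ratio's
#' threshold is the maximum of its value over the training controls; a case
#' is covered by a ratio if its value strictly exceeds that threshold.  The
#' candidate covering the most not-yet-covered cases is added repeatedly
#' (ties broken by candidate rank) until no candidate adds coverage, giving
#' the smallest-in-practice set of ratios with maximal joint separation.
#'
#' @param candidates A `ratio_candidates` frame (or any data frame with
#'   `numerator`/`denominator` columns), already ranked.
#' @param expr Training `expression_matrix`.
#' @param case_label,control_label Group label(s).
#' @param max_size Optional cap on panel size.
#' @return A `ratio_panel`: data frame `numerator`, `denominator`,
#'   `threshold` with attributes `case_label`, `control_label`.
#' @export
select_panel <- function(candidates, expr, case_label, control_label,
                         max_size = Inf) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(candidates) == 0L) stop_("no candidates supplied")
  case_rows <- group_rows(expr, case_label)
  ctrl_rows <- group_rows(expr, control_label)
  if (length(ctrl_rows) == 0L) stop_("empty control group")
  L <- log2(expr$levels)
  check_probes(expr, unique(c(candidates$numerator, candidates$denominator)))
  vals <- L[, candidates$numerator, drop = FALSE] -
    L[, candidates$denominator, drop = FALSE]
  thr_log <- col_max(vals[ctrl_rows, , drop = FALSE])
  covers <- vals[case_rows, , drop = FALSE] >
    rep(thr_log, each = length(case_rows))
  covers[is.na(covers)] <- FALSE
  chosen <- integer(0)
  covered <- rep(FALSE, length(case_rows))
  repeat {
    gain <- colSums(covers & !covered)
    gain[chosen] <- -1L
    best <- which.max(gain)  # first index on ties = highest candidate rank
    if (gain[best] <= 0L || length(chosen) >= max_size) break
    chosen <- c(chosen, best)
    covered <- covered | covers[, best]
  }
  if (length(chosen) == 0L) {
    warning("no candidate covers any case subject; returning empty panel",
            call. = FALSE)
  }
  panel <- data.frame(numerator = candidates$numerator[chosen],
                      denominator = candidates$denominator[chosen],
                      threshold = 2 ^ thr_log[chosen],
                      stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  structure(panel, class = c("ratio_panel", "data.frame"),
            case_label = case_label, control_label = control_label)
}

#' @export
print.ratio_panel <- function(x, ...) {
  cat(sprintf("ratio_panel: %d ratios (%s vs %s)\n", nrow(x),
              paste(attr(x, "case_label"), collapse = "+"),
              paste(attr(x, "control_label"), collapse = "+")))
  if (nrow(x) > 0L) print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Score subjects against a ratio panel
#'
#' For each subject, indicator i is 1 when the subject's value of panel
#' ratio i strictly exceeds that ratio's threshold (the training-control
#' maximum).  The ratioscore is the count of 1s in the indicator n-tuple;
#' a subject is called positive when the ratioscore is at least 1.  Strict
#' exceedance guarantees every training control scores 0.  Subjects with a
#' missing level for a panel probe get indicator 0 for the affected ratios
#' (a well that did not amplify cannot witness over-expression).
#'
#' @param panel A `ratio_panel`.
#' @param expr An `expression_matrix` containing every panel probe.
#' @param subjects Subject ids to score (default: all).
#' @return Data frame of class `score_result`: `subject_id`, `group`,
#'   `tuple` (the indicator n-tuple as a 0/1 string), `ratioscore`,
#'   `call` in {positive, negative}.  Attribute `indicators` holds the
#'   subjects x ratios 0/1 matrix.
#' @export
score_subjects <- function(panel, expr, subjects = NULL) {
  stopifnot(inherits(panel, "ratio_panel"), inherits(expr, "expression_matrix"))
  subjects <- subjects %||% rownames(expr$levels)
  missing_subj <- setdiff(subjects, rownames(expr$levels))
  if (length(missing_subj) > 0L)
    stop_("unknown subject(s): %s", paste(missing_subj, collapse = ", "))
  probes <- unique(c(panel$numerator, panel$denominator))
  miss <- setdiff(probes, colnames(expr$levels))
  if (length(miss) > 0L)
    stop_("panel probe(s) %s absent from expression matrix (subjects %s...)",
          paste(miss, collapse = ", "), subjects[1L])
  # ratio values via the same arithmetic path used to fit the thresholds
  # (log2 subtraction, then 2^): guarantees the maximal training control
  # compares equal, never strictly greater, to its own threshold
  L <- log2(expr$levels[subjects, , drop = FALSE])
  vals <- 2 ^ (L[, panel$numerator, drop = FALSE] -
                 L[, panel$denominator, drop = FALSE])
  ind <- vals > rep(panel$threshold, each = length(subjects))
  ind[is.na(ind)] <- FALSE
  mode(ind) <- "integer"
  if (nrow(panel) == 0L) ind <- matrix(0L, length(subjects), 0L)
  score <- as.integer(rowSums(ind))
  out <- data.frame(subject_id = subjects,
                    group = unname(expr$groups[subjects]),
                    tuple = apply(ind, 1L, paste, collapse = ""),
                    ratioscore = score,
                    call = ifelse(score >= 1L, "positive", "negative"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  dimnames(ind) <- list(subjects, paste(panel$numerator, panel$denominator,
                                        sep = "/"))
  structure(out, class = c("score_result", "data.frame"), indicators = ind)
}

#' Fraction of subjects called positive
#'
#' Panel coverage: the fraction of (case) subjects with ratioscore >= 1.
#' The larger the coverage, the better the panel separates cases from
#' controls.
#'
#' @param scores A `score_result` frame.
#' @param group_label Optional: restrict to subjects of these group(s).
#' @return Fraction in [0, 1].
#' @export
coverage <- function(scores, group_label = NULL) {
  stopifnot(inherits(scores, "data.frame"))
  if (!is.null(group_label)) scores <- scores[scores$group %in% group_label, ]
  if (nrow(scores) == 0L) stop_("no subjects to compute coverage over")
  mean(scores$ratioscore >= 1L)
}

#' One-call ratioscore training pipeline
#'
#' Runs the resampled candidate search, greedy panel assembly, and scoring
#' of the training data in one step.
#'
#' @inheritParams search_candidates
#' @param max_size Optional cap on panel size.
#' @return List with `candidates`, `panel`, `scores` (all training
#'   subjects of the two groups), `case_coverage`, and
#'   `control_specificity` (fraction of training controls scoring 0;
#'   equals 1 by construction).
#' @export
fit_ratioscore <- function(expr, case_label, control_label,
                           resample_frac = 0.80, reps = 200L, top_k = 500L,
                           seed, max_size = Inf) {
  cand <- search_candidates(expr, case_label, control_label,
                            resample_frac = resample_frac, reps = reps,
                            top_k = top_k, seed = seed)
  panel <- select_panel(cand, expr, case_label, control_label,
                        max_size = max_size)
  subj <- rownames(expr$levels)[group_rows(expr, c(case_label, control_label))]
  scores <- score_subjects(panel, expr, subjects = subj)
  ctrl <- scores[scores$group %in% control_label, ]
  list(candidates = cand, panel = panel, scores = scores,
       case_coverage = coverage(scores, case_label),
       control_specificity = mean(ctrl$ratioscore == 0L))
}

#' Serialize a ratio panel to JSON
#'
#' @param panel A `ratio_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ratio_panel"))
  obj <- list(case_label = attr(panel, "case_label"),
              control_label = attr(panel, "control_label"),
              ratios = lapply(seq_len(nrow(panel)), function(i) {
                list(numerator = panel$numerator[i],
                     denominator = panel$denominator[i],
                     threshold = panel$threshold[i])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(panel)
}

#' Read a ratio panel from JSON
#'
#' @param path Path written by [write_panel].
#' @return A `ratio_panel`.
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ratios <- obj$ratios
  panel <- data.frame(
    numerator = vapply(ratios, `[[`, character(1), "numerator"),
    denominator = vapply(ratios, `[[`, character(1), "denominator"),
    threshold = vapply(ratios, `[[`, numeric(1), "threshold"),
    stringsAsFactors = FALSE)
  structure(panel, class = c("ratio_panel", "data.frame"),
            case_label = unlist(obj$case_label),
            control_label = unlist(obj$control_label))
}

#' Write scoring results as TSV
#'
#' @param scores A `score_result`.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(scores)
}
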