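#' Construct a CT table
#'
#' Container for raw qPCR threshold-cycle measurements: a subjects x probes
#' matrix of CT values plus a group label per subject.  Lower CT means more
#' transcript.  CT values must lie in (0, 40]; 40 is the detection ceiling
#' and missing values (undetected wells) are allowed as `NA`.
#'
#' @param ct Numeric matrix, rows = subjects (rownames = subject ids),
#'   columns = probes (colnames = probe ids).
#' @param groups Character vector of group labels, one per subject, in
#'   {CTRL, IBS, CD, UC, CeD}.  May be named by subject id.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, groups) {
  if (!is.matrix(ct) || !is.numeric(ct)) stop_("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop_("`ct` needs subject ids as rownames and probe ids as colnames")
  if (anyDuplicated(rownames(ct)))
    stop_("duplicate subject id(s): %s",
          paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop_("duplicate probe id(s): %s",
          paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  if (length(groups) != nrow(ct))
    stop_("got %d group labels for %d subjects", length(groups), nrow(ct))
  if (!is.null(names(groups))) {
    missing_subj <- setdiff(rownames(ct), names(groups))
    if (length(missing_subj) > 0L)
      stop_("no group label for subject(s): %s", paste(missing_subj, collapse = ", "))
    groups <- groups[rownames(ct)]
  }
  groups <- as.character(groups)
  check_groups(groups)
  finite <- ct[is.finite(ct)]
  if (any(finite <= 0 | finite > 40))
    stop_("CT values must lie in (0, 40]; found values outside this range")
  names(groups) <- rownames(ct)
  structure(list(ct = ct, groups = groups), class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d subjects x %d probes\n", nrow(x$ct), ncol(x$ct)))
  print(table(x$groups))
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

parse_ct_field <- function(v, what) {
  raw <- trimws(as.character(v))
  raw[raw == "" | toupper(raw) == "UNDETERMINED" | toupper(raw) == "NA"] <- NA
  out <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & is.na(out)
  if (any(bad))
    stop_("non-numeric %s value(s): %s", what,
          paste(unique(raw[bad]), collapse = ", "))
  out
}

#' Read a CT table from TSV files
#'
#' The CT file is tab-separated with a header row, first column
#' `subject_id`, remaining columns one per probe.  Missing CT values are
#' encoded as an empty field or `Undetermined`.  The metadata file has
#' columns `subject_id` and `group` and must list exactly the subjects of
#' the CT file.
#'
#' @param path Path to the CT TSV.
#' @param metadata_path Path to the subject metadata TSV.
#' @return A [ct_table].
#' @export
read_ct_table <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop_("CT table needs a subject_id column plus probes")
  subj <- tab[[1L]]
  ct <- vapply(tab[-1L], parse_ct_field, numeric(nrow(tab)), what = "CT")
  ct <- matrix(ct, nrow = nrow(tab),
               dimnames = list(subj, colnames(tab)[-1L]))
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            colClasses = "character")
  if (!all(c("subject_id", "group") %in% colnames(meta)))
    stop_("metadata must have columns subject_id and group")
  extra <- setdiff(meta$subject_id, subj)
  if (length(extra) > 0L)
    stop_("metadata subject(s) missing from CT table: %s",
          paste(extra, collapse = ", "))
  missing_meta <- setdiff(subj, meta$subject_id)
  if (length(missing_meta) > 0L)
    stop_("CT table subject(s) missing from metadata: %s",
          paste(missing_meta, collapse = ", "))
  groups <- stats::setNames(meta$group, meta$subject_id)
  ct_table(ct, groups)
}

#' Write a CT table to TSV files
#'
#' @param x A [ct_table].
#' @param path Output path for the CT TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_ct_table <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "ct_table"))
  ctc <- apply(x$ct, c(1L, 2L), function(v)
    if (is.na(v)) "" else format(v, digits = 15))
  df <- data.frame(subject_id = rownames(x$ct), ctc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(subject_id = rownames(x$ct), group = unname(x$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Convert raw CT values to reference-normalized relative expression
#'
#' Relative expression of a target probe in a subject is
#' `2^(CT_reference - CT_target)`: one cycle less than the reference means
#' twice its transcript level.  The reference probe (GAPDH by default) is
#' removed from the output.  Missing target CTs propagate as `NA`; a
#' missing reference CT is an error because every level of that subject
#' would be undefined.
#'
#' @param x A [ct_table].
#' @param reference_probe Probe used as normalizer.
#' @return An object of class `expression_matrix` with fields `levels`
#'   (subjects x probes, strictly positive where observed) and `groups`.
#' @export
ct_to_relative <- function(x, reference_probe = "GAPDH") {
  stopifnot(inherits(x, "ct_table"))
  if (!reference_probe %in% colnames(x$ct))
    stop_("reference probe %s not in table", sQuote(reference_probe))
  ref <- x$ct[, reference_probe]
  if (anyNA(ref))
    stop_("missing reference (%s) CT for subject(s): %s", reference_probe,
          paste(rownames(x$ct)[is.na(ref)], collapse = ", "))
  targets <- setdiff(colnames(x$ct), reference_probe)
  levels <- 2 ^ (ref - x$ct[, targets, drop = FALSE])
  structure(list(levels = levels, groups = x$groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d subjects x %d probes\n",
              nrow(x$levels), ncol(x$levels)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$levels)

check_probes <- function(expr, probes) {
  missing <- setdiff(probes, colnames(expr$levels))
  if (length(missing) > 0L)
    stop_("probe(s) not in expression matrix: %s",
          paste(missing, collapse = ", "))
  invisible(probes)
}

#' Two-gene expression ratio for one or more subjects
#'
#' Ratio of relative expression levels `numerator/denominator`.  Because
#' both levels share the same reference normalization, the reference
#' cancels: the ratio equals `2^(CT_denominator - CT_numerator)`.
#'
#' @param expr An `expression_matrix`.
#' @param numerator_probe,denominator_probe Probe ids.
#' @param subjects Subject ids (default: all).
#' @return Named numeric vector of ratio values.
#' @export
ratio_value <- function(expr, numerator_probe, denominator_probe,
                        subjects = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  check_probes(expr, c(numerator_probe, denominator_probe))
  subjects <- subjects %||% rownames(expr$levels)
  den <- expr$levels[subjects, denominator_probe]
  if (anyNA(den) || any(den <= 0, na.rm = TRUE))
    stop_("denominator probe %s missing or nonpositive for subject(s): %s",
          sQuote(denominator_probe),
          paste(subjects[is.na(den) | den <= 0], collapse = ", "))
  expr$levels[subjects, numerator_probe] / den
}

# Subject row indices whose group is in `labels` (labels may be a vector,
# e.g. c("CD","UC") for the IBD union).
group_rows <- function(expr, labels) {
  check_groups(labels)
  which(expr$groups %in% labels)
}
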