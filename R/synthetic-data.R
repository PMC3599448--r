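#' Specify a planted expression effect
#'
#' One disease effect on one probe: a multiplicative fold change on the
#' relative-expression scale, carried by a random subset of case subjects.
#' Penetrance below 1 models cohort heterogeneity — different subjects with
#' the same disease may carry defects in different genes, so no single gene
#' separates every case.
#'
#' @param probe_id Probe the effect acts on.  Duplicate probes of one gene
#'   (e.g. TP53-1/TP53-2) share the underlying transcript, so an effect on
#'   either co-shifts both.
#' @param direction `"up"` (over-expression, lower CT) or `"down"`.
#' @param fold_change Multiplicative effect, > 1.
#' @param penetrance Probability a given case subject carries the effect.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(probe_id, direction = c("up", "down"),
                        fold_change, penetrance = 1) {
  direction <- match.arg(direction)
  if (!is.numeric(fold_change) || length(fold_change) != 1L || fold_change <= 1)
    stop_("fold_change must be a single number > 1")
  if (!is.numeric(penetrance) || penetrance < 0 || penetrance > 1)
    stop_("penetrance must lie in [0, 1]")
  structure(list(probe_id = probe_id, direction = direction,
                 fold_change = fold_change, penetrance = penetrance),
            class = "effect_spec")
}

#' Specify one synthetic cohort
#'
#' @param group_label One of CTRL, IBS, CD, UC, CeD.
#' @param n_subjects Number of subjects (>= 1).
#' @param effects List of [effect_spec]s (empty for CTRL-like cohorts).
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(group_label, n_subjects, effects = list()) {
  check_groups(group_label)
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_("n_subjects must be >= 1")
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  probes <- vapply(effects, `[[`, character(1), "probe_id")
  if (anyDuplicated(probes))
    stop_("duplicate effect probe(s) in cohort %s: %s", group_label,
          paste(unique(probes[duplicated(probes)]), collapse = ", "))
  structure(list(group_label = group_label,
                 n_subjects = as.integer(n_subjects), effects = effects),
            class = "cohort_spec")
}

#' Configure the synthetic qPCR cohort generator
#'
#' @param cohorts List of [cohort_spec]s.
#' @param seed Integer seed; required — generation is deterministic.
#' @param panel Probe identifiers (default: the 47-probe TLDA panel).
#' @param reference_probe Normalizer probe, must be in `panel`.
#' @param baseline_ct_mean Named numeric vector of per-probe baseline CT
#'   means (cycles, in (0, 40]).  Default: an even spread over 22-31
#'   cycles, a realistic range for moderately expressed blood transcripts.
#' @param ct_noise_sd Gaussian replicate noise on the CT (log2) scale,
#'   cycles.  Default 0.35, typical qPCR replicate scatter.
#' @param reference_ct_mean Mean CT of the reference probe (default 19,
#'   GAPDH is abundant).
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(cohorts, seed, panel = tlda_probes(),
                             reference_probe = "GAPDH",
                             baseline_ct_mean = NULL,
                             ct_noise_sd = 0.35,
                             reference_ct_mean = 19) {
  if (missing(seed) || is.null(seed)) stop_("seed is required")
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  if (!reference_probe %in% panel)
    stop_("reference_probe %s not in panel", sQuote(reference_probe))
  targets <- setdiff(panel, reference_probe)
  if (is.null(baseline_ct_mean)) {
    baseline_ct_mean <- stats::setNames(
      seq(22, 31, length.out = length(targets)), targets)
  }
  missing_bl <- setdiff(targets, names(baseline_ct_mean))
  if (length(missing_bl) > 0L)
    stop_("no baseline_ct_mean for probe(s): %s",
          paste(missing_bl, collapse = ", "))
  if (ct_noise_sd < 0) stop_("ct_noise_sd must be >= 0")
  all_ct <- c(baseline_ct_mean[targets], reference_ct_mean)
  if (any(all_ct <= 0 | all_ct > 40)) stop_("CT means must lie in (0, 40]")
  for (co in cohorts) {
    stopifnot(inherits(co, "cohort_spec"))
    for (ef in co$effects) {
      if (!ef$probe_id %in% panel)
        stop_("effect probe %s is not in the panel", sQuote(ef$probe_id))
    }
  }
  structure(list(panel = panel, reference_probe = reference_probe,
                 baseline_ct_mean = baseline_ct_mean[targets],
                 ct_noise_sd = ct_noise_sd,
                 reference_ct_mean = reference_ct_mean,
                 cohorts = cohorts, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic case/control CT table
#'
#' For every subject, each probe's CT is drawn as
#' `baseline - log2(applied fold) + N(0, ct_noise_sd)`: an up effect of
#' fold f lowers CT by log2(f) (more transcript, earlier amplification), a
#' down effect raises it.  Each effect is carried independently per subject
#' with probability `penetrance`, and acts at the gene level, so duplicate
#' probes of one gene co-shift while keeping independent measurement noise.
#' CT values are clipped at the detection ceiling of 40 cycles; the number
#' of clipped wells is recorded in the `n_censored` attribute.
#'
#' @param config A [synthetic_config].
#' @return A [ct_table] carrying group labels; attribute `effects_carried`
#'   is a logical subjects x effects matrix of ground-truth carrier status.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  targets <- names(config$baseline_ct_mean)
  target_genes <- probe_gene(targets)
  with_seed(config$seed, {
    per_label_counter <- integer(0)
    rows <- list(); groups <- character(0)
    carried_all <- list()
    for (co in config$cohorts) {
      lab <- co$group_label
      start <- if (lab %in% names(per_label_counter))
        per_label_counter[[lab]] else 0L
      per_label_counter[lab] <- start + co$n_subjects
      ids <- sprintf("%s_%03d", lab, start + seq_len(co$n_subjects))
      n <- co$n_subjects
      shift <- matrix(0, n, length(targets),
                      dimnames = list(ids, targets))
      for (ef in co$effects) {
        carrier <- stats::runif(n) < ef$penetrance
        delta <- log2(ef$fold_change) * if (ef$direction == "up") -1 else 1
        cols <- which(target_genes == probe_gene(ef$probe_id))
        shift[carrier, cols] <- shift[carrier, cols] + delta
        carried_all[[paste(lab, ef$probe_id, sep = ":")]] <-
          stats::setNames(carrier, ids)
      }
      noise <- matrix(stats::rnorm(n * length(targets), 0, config$ct_noise_sd),
                      n, length(targets))
      ct <- matrix(config$baseline_ct_mean, n, length(targets),
                   byrow = TRUE) + shift + noise
      ref <- config$reference_ct_mean +
        stats::rnorm(n, 0, config$ct_noise_sd)
      ct <- cbind(ct, ref)
      dimnames(ct) <- list(ids, c(targets, config$reference_probe))
      rows[[length(rows) + 1L]] <- ct
      groups <- c(groups, rep(lab, n))
    }
    ct <- do.call(rbind, rows)[, config$panel, drop = FALSE]
    n_censored <- sum(ct > 40)
    ct[ct > 40] <- 40
    ct[ct <= 0] <- 0.01
    out <- ct_table(ct, stats::setNames(groups, rownames(ct)))
    attr(out, "n_censored") <- n_censored
    attr(out, "effects_carried") <- carried_all
    out
  })
}

# Figure-1-patterned planted effects (folds fixed once: canonical strong
# markers PGK1/ASL at fold 4, most others 3, SPIB/RANGAP1/ACTR1A at the
# weak end to span the 2-4 range).  Penetrance 0.5 throughout: cohort
# heterogeneity, no single gene marks every case.
paperlike_effects <- function() {
  up <- function(p, f) effect_spec(p, "up", f, 0.5)
  dn <- function(p, f) effect_spec(p, "down", f, 0.5)
  list(
    IBS = list(up("PGK1", 4), up("ABR", 3), up("ACTR1A", 2), up("EXT2", 3),
               up("HRAS", 4), up("KRAS", 3)),
    CD  = list(up("PGK1", 4), dn("APOBEC3F", 3), dn("ASL", 4), dn("SPIB", 2),
               dn("ANAPC1", 3), dn("RANGAP1", 2), dn("TP53-1", 3)),
    UC  = list(up("PGK1", 4), dn("APOBEC3F", 3), dn("ASL", 4), dn("SPIB", 2))
  )
}

#' Built-in synthetic fixtures
#'
#' `"tiny"` is a hand-auditable 6-probe, 8-subject table with exact
#' rational CT values, used by oracle tests.  `"paperlike"` is a full
#' 47-probe cohort with sizes CTRL 113, CD 46, UC 40, IBS 44 and planted
#' disease patterns: PGK1 over-expressed in every disease; ABR, ACTR1A,
#' EXT2, HRAS, KRAS over-expressed in IBS only; APOBEC3F, ASL, SPIB
#' under-expressed in CD and UC; ANAPC1, RANGAP1, TP53 under-expressed in
#' CD only.  All planted folds are 2-4x at penetrance 0.5 with 0.35-cycle
#' CT noise.
#'
#' @param kind `"tiny"` or `"paperlike"`.
#' @param seed Seed for the paperlike fixture (ignored for tiny, which is
#'   deterministic by construction).
#' @return A [ct_table].
#' @export
make_fixture <- function(kind = c("tiny", "paperlike"), seed = 20121121L) {
  kind <- match.arg(kind)
  if (kind == "tiny") {
    probes <- c("GAPDH", "PGK1", "POU6F1", "ANAPC1", "HRAS", "TBP")
    ct <- rbind(
      c(20, 24, 26, 25, 27, 26),    # CTRL_001
      c(20, 24.5, 26, 25, 27.5, 26),# CTRL_002
      c(19, 23, 25, 24, 26, 25),    # CTRL_003
      c(21, 25.5, 27, 26, 28, 27),  # CTRL_004
      c(20, 21, 27, 27, 26, 26),    # CD_001  PGK1 up, ANAPC1 down
      c(20, 21.5, 26.5, 27.5, 27, 26), # CD_002
      c(19, 20, 26, 26, 25, 25),    # CD_003
      c(21, 22, 28, 28, 27, 27))    # CD_004
    dimnames(ct) <- list(c(paste0("CTRL_00", 1:4), paste0("CD_00", 1:4)),
                         probes)
    return(ct_table(ct, rep(c("CTRL", "CD"), each = 4L)))
  }
  eff <- paperlike_effects()
  cfg <- synthetic_config(
    cohorts = list(cohort_spec("CTRL", 113L),
                   cohort_spec("CD", 46L, eff$CD),
                   cohort_spec("UC", 40L, eff$UC),
                   cohort_spec("IBS", 44L, eff$IBS)),
    seed = seed)
  generate_cohorts(cfg)
}

#' Shuffle group labels (null-calibration utility)
#'
#' Random permutation of the subject-to-group assignment, preserving group
#' sizes.  Used to build empirical null distributions; the permutation
#' significance machinery of the original ratioscore work is otherwise out
#' of scope.
#'
#' @param x A [ct_table] or `expression_matrix`.
#' @param seed Integer seed.
#' @return Object of the same class with permuted labels.
#' @export
permute_labels <- function(x, seed) {
  with_seed(seed, {
    perm <- sample(length(x$groups))
    x$groups <- stats::setNames(unname(x$groups)[perm], names(x$groups))
    x
  })
}
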