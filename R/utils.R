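#' @keywords internal
"_PACKAGE"

# Allowed subject group labels (control plus the four disease cohorts).
GI_GROUP_LABELS <- c("CTRL", "IBS", "CD", "UC", "CeD")

#' Probe identifiers of the 47-probe TaqMan low-density array panel
#'
#' The panel interrogates 44 target genes plus housekeeping probes; GNB5 and
#' TP53 are each measured by two probes targeting different exon-intron
#' junctions (`GNB5-1`/`GNB5-2`, `TP53-1`/`TP53-2`).  GAPDH is the
#' normalizer used throughout.
#'
#' @return Character vector of 47 probe identifiers.
#' @export
tlda_probes <- function() {
  c("ABR", "ACTB", "ACTR1A", "ADAMTSL4", "ANAPC1", "APOBEC3F", "ASL",
    "B2M", "BRCA1", "CD55", "CDH1", "CDKN1B", "CHEK2", "CSF3R", "CTSS",
    "EPHX2", "EXT2", "FOS", "FOSL1", "GAPDH", "GATA3", "GNB5-1", "GNB5-2",
    "GSTM4", "HLA-DRA", "HRAS", "IFI27", "IL11RA", "JUN", "KRAS",
    "LEPREL4", "LLGL2", "NRAS", "OAS1", "ORC1L", "PGK1", "PMAIP1",
    "POU6F1", "RANGAP1", "SC65", "SPIB", "TAF11", "TBP", "TGFBR2",
    "TP53-1", "TP53-2", "TXK")
}

# Map probe identifiers to their underlying gene: duplicate probes such as
# GNB5-1/GNB5-2 read the same transcript, so they share one biological
# signal (the synthetic generator co-shifts them).
probe_gene <- function(probe_ids) sub("-[0-9]+$", "", probe_ids)

# Column maxima ignoring nothing; input has no NA in the paths that use it.
col_max <- function(m) {
  if (nrow(m) == 1L) return(m[1L, ])
  apply(m, 2L, max)
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) trunc(x + 0.5 * sign(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_groups <- function(groups) {
  bad <- setdiff(unique(groups), GI_GROUP_LABELS)
  if (length(bad) > 0L) {
    stop_("unknown group label(s) %s; allowed labels are: %s",
          paste(sQuote(bad), collapse = ", "),
          paste(GI_GROUP_LABELS, collapse = ", "))
  }
  invisible(groups)
}

# Evaluate `expr` under a seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) {
    stop_("a seed is required (no silent nondeterminism)")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stratified sample of row indices: `frac` of each label class, >= 1 each.
stratified_sample <- function(labels, frac) {
  idx <- seq_along(labels)
  unlist(lapply(split(idx, labels), function(i) {
    sample(i, max(1L, ceiling(frac * length(i))))
  }), use.names = FALSE)
}
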