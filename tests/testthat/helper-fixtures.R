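# Fixture builders shared across the suite.  Everything is generated in
# code; nothing is read from disk.

tiny_expr <- function() ct_to_relative(make_fixture("tiny"))

# Expression matrix with prescribed relative levels: encode levels as CT
# values around a GAPDH reference of 20 cycles, then normalize back.
expr_from_levels <- function(levels, groups) {
  ct <- cbind(GAPDH = rep(20, nrow(levels)), 20 - log2(levels))
  rownames(ct) <- rownames(levels)
  ct_to_relative(ct_table(ct, groups))
}

# Small synthetic cohort on a compact probe panel.
small_panel <- function(k = 6L) c("GAPDH", paste0("G", seq_len(k)))

small_cohort <- function(n_ctrl, n_case, effects = list(), seed,
                         ct_noise_sd = 0.35, case_label = "CD",
                         panel = small_panel()) {
  cfg <- synthetic_config(
    cohorts = list(cohort_spec("CTRL", n_ctrl),
                   cohort_spec(case_label, n_case, effects)),
    seed = seed, panel = panel, ct_noise_sd = ct_noise_sd)
  generate_cohorts(cfg)
}

# Row subset of an expression matrix (keeps class and groups aligned).
subset_expr <- function(expr, rows) {
  expr$levels <- expr$levels[rows, , drop = FALSE]
  expr$groups <- expr$groups[rows]
  expr
}

# A hand-buildable ratio panel (bypasses search) for scoring tests.
manual_panel <- function(numerator, denominator, threshold,
                         case_label = "CD", control_label = "CTRL") {
  structure(data.frame(numerator = numerator, denominator = denominator,
                       threshold = threshold, stringsAsFactors = FALSE),
            class = c("ratio_panel", "data.frame"),
            case_label = case_label, control_label = control_label)
}

small_grid <- function() list(width_or_degree = 2 ^ c(-2, 0, 2),
                              soft_margin_C = 2 ^ c(-2, 0, 2))

# Two well-separated Gaussian blobs for classifier sanity checks.
blob_data <- function(n_per = 20L, sep = 6, d = 2L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  rownames(x) <- sprintf("S%03d", seq_len(2L * n_per))
  colnames(x) <- paste0("F", seq_len(d))
  list(x = x, labels = rep(c("A", "B"), each = n_per))
}
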