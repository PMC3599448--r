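#' Build the ratio feature matrix for kernel classification
#'
#' The classifiers consume exactly the ratios of a fitted panel: column j
#' is the log2 of panel ratio j's value (log2 because kernel machines work
#' best with symmetric, roughly Gaussian features; the ratio scale spans
#' orders of magnitude).
#'
#' @param expr An `expression_matrix`.
#' @param panel A `ratio_panel` (thresholds are ignored; only the probe
#'   pairs matter).
#' @param subjects Subject ids (default all).
#' @return Numeric matrix, subjects x ratios, colnames `num/den`.
#' @export
build_features <- function(expr, panel, subjects = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(panel) == 0L) stop_("panel is empty")
  check_probes(expr, unique(c(panel$numerator, panel$denominator)))
  subjects <- subjects %||% rownames(expr$levels)
  L <- log2(expr$levels[subjects, , drop = FALSE])
  f <- L[, panel$numerator, drop = FALSE] - L[, panel$denominator, drop = FALSE]
  dimnames(f) <- list(subjects,
                      paste(panel$numerator, panel$denominator, sep = "/"))
  f
}

#' Training configuration for the kernel classifier protocols
#'
#' @param protocol `"subset_grid"` (random training subsets, parameters
#'   chosen to minimize misclassifications over the full data) or
#'   `"cv_holdout"` (one training split, parameters tuned by L-fold
#'   cross-validation inside it, then evaluated on total/training/
#'   validation sets).
#' @param train_fraction Fraction of subjects in each training subset
#'   (0.5, 0.6 or 0.8 in the original protocols; default 0.6).
#' @param n_folds Folds for cross-validation tuning (default 10).
#' @param n_random_subsets Random subsets for `subset_grid` (default 50).
#' @param family Kernel family, `"radial_basis"` or `"polynomial"`.
#' @param grid Candidate parameter grid, as from [default_grid()].
#' @param seed Integer seed (required; both protocols are deterministic
#'   given data + config + seed).
#' @return A `train_config`.
#' @export
train_config <- function(protocol = c("subset_grid", "cv_holdout"),
                         train_fraction = 0.6, n_folds = 10L,
                         n_random_subsets = 50L,
                         family = c("radial_basis", "polynomial"),
                         grid = NULL, seed) {
  protocol <- match.arg(protocol)
  family <- match.arg(family)
  if (missing(seed)) stop_("a seed is required")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_("train_fraction must lie in (0, 1)")
  if (n_folds < 2L) stop_("n_folds must be >= 2")
  grid <- grid %||% default_grid(family)
  if (length(grid$width_or_degree) == 0L || length(grid$soft_margin_C) == 0L)
    stop_("parameter grid is empty")
  structure(list(protocol = protocol, train_fraction = train_fraction,
                 n_folds = as.integer(n_folds),
                 n_random_subsets = as.integer(n_random_subsets),
                 family = family, grid = grid, seed = as.integer(seed)),
            class = "train_config")
}

as_pm1 <- function(labels, positive_label) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop_("binary classification needs exactly 2 labels, got: %s",
          paste(lev, collapse = ", "))
  if (is.null(positive_label)) positive_label <- sort(lev)[1L]
  if (!positive_label %in% lev)
    stop_("positive_label %s not among labels", sQuote(positive_label))
  ifelse(labels == positive_label, 1, -1)
}

make_classifier <- function(model, positive_label, negative_label,
                            feature_names, protocol, train_idx, panel,
                            tuning) {
  structure(list(model = model, positive_label = positive_label,
                 negative_label = negative_label,
                 feature_names = feature_names, protocol = protocol,
                 train_idx = train_idx, panel = panel, tuning = tuning),
            class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat(sprintf(
    "fitted_classifier (%s): %s vs %s, %d features, kernel %s (w=%g, C=%g)\n",
    x$protocol, x$positive_label, x$negative_label,
    length(x$feature_names), x$model$kernel$family,
    x$model$kernel$width_or_degree, x$model$kernel$soft_margin_C))
  invisible(x)
}

#' Real-valued decision scores of a fitted classifier
#'
#' Positive scores favour the classifier's positive label; usable directly
#' for ROC analysis.
#'
#' @param object A `fitted_classifier`.
#' @param features Feature matrix with the training columns.
#' @return Numeric vector.
#' @export
decision_scores <- function(object, features) {
  stopifnot(inherits(object, "fitted_classifier"))
  if (!identical(colnames(features), object$feature_names))
    features <- features[, object$feature_names, drop = FALSE]
  lssvm_decision(object$model, features)
}

#' @export
predict.fitted_classifier <- function(object, features, ...) {
  s <- decision_scores(object, features)
  stats::setNames(ifelse(s > 0, object$positive_label,
                         object$negative_label), rownames(features))
}

# Fit/predict over a full parameter grid with shared precomputation.
# Returns, for each grid point (width outer, C inner), the decision values
# on `x_eval` rows; used by both protocols.
grid_decisions <- function(x_train, y, x_eval, family, grid) {
  center <- colMeans(x_train)
  scale_ <- apply(x_train, 2L, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xt <- sweep(sweep(x_train, 2L, center), 2L, scale_, `/`)
  xe <- sweep(sweep(x_eval, 2L, center), 2L, scale_, `/`)
  pre_tt <- if (family == "radial_basis") sqdist(xt, xt) else 1 + tcrossprod(xt)
  pre_et <- if (family == "radial_basis") sqdist(xe, xt) else
    1 + tcrossprod(xe, xt)
  out <- vector("list", length(grid$width_or_degree) *
                  length(grid$soft_margin_C))
  i <- 0L
  for (w in grid$width_or_degree) {
    for (C in grid$soft_margin_C) {
      spec <- kernel_spec(family, w, C)
      sol <- lssvm_solve(spec, y, pre_tt)
      K_et <- kernel_gram(spec, precomp = pre_et)
      i <- i + 1L
      out[[i]] <- list(width_or_degree = w, soft_margin_C = C,
                       scores = drop(K_et %*% (sol$alpha * y) + sol$b))
    }
  }
  out
}

#' Protocol #1: random-subset grid search
#'
#' Repeatedly draws stratified random training subsets of
#' `train_fraction` of each group, fits the soft-margin kernel classifier
#' at every grid point, and counts misclassifications over the full
#' dataset.  The (subset, parameter) combination with the fewest total
#' errors defines the returned machine.  Deterministic given the seed.
#'
#' @param features Subjects x ratios matrix from [build_features()].
#' @param labels Binary label vector (one per row of `features`).
#' @param config A [train_config()] with `protocol = "subset_grid"`.
#' @param positive_label Label treated as the case class (default: first
#'   alphabetically).
#' @param panel Optional `ratio_panel` stored with the model so the
#'   classifier can be applied straight to an expression matrix.
#' @return A `fitted_classifier`.
#' @export
train_subset_grid <- function(features, labels, config,
                              positive_label = NULL, panel = NULL) {
  stopifnot(inherits(config, "train_config"))
  y <- as_pm1(labels, positive_label)
  pos <- unique(as.character(labels)[y == 1])
  neg <- unique(as.character(labels)[y == -1])
  best <- list(errors = Inf)
  with_seed(config$seed, {
    for (s in seq_len(config$n_random_subsets)) {
      idx <- sort(stratified_sample(labels, config$train_fraction))
      fits <- grid_decisions(features[idx, , drop = FALSE], y[idx],
                             features, config$family, config$grid)
      for (f in fits) {
        errors <- sum(sign(f$scores) != y)
        if (errors < best$errors) {
          best <- list(errors = errors, idx = idx,
                       width_or_degree = f$width_or_degree,
                       soft_margin_C = f$soft_margin_C)
        }
      }
    }
  })
  spec <- kernel_spec(config$family, best$width_or_degree,
                      best$soft_margin_C)
  model <- lssvm_fit(features[best$idx, , drop = FALSE], y[best$idx], spec)
  make_classifier(model, pos, neg, colnames(features), "subset_grid",
                  best$idx, panel,
                  tuning = list(total_errors = best$errors))
}

# Stratified fold assignment; guarantees every fold complement keeps both
# classes (n_folds <= smallest class size would be needed for both classes
# in every *fold*; complements are what training uses).
make_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in split(seq_along(labels), labels)) {
    fold[sample(cl)] <- rep_len(seq_len(n_folds), length(cl))
  }
  fold
}

#' Protocol #2: holdout training with cross-validated tuning
#'
#' Selects a stratified `train_fraction` of the data; tunes the kernel
#' parameters by `n_folds`-fold cross-validation within that training set;
#' refits on the whole training set; and tabulates correct (Tc) and
#' incorrect (Ti) calls separately for the total, training and validation
#' sets, with `%I = round(100 * Ti / TOTAL)` (half away from zero).
#'
#' @inheritParams train_subset_grid
#' @return List with `classifier` (a `fitted_classifier`), `report` (the
#'   Tc/Ti/TOTAL/%I table, one row per set), and `train_idx`.
#' @export
train_cv_holdout <- function(features, labels, config,
                             positive_label = NULL, panel = NULL) {
  stopifnot(inherits(config, "train_config"))
  y <- as_pm1(labels, positive_label)
  pos <- unique(as.character(labels)[y == 1])
  neg <- unique(as.character(labels)[y == -1])
  n <- nrow(features)
  res <- with_seed(config$seed, {
    train_idx <- sort(stratified_sample(labels, config$train_fraction))
    ytr <- y[train_idx]
    xtr <- features[train_idx, , drop = FALSE]
    fold <- make_folds(ytr, config$n_folds)
    while (any(vapply(seq_len(config$n_folds), function(k)
      length(unique(ytr[fold != k])) < 2L, logical(1)))) {
      fold <- make_folds(ytr, config$n_folds)  # re-stratify degenerate split
    }
    n_grid <- length(config$grid$width_or_degree) *
      length(config$grid$soft_margin_C)
    cv_err <- numeric(n_grid)
    for (k in seq_len(config$n_folds)) {
      hold <- which(fold == k)
      if (length(hold) == 0L) next
      fits <- grid_decisions(xtr[-hold, , drop = FALSE], ytr[-hold],
                             xtr[hold, , drop = FALSE], config$family,
                             config$grid)
      cv_err <- cv_err + vapply(fits, function(f)
        sum(sign(f$scores) != ytr[hold]), numeric(1))
    }
    best <- which.min(cv_err)  # first grid point on ties
    list(train_idx = train_idx, best = best, cv_err = cv_err)
  })
  grid_pts <- expand.grid(C = config$grid$soft_margin_C,
                          w = config$grid$width_or_degree)[, c("w", "C")]
  spec <- kernel_spec(config$family, grid_pts$w[res$best],
                      grid_pts$C[res$best])
  model <- lssvm_fit(features[res$train_idx, , drop = FALSE],
                     y[res$train_idx], spec)
  clf <- make_classifier(model, pos, neg, colnames(features), "cv_holdout",
                         res$train_idx, panel,
                         tuning = list(cv_errors = res$cv_err[res$best]))
  scores <- lssvm_decision(model, features)
  correct <- sign(scores) == y
  blocks <- list(total = seq_len(n), training = res$train_idx,
                 validation = setdiff(seq_len(n), res$train_idx))
  report <- do.call(rbind, lapply(names(blocks), function(b) {
    i <- blocks[[b]]
    tc <- sum(correct[i]); ti <- length(i) - tc
    data.frame(set = b, Tc = tc, Ti = ti, TOTAL = length(i),
               pct_I = round_half_up(100 * ti / length(i)),
               stringsAsFactors = FALSE)
  }))
  list(classifier = clf, report = report, train_idx = res$train_idx)
}

#' Apply a fitted classifier directly to an expression matrix
#'
#' Requires the classifier to have been trained with its `panel` stored;
#' features are rebuilt from the panel's probe pairs.
#'
#' @param object A `fitted_classifier` (or `multiclass_classifier`).
#' @param expr An `expression_matrix`.
#' @param subjects Subject ids (default all).
#' @return Named character vector of predicted labels.
#' @export
classify_expr <- function(object, expr, subjects = NULL) {
  if (inherits(object, "multiclass_classifier"))
    return(predict(object, expr, subjects = subjects))
  stopifnot(inherits(object, "fitted_classifier"))
  if (is.null(object$panel))
    stop_("classifier was trained without a stored panel")
  f <- build_features(expr, object$panel, subjects = subjects)
  predict(object, f)
}

dedup_ratios <- function(df) {
  key <- paste(df$numerator, df$denominator, sep = "/")
  df[!duplicated(key), c("numerator", "denominator"), drop = FALSE]
}

#' Three-class kernel classification (CTRL / UC / CD)
#'
#' Extends the binary machinery to three classes by one-vs-one voting over
#' the three pairwise classifiers; vote ties are broken by summed decision
#' margins.  The ratio features are chosen per `ratio_set_mode`:
#' `"case_vs_control"` uses the single panel from searching control vs the
#' pooled cases; `"union"` concatenates the three pairwise panels'
#' ratios (deduplicated), which enlarges the feature set and, with
#' disjoint class signatures, improves per-class recall.
#'
#' @param expr An `expression_matrix` containing all three classes.
#' @param class_labels The three class labels (first = control).
#' @param ratio_set_mode `"case_vs_control"` or `"union"`.
#' @param reps,top_k Candidate-search parameters.
#' @param config A [train_config()] used for each pairwise machine.
#' @param seed Integer seed for the ratio searches.
#' @return A `multiclass_classifier` with fields `classes`, `pair_models`,
#'   `ratios` (feature pairs) and `train_recall` (per-class recall on the
#'   training data).
#' @export
train_multiclass <- function(expr, class_labels = c("CTRL", "UC", "CD"),
                             ratio_set_mode = c("case_vs_control", "union"),
                             reps = 50L, top_k = 100L, config, seed) {
  ratio_set_mode <- match.arg(ratio_set_mode)
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(class_labels) != 3L) stop_("exactly three classes required")
  present <- class_labels %in% expr$groups
  if (!all(present))
    stop_("class(es) absent from data: %s",
          paste(class_labels[!present], collapse = ", "))
  control <- class_labels[1L]; cases <- class_labels[-1L]
  if (ratio_set_mode == "case_vs_control") {
    cand <- search_candidates(expr, cases, control, reps = reps,
                              top_k = top_k, seed = seed)
    ratios <- dedup_ratios(select_panel(cand, expr, cases, control))
  } else {
    prs <- list(c(control, cases[1L]), c(control, cases[2L]), cases)
    panels <- lapply(seq_along(prs), function(i) {
      pr <- prs[[i]]
      cand <- search_candidates(expr, pr[2L], pr[1L], reps = reps,
                                top_k = top_k, seed = seed + i)
      select_panel(cand, expr, pr[2L], pr[1L])
    })
    ratios <- dedup_ratios(do.call(rbind, lapply(panels, as.data.frame)))
  }
  fake_panel <- structure(data.frame(ratios, threshold = NA_real_),
                          class = c("ratio_panel", "data.frame"))
  rows <- group_rows(expr, class_labels)
  feats <- build_features(expr, fake_panel,
                          subjects = rownames(expr$levels)[rows])
  labs <- unname(expr$groups[rows])
  pair_list <- utils::combn(class_labels, 2L, simplify = FALSE)
  pair_models <- lapply(seq_along(pair_list), function(i) {
    pr <- pair_list[[i]]
    sel <- labs %in% pr
    cfg <- config
    cfg$seed <- config$seed + i
    train_subset_grid(feats[sel, , drop = FALSE], labs[sel], cfg,
                      positive_label = pr[1L], panel = fake_panel)
  })
  obj <- structure(list(classes = class_labels, pair_models = pair_models,
                        ratios = ratios, panel = fake_panel,
                        mode = ratio_set_mode),
                   class = "multiclass_classifier")
  pred <- predict(obj, expr, subjects = rownames(expr$levels)[rows])
  obj$train_recall <- vapply(class_labels, function(cl)
    mean(pred[labs == cl] == cl), numeric(1))
  obj
}

#' @export
predict.multiclass_classifier <- function(object, expr, subjects = NULL, ...) {
  feats <- build_features(expr, object$panel, subjects = subjects)
  votes <- matrix(0L, nrow(feats), length(object$classes),
                  dimnames = list(rownames(feats), object$classes))
  margin <- matrix(0, nrow(feats), length(object$classes),
                   dimnames = dimnames(votes))
  for (m in object$pair_models) {
    s <- decision_scores(m, feats)
    win <- ifelse(s > 0, m$positive_label, m$negative_label)
    for (cl in c(m$positive_label, m$negative_label))
      votes[win == cl, cl] <- votes[win == cl, cl] + 1L
    margin[, m$positive_label] <- margin[, m$positive_label] + s
    margin[, m$negative_label] <- margin[, m$negative_label] - s
  }
  picks <- vapply(seq_len(nrow(votes)), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) top <- top[which.max(margin[i, top])]
    object$classes[top]
  }, character(1))
  stats::setNames(picks, rownames(feats))
}

#' Tiered two-stage disease classification
#'
#' Stage 1 assigns each subject IBD or IBS; subjects called IBD are routed
#' to stage 2, which discriminates CD from UC.  Subjects assigned IBS at
#' stage 1 never receive a stage-2 label.
#'
#' @param expr An `expression_matrix`.
#' @param stage1_model `fitted_classifier` for IBD vs IBS (trained with a
#'   stored panel).
#' @param stage2_model `fitted_classifier` for CD vs UC.
#' @param subjects Subject ids (default all).
#' @param ibs_label Stage-1 label that terminates the cascade.
#' @return Named character vector of labels in {IBS, CD, UC}.
#' @export
tiered_classify <- function(expr, stage1_model, stage2_model,
                            subjects = NULL, ibs_label = "IBS") {
  subjects <- subjects %||% rownames(expr$levels)
  pred1 <- classify_expr(stage1_model, expr, subjects = subjects)
  out <- pred1
  ibd <- names(pred1)[pred1 != ibs_label]
  if (length(ibd) > 0L)
    out[ibd] <- classify_expr(stage2_model, expr, subjects = ibd)
  out[subjects]
}

#' Serialize a fitted classifier to JSON
#'
#' @param object A `fitted_classifier`.
#' @param path Output path.
#' @export
write_classifier <- function(object, path) {
  stopifnot(inherits(object, "fitted_classifier"))
  m <- object$model
  obj <- list(kernel = unclass(m$kernel),
              positive_label = object$positive_label,
              negative_label = object$negative_label,
              feature_names = object$feature_names,
              protocol = object$protocol,
              alpha = m$alpha, b = m$b, y_train = m$y_train,
              center = m$center, scale = m$scale,
              x_train = apply(m$x_train, 1L, identity, simplify = FALSE),
              panel = if (!is.null(object$panel))
                list(numerator = object$panel$numerator,
                     denominator = object$panel$denominator,
                     threshold = object$panel$threshold))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(object)
}

#' Read a fitted classifier from JSON
#'
#' @param path Path written by [write_classifier].
#' @return A `fitted_classifier`.
#' @export
read_classifier <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- kernel_spec(o$kernel$family, o$kernel$width_or_degree,
                      o$kernel$soft_margin_C)
  x_train <- do.call(rbind, o$x_train)
  colnames(x_train) <- o$feature_names
  model <- structure(list(kernel = spec, x_train = x_train,
                          y_train = o$y_train, alpha = o$alpha, b = o$b,
                          center = stats::setNames(o$center, o$feature_names),
                          scale = stats::setNames(o$scale, o$feature_names)),
                     class = "lssvm")
  panel <- if (!is.null(o$panel)) {
    structure(data.frame(numerator = o$panel$numerator,
                         denominator = o$panel$denominator,
                         threshold = o$panel$threshold,
                         stringsAsFactors = FALSE),
              class = c("ratio_panel", "data.frame"))
  }
  make_classifier(model, o$positive_label, o$negative_label,
                  o$feature_names, o$protocol, NULL, panel, tuning = NULL)
}
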