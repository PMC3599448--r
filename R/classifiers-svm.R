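# Least-squares soft-margin kernel classifier (LS-SVM).
#
# The soft-margin kernel machine is fitted in its least-squares form: with
# labels y_i in {-1,+1} and kernel K, the dual solution (alpha, b) solves
# the (n+1)x(n+1) linear KKT system
#
#   [ 0    y^T          ] [ b     ]   [ 0 ]
#   [ y    Yy K Yy + I/C ] [ alpha ] = [ 1 ]
#
# where (Yy K Yy)_ij = y_i y_j K(x_i, x_j) and C is the soft-margin cost.
# The decision function is f(x) = sum_i alpha_i y_i K(x, x_i) + b.  This
# keeps training deterministic (a single linear solve), which the grid
# protocols rely on.

#' Kernel specification for the soft-margin classifier
#'
#' @param family `"radial_basis"` (`K(x,z) = exp(-beta * ||x-z||^2)`) or
#'   `"polynomial"` (`K(x,z) = (1 + <x,z>)^degree`).
#' @param width_or_degree Kernel width beta (> 0) for radial basis, or
#'   integer degree (>= 1) for polynomial.
#' @param soft_margin_C Soft-margin cost C (> 0).
#' @return A `kernel_spec`.
#' @export
kernel_spec <- function(family = c("radial_basis", "polynomial"),
                        width_or_degree, soft_margin_C) {
  family <- match.arg(family)
  if (!is.numeric(width_or_degree) || width_or_degree <= 0)
    stop_("width_or_degree must be positive")
  if (family == "polynomial" && width_or_degree < 1)
    stop_("polynomial degree must be >= 1")
  if (!is.numeric(soft_margin_C) || soft_margin_C <= 0)
    stop_("soft_margin_C must be positive")
  structure(list(family = family, width_or_degree = width_or_degree,
                 soft_margin_C = soft_margin_C), class = "kernel_spec")
}

# Pairwise squared Euclidean distances between rows of A and rows of B.
sqdist <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

kernel_gram <- function(spec, a, b, precomp = NULL) {
  if (spec$family == "radial_basis") {
    d <- precomp %||% sqdist(a, b)
    exp(-spec$width_or_degree * d)
  } else {
    g <- precomp %||% (1 + tcrossprod(a, b))
    g ^ spec$width_or_degree
  }
}

# precomp: sqdist (rbf) or 1 + inner products (poly) of the training rows.
lssvm_solve <- function(spec, y, precomp) {
  n <- length(y)
  K <- kernel_gram(spec, precomp = precomp)
  H <- (K * tcrossprod(y)) + diag(n) / spec$soft_margin_C
  A <- rbind(c(0, y), cbind(y, H))
  sol <- tryCatch(solve(A, c(0, rep(1, n))),
                  error = function(e) solve(A + diag(n + 1) * 1e-8,
                                            c(0, rep(1, n))))
  list(b = sol[1L], alpha = sol[-1L])
}

# Fit on a feature matrix; standardizes features on the training set
# (kernel machines are scale-sensitive).
lssvm_fit <- function(x, y, spec) {
  stopifnot(is.matrix(x), all(y %in% c(-1, 1)))
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, `/`)
  precomp <- if (spec$family == "radial_basis") sqdist(xs, xs) else
    1 + tcrossprod(xs)
  sol <- lssvm_solve(spec, y, precomp)
  structure(list(kernel = spec, x_train = xs, y_train = y,
                 alpha = sol$alpha, b = sol$b,
                 center = center, scale = scale_),
            class = "lssvm")
}

lssvm_decision <- function(model, x) {
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, `/`)
  pre <- if (model$kernel$family == "radial_basis")
    sqdist(xs, model$x_train) else 1 + tcrossprod(xs, model$x_train)
  k <- kernel_gram(model$kernel, precomp = pre)
  drop(k %*% (model$alpha * model$y_train) + model$b)
}

#' Default logarithmic tuning grid
#'
#' 13-point log2 grids over `2^-6 .. 2^6` for the kernel width beta and the
#' soft-margin cost C (for polynomial kernels the width grid is replaced by
#' degrees 1-4).
#'
#' @param family Kernel family.
#' @param n_points Grid points per axis for the log grids.
#' @return List with `width_or_degree` and `soft_margin_C` vectors.
#' @export
default_grid <- function(family = c("radial_basis", "polynomial"),
                         n_points = 13L) {
  family <- match.arg(family)
  wd <- if (family == "radial_basis")
    2 ^ seq(-6, 6, length.out = n_points) else 1:4
  list(width_or_degree = wd,
       soft_margin_C = 2 ^ seq(-6, 6, length.out = n_points))
}
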