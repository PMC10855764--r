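#' Autoscale a data matrix
#'
#' Column-centers and scales each variable to unit variance (n-1 denominator),
#' the standard pretreatment for GC-MS areas whose magnitudes span orders of
#' magnitude. Constant columns are centered and left at zero with a warning.
#'
#' @param X Numeric matrix or data frame (samples x variables), >= 2 rows.
#' @return An object of class `scaled_matrix`: list with `values` (scaled
#'   matrix), `center` and `scale` (per-column statistics used, for applying
#'   the identical transform to new data).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 rows", call. = FALSE)
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  if (any(const)) {
    warning(sum(const), " constant column(s) centered and left at zero",
            call. = FALSE)
    scl[const] <- 1
  }
  structure(list(values = sweep(sweep(X, 2, center), 2, scl, "/"),
                 center = center, scale = scl),
            class = "scaled_matrix")
}

#' Apply stored scaling parameters to new data
#'
#' @param scaled A `scaled_matrix` (the training scaling).
#' @param X_new New data with the same variables.
#' @return Scaled numeric matrix.
#' @export
apply_scaling <- function(scaled, X_new) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(scaled$center)) {
    stop("variable count mismatch with training scaling", call. = FALSE)
  }
  sweep(sweep(X_new, 2, scaled$center), 2, scaled$scale, "/")
}

#' Principal component analysis by singular value decomposition
#'
#' Decomposes an already-scaled matrix; scores are the projections of the data
#' onto the orthonormal loadings and the explained-variance fraction of
#' component i is its squared singular value over the total. The sign of each
#' component is fixed so that the loading with the largest magnitude is
#' positive, for reproducible score plots.
#'
#' @param X A `scaled_matrix` or a pre-treated numeric matrix.
#' @param n_components Number of components to keep; truncated to the matrix
#'   rank with a warning if larger.
#' @return Object of class `pca_model`: `scores` (n x A), `loadings` (p x A,
#'   orthonormal), `explained` (fraction per component, non-increasing).
#' @export
pca <- function(X, n_components = 2L) {
  M <- if (inherits(X, "scaled_matrix")) X$values else as.matrix(X)
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncated", call. = FALSE)
    n_components <- rank
  }
  a <- seq_len(n_components)
  loadings <- sv$v[, a, drop = FALSE]
  scores <- sv$u[, a, drop = FALSE] %*% diag(sv$d[a], length(a))
  # sign convention: largest-magnitude loading positive per component
  for (j in a) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(colnames(M), paste0("PC", a))
  dimnames(scores) <- list(rownames(M), paste0("PC", a))
  structure(list(scores = scores, loadings = loadings,
                 explained = sv$d[a]^2 / sum(sv$d^2),
                 singular_values = sv$d),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA: %d components, explained variance %s\n",
              ncol(x$scores),
              paste0(sprintf("%.1f%%", 100 * x$explained), collapse = " / ")))
  invisible(x)
}

#' Group confidence ellipse in score space
#'
#' The (1 - alpha) confidence ellipse of a group of 2-D scores is centered at
#' the group mean with shape given by the group covariance scaled by the
#' chi-square quantile with 2 degrees of freedom: a point lies inside iff its
#' squared Mahalanobis distance from the center is at most that quantile.
#'
#' @param scores Two-column matrix of scores for one group (>= 3 rows).
#' @param level Confidence level in (0, 1); 0.95 corresponds to p = 0.05.
#' @return Object of class `group_ellipse`: `center`, `cov`, `shape`
#'   (`cov * qchisq(level, 2)`), `level`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, level > 0, level < 1)
  if (nrow(scores) < 3L) stop("a group needs >= 3 samples for an ellipse",
                              call. = FALSE)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  if (!is.finite(determinant(S)$modulus) || det(S) <= 0) {
    stop("degenerate group: singular score covariance", call. = FALSE)
  }
  q <- stats::qchisq(level, df = 2)
  structure(list(center = ctr, cov = S, shape = S * q, level = level,
                 chisq_quantile = q),
            class = "group_ellipse")
}

#' Test points for ellipse membership
#'
#' @param ellipse A `group_ellipse`.
#' @param points Two-column matrix of score coordinates.
#' @return Logical vector: squared Mahalanobis distance <= the chi-square
#'   quantile of the ellipse's level.
#' @export
ellipse_contains <- function(ellipse, points) {
  stopifnot(inherits(ellipse, "group_ellipse"))
  points <- matrix(as.numeric(points), ncol = 2L)
  d2 <- stats::mahalanobis(points, ellipse$center, ellipse$cov)
  d2 <= ellipse$chisq_quantile
}

#' Boundary path of a confidence ellipse (for plotting)
#'
#' @param ellipse A `group_ellipse`.
#' @param n Number of boundary points.
#' @return n x 2 matrix tracing the ellipse boundary.
#' @export
ellipse_path <- function(ellipse, n = 120L) {
  stopifnot(inherits(ellipse, "group_ellipse"))
  theta <- seq(0, 2 * pi, length.out = n)
  circle <- cbind(cos(theta), sin(theta))
  # chol(shape) maps the unit circle onto the ellipse boundary
  sweep(circle %*% chol(ellipse$shape), 2, ellipse$center, "+")
}

# --- NIPALS PLS1 core ---------------------------------------------------------

# Fit a single-response PLS model by NIPALS with deflation of X.
# Xs: scaled predictor matrix; y: response vector (centered internally).
# Returns weights W, X-loadings P, y-loadings q, scores T and the y mean.
pls1_nipals <- function(Xs, y, ncomp, tol = 1e-10, max_iter = 500L) {
  Xs <- as.matrix(Xs)
  n <- nrow(Xs); p <- ncol(Xs)
  ncomp <- min(ncomp, n - 1L, p)
  y_mean <- mean(y)
  u <- y - y_mean
  E <- Xs
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, u)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * p) break  # residual X carries no covariance
    w <- w / nw
    # with a single response the NIPALS weight update is a fixed point after
    # one pass; iterate anyway to honor the generic convergence contract
    for (it in seq_len(max_iter)) {
      w_new <- crossprod(E, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      if (delta < tol) break
    }
    t_sc <- drop(E %*% w)
    tt <- sum(t_sc^2)
    if (tt == 0) break
    p_a <- crossprod(E, t_sc) / tt
    q_a <- sum(u * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_a)
    u <- u - t_sc * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_sc; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) stop("PLS found no covariance between X and y", call. = FALSE)
  keep <- seq_len(a_used)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Tm = Tm[, keep, drop = FALSE], q = q[keep],
       ncomp = a_used, y_mean = y_mean)
}

# Cumulative predictions of a PLS1 fit on new (already scaled) data:
# column a holds the prediction using components 1..a.
pls1_predict_cum <- function(fit, Xs_new) {
  Xs_new <- as.matrix(Xs_new)
  n <- nrow(Xs_new)
  preds <- matrix(0, n, fit$ncomp)
  E <- Xs_new
  acc <- rep(fit$y_mean, n)
  for (a in seq_len(fit$ncomp)) {
    t_new <- drop(E %*% fit$W[, a])
    E <- E - tcrossprod(t_new, fit$P[, a])
    acc <- acc + t_new * fit$q[a]
    preds[, a] <- acc
  }
  preds
}

#' Fit a PLS-DA classifier
#'
#' Partial least squares discriminant analysis: the class membership is coded
#' as a one-versus-rest 0/1 indicator and one NIPALS PLS1 model is fitted per
#' class on the autoscaled predictor matrix. For a two-class problem this
#' reduces to a single binary model. Predictors are autoscaled internally and
#' the training scaling parameters are stored, so that new data are always
#' transformed with the training statistics.
#'
#' @param X Numeric matrix (samples x variables) of, e.g., IS-normalized areas.
#' @param labels Factor or character vector of class labels (>= 2 classes).
#' @param n_lv Number of latent variables per class model.
#' @param scale Logical: autoscale X (default). Disable only for pre-treated
#'   input.
#' @return Object of class `plsda_model`: `classes`, per-class `fits`
#'   (NIPALS weights/loadings/scores), `scaling`, `n_lv`.
#' @export
fit_plsda <- function(X, labels, n_lv = 2L, scale = TRUE) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  stopifnot(n_lv >= 1L, nrow(X) == length(labels))
  scaling <- if (scale) {
    autoscale(X)
  } else {
    structure(list(values = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X))),
              class = "scaled_matrix")
  }
  fits <- lapply(classes, function(cl) {
    pls1_nipals(scaling$values, as.numeric(labels == cl), ncomp = n_lv)
  })
  names(fits) <- classes
  structure(list(classes = classes, fits = fits, scaling = scaling,
                 n_lv = n_lv, labels = labels, variables = colnames(X)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA: %d classes (%s), up to %d latent variables\n",
              length(x$classes), paste(x$classes, collapse = ", "), x$n_lv))
  invisible(x)
}

#' Predict class membership from a PLS-DA model
#'
#' Returns the continuous predicted indicator per class and hard labels: the
#' class with the maximal score (one-vs-rest argmax); for a binary model this
#' is equivalent to thresholding the positive-class indicator at `threshold`.
#'
#' @param object A `plsda_model`.
#' @param X_new New samples with the training variable set (raw scale; the
#'   training scaling is applied internally).
#' @param threshold Hard-label threshold on the indicator for binary models.
#' @param ... Unused.
#' @return List with `scores` (samples x classes matrix of continuous
#'   indicators) and `labels` (character vector of hard assignments).
#' @export
predict.plsda_model <- function(object, X_new, threshold = 0.5, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$scaling$center)) {
    stop("variable set mismatch with training data", call. = FALSE)
  }
  Xs <- apply_scaling(object$scaling, X_new)
  sc <- vapply(object$fits, function(f) {
    pls1_predict_cum(f, Xs)[, f$ncomp]
  }, numeric(nrow(Xs)))
  sc <- matrix(sc, nrow = nrow(Xs),
               dimnames = list(rownames(X_new), object$classes))
  labels <- if (length(object$classes) == 2L) {
    ifelse(sc[, 2L] > threshold, object$classes[2L], object$classes[1L])
  } else {
    object$classes[max.col(sc, ties.method = "first")]
  }
  list(scores = sc, labels = labels)
}

#' Variable importance in projection (VIP)
#'
#' For a fitted PLS1 component sequence, the VIP of variable j is
#' `sqrt(p * sum_a(ssy_a * (w_ja / ||w_a||)^2) / sum_a(ssy_a))` where
#' `ssy_a = q_a^2 t_a' t_a` is the y-variance explained by component a and p
#' the number of variables. The normalization identity `sum(VIP^2) = p` holds
#' for every fitted model.
#'
#' @param model A `plsda_model` or a single PLS1 fit.
#' @param class For multi-model `plsda_model`s, which class model to use;
#'   default the second class of a binary model, otherwise required.
#' @return Numeric vector of VIP scores (named by variable when available).
#' @export
vip_scores <- function(model, class = NULL) {
  fit <- if (inherits(model, "plsda_model")) {
    if (is.null(class)) {
      if (length(model$classes) != 2L) {
        stop("specify `class` for a multi-class model", call. = FALSE)
      }
      class <- model$classes[2L]
    }
    if (!class %in% model$classes) stop("unknown class ", class, call. = FALSE)
    model$fits[[class]]
  } else {
    model
  }
  p <- nrow(fit$W)
  ssy <- fit$q^2 * colSums(fit$Tm^2)  # y-variance captured per component
  if (sum(ssy) <= 0) stop("zero explained y-variance: VIP undefined", call. = FALSE)
  wn2 <- sweep(fit$W^2, 2, colSums(fit$W^2), "/")
  vip <- sqrt(p * drop(wn2 %*% ssy) / sum(ssy))
  if (inherits(model, "plsda_model") && !is.null(model$variables)) {
    names(vip) <- model$variables
  }
  vip
}

#' Per-variable maximum VIP across all class models
#'
#' For a multi-class PLS-DA fitted as one-vs-rest binary models, a variable is
#' an important contributor if it matters to *any* class model; the natural
#' aggregate is the per-variable maximum VIP. For a binary model this equals
#' the VIP of the positive-class model.
#'
#' @param model A `plsda_model`.
#' @return Named numeric vector of maximum VIP scores.
#' @export
vip_max <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  V <- vapply(model$classes, function(cl) vip_scores(model, class = cl),
              numeric(nrow(model$fits[[1]]$W)))
  v <- apply(V, 1, max)
  if (!is.null(model$variables)) names(v) <- model$variables
  v
}

#' Select marker variables by VIP threshold
#'
#' @param vip Numeric vector of VIP scores (named).
#' @param cutoff Inclusive selection threshold; the conventional value for
#'   marker screening is 1.2.
#' @return Named numeric vector of the selected VIPs, sorted decreasing.
#' @export
select_markers <- function(vip, cutoff = 1.2) {
  stopifnot(cutoff > 0)
  sel <- vip[vip >= cutoff]
  sel[order(sel, decreasing = TRUE)]
}
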