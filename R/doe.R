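#' Define a design factor
#'
#' @param name Factor name.
#' @param low,high Low and high levels in natural units; the center level is
#'   their midpoint, as required by face-centered coding.
#' @return An object of class `doe_factor`.
#' @examples
#' temp <- doe_factor("temp_c", 30, 50)   # 30/40/50 C
#' time <- doe_factor("time_min", 20, 60) # 20/40/60 min
#' @export
doe_factor <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L, low < high)
  structure(list(name = name, low = low, mid = (low + high) / 2, high = high),
            class = "doe_factor")
}

#' Generate a face-centered central composite design
#'
#' A CCD for `k` factors at coded levels -1/0/+1 comprises the `2^k` factorial
#' corners, `2k` axial (star) points and `n_center` replicated center points.
#' With the axial distance at 1 (face-centered), the axial points sit on the
#' faces of the factorial cube, so only three distinct levels per factor are
#' required. For two factors with three center replicates this is the classic
#' 11-run design.
#'
#' @param factors List of [doe_factor()] objects (k >= 2).
#' @param n_center Number of center-point replicates (>= 1).
#' @return An object of class `ccd_design`: list with `coded` (runs x k matrix
#'   of -1/0/+1), `factors`, and `n_center`.
#' @export
generate_ccd <- function(factors, n_center = 3L) {
  k <- length(factors)
  if (k < 2L) stop("central composite designs need at least 2 factors", call. = FALSE)
  stopifnot(n_center >= 1L, all(vapply(factors, inherits, logical(1), "doe_factor")))
  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (j in seq_len(k)) axial[c(2L * j - 1L, 2L * j), j] <- c(-1, 1)
  centers <- matrix(0, n_center, k)
  coded <- rbind(corners, axial, centers)
  dimnames(coded) <- list(NULL, vapply(factors, `[[`, character(1), "name"))
  structure(list(coded = coded, factors = factors, n_center = as.integer(n_center)),
            class = "ccd_design")
}

#' @export
print.ccd_design <- function(x, ...) {
  cat(sprintf("Face-centered CCD: %d factors, %d runs (%d center replicates)\n",
              ncol(x$coded), nrow(x$coded), x$n_center))
  print(decode_runs(x))
  invisible(x)
}

#' Decode a design from coded to natural units
#'
#' Coded level -1 maps to each factor's low value, 0 to its midpoint and +1 to
#' its high value.
#'
#' @param design A `ccd_design`.
#' @return Data frame of runs in natural units with a `run` id column.
#' @export
decode_runs <- function(design) {
  stopifnot(inherits(design, "ccd_design"))
  coded <- design$coded
  if (!all(coded %in% c(-1, 0, 1))) stop("unknown coded level", call. = FALSE)
  nat <- coded
  for (j in seq_along(design$factors)) {
    f <- design$factors[[j]]
    nat[, j] <- f$mid + coded[, j] * (f$high - f$low) / 2
  }
  data.frame(run = seq_len(nrow(nat)), nat, check.names = FALSE)
}

# model matrix for the full second-order polynomial in coded units
quadratic_model_matrix <- function(coded) {
  k <- ncol(coded)
  cols <- list(`(Intercept)` = rep(1, nrow(coded)))
  for (j in seq_len(k)) cols[[colnames(coded)[j]]] <- coded[, j]
  if (k >= 2L) {
    for (pair in utils::combn(k, 2, simplify = FALSE)) {
      nm <- paste(colnames(coded)[pair], collapse = ":")
      cols[[nm]] <- coded[, pair[1]] * coded[, pair[2]]
    }
  }
  for (j in seq_len(k)) {
    cols[[paste0("I(", colnames(coded)[j], "^2)")]] <- coded[, j]^2
  }
  do.call(cbind, cols)
}

#' Fit a second-order response surface
#'
#' Ordinary least-squares fit of the full quadratic polynomial (intercept, k
#' linear, k(k-1)/2 interaction and k pure quadratic terms) in coded units,
#' the standard model family for central composite designs.
#'
#' @param design A `ccd_design`.
#' @param response Numeric response vector, one value per run.
#' @return An object of class `quadratic_surface` with elements `coefficients`
#'   (named), `r_squared`, `design` and `fitted`.
#' @export
fit_response_surface <- function(design, response) {
  stopifnot(inherits(design, "ccd_design"))
  y <- as.numeric(response)
  if (length(y) != nrow(design$coded)) {
    stop("response length (", length(y), ") != run count (",
         nrow(design$coded), ")", call. = FALSE)
  }
  mm <- quadratic_model_matrix(design$coded)
  if (nrow(mm) < ncol(mm) || qr(mm)$rank < ncol(mm)) {
    stop("singular fit: design cannot identify the full quadratic", call. = FALSE)
  }
  fit <- stats::lm.fit(mm, y)
  fitted <- mm %*% fit$coefficients
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - fitted)^2) / tss else 1
  structure(list(coefficients = fit$coefficients,
                 r_squared = r2,
                 factors = design$factors,
                 fitted = drop(fitted)),
            class = "quadratic_surface")
}

#' Construct a quadratic surface from known coefficients
#'
#' Used to define ground-truth surfaces for simulation and round-trip tests.
#' Coefficient order follows [fit_response_surface()]: intercept, linear terms,
#' interactions (in `combn` order), pure quadratics.
#'
#' @param coefficients Numeric vector of length `1 + 2k + k(k-1)/2`.
#' @param factors List of [doe_factor()]s defining the natural-unit domain.
#' @return A `quadratic_surface`.
#' @export
quadratic_surface <- function(coefficients, factors) {
  k <- length(factors)
  expected <- 1L + 2L * k + (k * (k - 1L)) %/% 2L
  if (length(coefficients) != expected) {
    stop("expected ", expected, " coefficients for ", k, " factors", call. = FALSE)
  }
  structure(list(coefficients = as.numeric(coefficients),
                 r_squared = NA_real_, factors = factors, fitted = NULL),
            class = "quadratic_surface")
}

#' Predict a quadratic surface on coded points
#'
#' @param object A `quadratic_surface`.
#' @param coded Matrix of coded factor settings (columns = factors).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quadratic_surface <- function(object, coded, ...) {
  coded <- as.matrix(coded)
  if (is.null(colnames(coded))) {
    colnames(coded) <- vapply(object$factors, `[[`, character(1), "name")
  }
  drop(quadratic_model_matrix(coded) %*% object$coefficients)
}

code_points <- function(natural, factors) {
  coded <- as.matrix(natural)
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    coded[, j] <- (coded[, j] - f$mid) / ((f$high - f$low) / 2)
  }
  colnames(coded) <- vapply(factors, `[[`, character(1), "name")
  coded
}

#' Derringer desirability transform for a maximized response
#'
#' Maps a predicted response to the [0, 1] desirability scale: 0 at or below
#' the lower bound `L` (undesirable), 1 at or above the upper bound `U`
#' (ideal), and `((value - L)/(U - L))^s` in between.
#'
#' @param value Numeric vector of response values.
#' @param lower,upper Bounds `L < U` on the response scale.
#' @param s Positive exponent shaping the ramp (1 = linear).
#' @return Numeric vector of desirabilities in [0, 1].
#' @export
desirability <- function(value, lower, upper, s = 1) {
  stopifnot(lower < upper, s > 0)
  d <- ((value - lower) / (upper - lower))^s
  pmin(1, pmax(0, d))
}

#' Global desirability (geometric mean)
#'
#' @param d Numeric vector of individual desirabilities in [0, 1].
#' @return The geometric mean; 0 whenever any component is 0 (veto property).
#' @export
global_desirability <- function(d) {
  if (length(d) == 0L) stop("no desirabilities supplied", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]", call. = FALSE)
  exp(mean(log(pmax(d, 0))))  # exp(-Inf) = 0 handles the veto case
}

#' Optimize extraction conditions by the desirability method
#'
#' Evaluates the global desirability `D` (geometric mean of per-response
#' desirabilities) of the fitted response surfaces over a regular grid of the
#' natural-unit factor domain and returns the maximizing setting. Ties are
#' broken by the first point in row-major scan order and flagged.
#'
#' By default each response's desirability bounds are the min and max of its
#' fitted surface over the grid, so that desirability spans [0, 1] on the
#' explored region; explicit bounds can be supplied per response.
#'
#' @param surfaces Named list of `quadratic_surface` objects sharing a factor
#'   domain (e.g. `list(y1 = ..., y2 = ...)`).
#' @param factors List of [doe_factor()]s (the shared domain).
#' @param bounds Optional named list of `c(lower, upper)` per response.
#' @param s Desirability exponent, shared across responses.
#' @param resolution Grid points per factor (>= 2).
#' @return An object of class `dom_result`: list with `optimum` (named vector
#'   in natural units), `D_max`, `d_at_optimum`, `tie` flag and the evaluated
#'   `grid` (data frame with per-response predictions, desirabilities and D).
#' @export
optimize_dom <- function(surfaces, factors, bounds = NULL, s = 1,
                         resolution = 201L) {
  if (resolution < 2L) stop("grid resolution must be at least 2", call. = FALSE)
  stopifnot(length(surfaces) >= 1L,
            all(vapply(surfaces, inherits, logical(1), "quadratic_surface")))
  axes <- lapply(factors, function(f) seq(f$low, f$high, length.out = resolution))
  names(axes) <- vapply(factors, `[[`, character(1), "name")
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  coded <- code_points(grid, factors)

  d_all <- matrix(NA_real_, nrow(grid), length(surfaces),
                  dimnames = list(NULL, names(surfaces)))
  for (r in seq_along(surfaces)) {
    pred <- predict(surfaces[[r]], coded)
    b <- if (!is.null(bounds) && !is.null(bounds[[names(surfaces)[r]]])) {
      bounds[[names(surfaces)[r]]]
    } else {
      range(pred)
    }
    if (b[1] >= b[2]) {
      # constant surface: every setting equally desirable
      d_all[, r] <- 1
    } else {
      d_all[, r] <- desirability(pred, b[1], b[2], s = s)
    }
    grid[[paste0("pred_", names(surfaces)[r])]] <- pred
    grid[[paste0("d_", names(surfaces)[r])]] <- d_all[, r]
  }
  D <- apply(d_all, 1, global_desirability)
  grid$D <- D
  best <- which(D == max(D))
  tie <- length(best) > 1L
  if (tie) {
    warning("desirability maximum ties at ", length(best),
            " grid points; first in row-major scan returned", call. = FALSE)
  }
  i <- best[1L]
  structure(list(optimum = unlist(grid[i, names(axes)]),
                 D_max = D[i],
                 d_at_optimum = d_all[i, ],
                 tie = tie,
                 grid = grid),
            class = "dom_result")
}

#' @export
print.dom_result <- function(x, ...) {
  cat("Desirability optimization\n")
  cat("  optimum:", paste(names(x$optimum), signif(x$optimum, 4),
                          sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  D_max = %.3f%s\n", x$D_max, if (x$tie) " (tie)" else ""))
  invisible(x)
}

#' Choose the extraction fiber by response dominance
#'
#' Compares two (or more) fibers on a shared design by the VOC-count response:
#' if one fiber's response is at least as high as every other's on every run,
#' it dominates and is selected; otherwise the fiber with the highest mean
#' response is returned, flagged as non-dominant.
#'
#' @param responses Named list of numeric response vectors (one per fiber),
#'   all over the same design runs in the same order.
#' @return List with `selected` (fiber label), `dominant` (logical) and
#'   `means` (per-fiber mean response). Ties are flagged and resolved in favor
#'   of the first label.
#' @export
compare_fibers <- function(responses) {
  stopifnot(is.list(responses), length(responses) >= 2L, !is.null(names(responses)))
  n <- unique(vapply(responses, length, integer(1)))
  if (length(n) != 1L) stop("fibers measured on different run sets", call. = FALSE)
  mat <- do.call(cbind, responses)
  dominant_of <- function(j) all(mat[, j] >= mat[, -j, drop = FALSE])
  dom <- which(vapply(seq_len(ncol(mat)), dominant_of, logical(1)))
  means <- colMeans(mat)
  if (length(dom) >= 1L) {
    if (length(dom) > 1L) {
      warning("fiber responses tie on every run; first label returned",
              call. = FALSE)
    }
    list(selected = names(responses)[dom[1L]],
         dominant = length(dom) == 1L, means = means)
  } else {
    list(selected = names(responses)[which.max(means)],
         dominant = FALSE, means = means)
  }
}
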