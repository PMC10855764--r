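#' Score plot with group confidence ellipses
#'
#' @param pca_model A [pca()] result with at least two components.
#' @param groups Group label per sample (e.g. dose class).
#' @param level Confidence level of the ellipses.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_scores <- function(pca_model, groups, level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(pca_model, "pca_model"), ncol(pca_model$scores) >= 2L)
  df <- data.frame(pc1 = pca_model$scores[, 1], pc2 = pca_model$scores[, 2],
                   group = as.character(groups))
  paths <- do.call(rbind, lapply(split(df, df$group), function(g) {
    if (nrow(g) < 3L) return(NULL)
    e <- confidence_ellipse(as.matrix(g[, c("pc1", "pc2")]), level = level)
    p <- as.data.frame(ellipse_path(e))
    names(p) <- c("pc1", "pc2")
    p$group <- g$group[1]
    p
  }))
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * pca_model$explained[1:2])
  ggplot2::ggplot(df, ggplot2::aes(x = pc1, y = pc2, colour = group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_path(data = paths, linewidth = 0.4) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::theme_minimal()
}

#' Permutation-null histogram with binomial overlay
#'
#' @param result A [permutation_test()] result.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_permutation <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(result, "permutation_result"))
  df <- data.frame(mis = result$misclassified)
  ref <- data.frame(x = result$reference$counts,
                    y = result$reference$pmf)
  ggplot2::ggplot(df, ggplot2::aes(x = mis)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = 1, fill = "grey70", colour = "white") +
    ggplot2::geom_line(data = ref, ggplot2::aes(x = x, y = y),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = result$observed, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "misclassified samples", y = "density") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("pc1", "pc2", "group", "mis", "x", "y"))
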