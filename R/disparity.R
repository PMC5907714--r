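# Morphological disparity and its partition into group contributions.

#' Total morphological disparity (Procrustes variance)
#'
#' Mean squared Procrustes distance of the specimens to the grand mean
#' shape, with divisor `n - 1`:
#' `sum_i d^2(x_i, xbar) / (n - 1)`.
#'
#' @param coords GPA-aligned coordinates: a `k x m x n` array, an `n x p`
#'   flat matrix, or a [gpa()] / [symmetric_component()] result (aligned
#'   resp. symmetric coordinates used).
#' @return A non-negative scalar in squared Procrustes units.
#' @export
procrustes_variance <- function(coords) {
  X <- coords_to_matrix(coords)
  if (nrow(X) < 2) stop("Procrustes variance needs at least 2 specimens")
  sum(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1)
}

coords_to_matrix <- function(coords) {
  if (inherits(coords, "symmetry_decomposition")) coords <- coords$symmetric
  if (inherits(coords, "gpa")) coords <- coords$aligned
  if (is.matrix(coords)) coords else flatten_coords(coords)
}

#' Foote partial disparity by group
#'
#' Partitions the total Procrustes variance additively into group
#' contributions. Following Foote, each group's partial disparity is the
#' sum of its members' squared Procrustes distances to the *grand* mean,
#' divided by `n_total - 1`:
#' `PD_g = sum_{i in g} d^2(x_i, xbar) / (n_total - 1)`,
#' so that `sum_g PD_g` equals the total Procrustes variance exactly and
#' the percentages sum to 100. A literal within-group-mean variant
#' (group-mean deviations rescaled by group size) is available via
#' `method = "literal"` for sensitivity analysis; it is not additive.
#'
#' @inheritParams procrustes_variance
#' @param groups group labels, one per specimen; no empty groups.
#' @param method `"foote"` (default) or `"literal"`.
#' @return An object of class `disparity_report`: `total_variance`,
#'   `partial` (data frame of group, n, PD, percent), `grand_mean`.
#' @export
partial_disparity <- function(coords, groups, method = c("foote", "literal")) {
  method <- match.arg(method)
  X <- coords_to_matrix(coords)
  g <- factor(groups)
  if (nrow(X) != length(g) || anyNA(g))
    stop("one group label per specimen is required")
  if (any(table(g) == 0)) stop("empty group in 'groups'")
  n <- nrow(X)
  grand <- colMeans(X)
  d2 <- rowSums(sweep(X, 2, grand)^2)
  pd <- if (method == "foote") {
    tapply(d2, g, sum) / (n - 1)
  } else {
    # literal reading: within-group-mean residuals, group variance
    # re-weighted by group size over n_total - 1
    vapply(levels(g), function(lev) {
      Xi <- X[g == lev, , drop = FALSE]
      ssw <- sum(sweep(Xi, 2, colMeans(Xi))^2)
      (ssw / max(nrow(Xi) - 1, 1)) * nrow(Xi) / (n - 1)
    }, numeric(1))
  }
  partial <- data.frame(group = levels(g), n = as.vector(table(g)),
                        PD = as.vector(pd),
                        percent = 100 * as.vector(pd) / sum(pd))
  structure(list(total_variance = sum(d2) / (n - 1), partial = partial,
                 grand_mean = grand, method = method),
            class = "disparity_report")
}

#' @export
print.disparity_report <- function(x, ...) {
  cat(sprintf("Disparity (total Procrustes variance %.4g, method %s)\n",
              x$total_variance, x$method))
  df <- x$partial
  df$PD <- signif(df$PD, 4); df$percent <- round(df$percent, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
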