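# Ordination and group classification of shape data.
#
# The symmetric shape coordinates are ordinated by PCA; the number of PCs
# carried into the discriminant analyses is chosen by maximizing the
# leave-one-out cross-validated classification rate over repeated balanced
# subsamples (the small groups set the subsample size, so unbalanced
# designs do not inflate the apparent accuracy). Group differences are
# tested by permutation Procrustes ANOVA, and classification is by
# leave-one-out LDA with equal priors, with Mahalanobis distances between
# group means in the reduced PC space.

## ---- PCA ------------------------------------------------------------------

#' Principal component analysis of shape data
#'
#' Centred eigen-decomposition of the specimen covariance of the flattened
#' (per-specimen) aligned coordinates, via [stats::prcomp()]. No scaling is
#' applied (all variables are Procrustes coordinates in the same units).
#'
#' @param x a [symmetric_component()] result (its symmetric coordinates are
#'   used), a [gpa()] result (aligned coordinates), a `k x m x n` array, or
#'   an `n x p` matrix of flattened coordinates.
#' @return An object of class `shape_pca`: `scores` (`n x q`),
#'   `eigenvalues` (non-increasing), `variance_fractions` (summing to 1),
#'   `loadings`, `center`, plus carried-over `ids`/`meta`.
#' @export
shape_pca <- function(x) {
  ids <- NULL; meta <- NULL; k <- NULL; m <- NULL
  if (inherits(x, "symmetry_decomposition")) {
    ids <- x$ids; meta <- x$meta; k <- x$k; m <- x$m
    x <- x$symmetric
  } else if (inherits(x, "gpa")) {
    ids <- x$ids; meta <- x$meta; k <- x$k; m <- x$m
    x <- x$aligned
  }
  X <- if (is.matrix(x)) x else flatten_coords(x)
  if (nrow(X) < 2) stop("PCA needs at least 2 specimens")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  structure(list(scores = p$x, eigenvalues = ev,
                 variance_fractions = ev / sum(ev),
                 loadings = p$rotation, center = p$center,
                 k = k, m = m, ids = if (is.null(ids)) rownames(X) else ids,
                 meta = meta),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, n_show = 5L, ...) {
  cat(sprintf("Shape PCA: %d specimens, %d components\n",
              nrow(x$scores), length(x$eigenvalues)))
  q <- min(n_show, length(x$eigenvalues))
  cat(sprintf("  PC%-2d %6.2f%%  (cumulative %6.2f%%)\n", seq_len(q),
              100 * x$variance_fractions[seq_len(q)],
              100 * cumsum(x$variance_fractions)[seq_len(q)]), sep = "")
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) print(object, n_show = 10L, ...)

#' @export
plot.shape_pca <- function(x, axes = c(1, 2), groups = NULL, ...) {
  if (is.null(groups) && !is.null(x$meta) && "group" %in% names(x$meta))
    groups <- x$meta$group
  col <- if (is.null(groups)) "black" else as.integer(factor(groups))
  plot(x$scores[, axes[1]], x$scores[, axes[2]], col = col, pch = 16,
       xlab = sprintf("PC%d (%.1f%%)", axes[1],
                      100 * x$variance_fractions[axes[1]]),
       ylab = sprintf("PC%d (%.1f%%)", axes[2],
                      100 * x$variance_fractions[axes[2]]), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 16,
                     bty = "n")
  invisible(x)
}

#' Project new configurations into an existing PC space
#'
#' @param pca a [shape_pca()].
#' @param coords a `k x m x n` array or `n x p` flat matrix of aligned
#'   coordinates in the same landmark scheme.
#' @return An `n x q` score matrix in the training PC space.
#' @export
project_scores <- function(pca, coords) {
  stopifnot(inherits(pca, "shape_pca"))
  X <- if (is.matrix(coords)) coords else flatten_coords(coords)
  sweep(X, 2, pca$center) %*% pca$loadings
}

## ---- helpers --------------------------------------------------------------

as_group_factor <- function(groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  g
}

# indices of a balanced subsample: `size` per group, without replacement
balanced_subsample <- function(g, size = min(table(g))) {
  unlist(lapply(split(seq_along(g), g), sample, size = size),
         use.names = FALSE)
}

# leave-one-out cross-validated LDA accuracy, equal priors
loo_lda_accuracy <- function(X, g) {
  fit <- suppressWarnings(
    MASS::lda(X, grouping = g, prior = rep(1 / nlevels(g), nlevels(g)),
              CV = TRUE))
  mean(fit$class == g)
}

## ---- dimensionality selection ---------------------------------------------

#' Cross-validated selection of the number of PCs
#'
#' For each candidate dimensionality N, estimates the leave-one-out
#' cross-validated LDA accuracy on the first N PC scores, averaged over
#' repeated balanced subsamples (each group subsampled to the smallest
#' group's size, so unbalanced designs are not rewarded for guessing the
#' majority group). The chosen N maximizes mean accuracy; ties go to the
#' smallest N.
#'
#' @param scores PC score matrix (`n x q`) from [shape_pca()].
#' @param groups group labels (length n); every group needs >= 2 members.
#' @param max_N largest dimensionality to try (capped, with a warning, so
#'   the subsampled LDA remains estimable).
#' @param resamples number of balanced subsamples per N (default 1000).
#' @param seed optional RNG seed.
#' @return An object of class `dimension_selection`: `chosen_N` and
#'   `accuracy_by_N` (data frame of N, mean and sd of accuracy).
#' @export
select_dimensions <- function(scores, groups, max_N = 20L, resamples = 1000L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_group_factor(groups)
  if (any(table(g) < 2)) stop("every group needs at least 2 members")
  n_min <- min(table(g)); n_groups <- nlevels(g)
  n_sub <- n_min * n_groups
  cap <- min(ncol(scores), n_sub - n_groups - 1L)
  if (max_N > cap) {
    warning("max_N capped at ", cap, " (balanced subsample size ", n_sub, ")")
    max_N <- cap
  }
  if (max_N < 2L) stop("too few specimens for any candidate dimensionality")
  Ns <- 2:max_N
  acc <- matrix(NA_real_, length(Ns), resamples)
  for (r in seq_len(resamples)) {
    idx <- balanced_subsample(g)
    for (j in seq_along(Ns))
      acc[j, r] <- loo_lda_accuracy(scores[idx, seq_len(Ns[j]), drop = FALSE],
                                    droplevels(g[idx]))
  }
  mean_acc <- rowMeans(acc)
  chosen <- Ns[which.max(mean_acc)]  # which.max takes the first (smallest N)
  structure(list(chosen_N = chosen,
                 accuracy_by_N = data.frame(N = Ns, accuracy = mean_acc,
                                            sd = apply(acc, 1, stats::sd)),
                 resamples = resamples, subsample_per_group = n_min),
            class = "dimension_selection")
}

#' @export
print.dimension_selection <- function(x, ...) {
  cat(sprintf(
    "Dimension selection: N = %d (%.1f%% cross-validated accuracy, %d balanced resamples)\n",
    x$chosen_N,
    100 * x$accuracy_by_N$accuracy[x$accuracy_by_N$N == x$chosen_N],
    x$resamples))
  invisible(x)
}

## ---- Procrustes ANOVA -----------------------------------------------------

#' Permutation Procrustes ANOVA on PC scores
#'
#' Tests group differences in shape with the pseudo-F statistic
#' `F = (SSB / (g - 1)) / (SSW / (n - g))` computed on the first N PC
#' scores (sums of squares traced over all N dimensions). The p-value is
#' the proportion of group-label permutations, the observed labelling
#' included, whose F is at least the observed one; it is therefore bounded
#' below by `1 / (permutations + 1)`.
#'
#' @param scores PC score matrix.
#' @param groups group labels; every group needs >= 2 members.
#' @param N number of leading PCs to use.
#' @param permutations number of label permutations (default 999).
#' @param seed optional RNG seed.
#' @return An object of class `procrustes_anova`: `F`, `p`, `permutations`,
#'   `N`, `ss` (between/within/total).
#' @export
procrustes_anova <- function(scores, groups, N, permutations = 999L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_group_factor(groups)
  if (any(table(g) < 2))
    stop("groups of size 1 have no within-group variance")
  if (N > ncol(scores)) stop("N exceeds the number of available PCs")
  X <- as.matrix(scores[, seq_len(N), drop = FALSE])
  n <- nrow(X); ng <- nlevels(g)
  pseudo_F <- function(g) {
    gm <- colMeans(X)
    sst <- sum(sweep(X, 2, gm)^2)
    means <- rowsum(X, g) / as.vector(table(g))
    ssb <- sum(as.vector(table(g)) * rowSums(sweep(means, 2, gm)^2))
    (ssb / (ng - 1)) / ((sst - ssb) / (n - ng))
  }
  f_obs <- pseudo_F(g)
  f_perm <- vapply(seq_len(permutations),
                   function(i) pseudo_F(sample(g)), numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (permutations + 1)
  structure(list(F = f_obs, p = p, permutations = permutations, N = N),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA (first %d PCs): F = %.3f, p = %.4g (%d permutations)\n",
              x$N, x$F, x$p, x$permutations))
  invisible(x)
}

## ---- Mahalanobis distances ------------------------------------------------

# pooled within-group covariance
pooled_covariance <- function(X, g) {
  n <- nrow(X); ng <- nlevels(g)
  S <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    S <- S + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  S / (n - ng)
}

#' Mahalanobis distances between group means
#'
#' Squared Mahalanobis distances between group mean scores in the first-N
#' PC space, scaled by the pooled within-group covariance. Values are
#' reported as `D = sqrt(D2)` by the print method, matching the convention
#' of published distance tables.
#'
#' @inheritParams procrustes_anova
#' @return An object of class `mahalanobis_distances`: `D2` (symmetric,
#'   zero diagonal) and `D`.
#' @export
mahalanobis_distances <- function(scores, groups, N) {
  g <- as_group_factor(groups)
  X <- as.matrix(scores[, seq_len(N), drop = FALSE])
  S <- pooled_covariance(X, g)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled within-group covariance is singular; use a smaller N"))
  means <- rowsum(X, g) / as.vector(table(g))
  ng <- nlevels(g)
  D2 <- matrix(0, ng, ng, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
    d <- means[i, ] - means[j, ]
    D2[i, j] <- D2[j, i] <- drop(d %*% Sinv %*% d)
  }
  structure(list(D2 = D2, D = sqrt(D2), N = N),
            class = "mahalanobis_distances")
}

#' @export
print.mahalanobis_distances <- function(x, digits = 3, ...) {
  cat(sprintf("Mahalanobis distances D (first %d PCs):\n", x$N))
  print(round(x$D, digits))
  invisible(x)
}

## ---- CVA / classification -------------------------------------------------

#' Canonical variates classification with cross-validated accuracy
#'
#' Leave-one-out cross-validated LDA (equal priors) on the first N PC
#' scores gives the overall and per-group correct-classification rates,
#' the confusion matrix and per-specimen posterior probabilities. The
#' confidence interval on the overall accuracy comes from percentile
#' bounds of the LOO accuracy over balanced resampled designs (each group
#' subsampled to the smallest group's size). Mahalanobis distances between
#' group means are computed in the same N-PC space.
#'
#' @inheritParams procrustes_anova
#' @param resamples balanced resamples for the confidence interval
#'   (default 1000).
#' @param ci percentile bounds (default `c(0.025, 0.975)`).
#' @return An object of class `cva_report`: `overall_accuracy`, `ci_low`,
#'   `ci_high` (percent), `per_group_accuracy`, `confusion` (rows = true
#'   groups), `posterior`, `mahalanobis` (a [mahalanobis_distances()]), `N`.
#' @export
cva_classify <- function(scores, groups, N, resamples = 1000L, seed = NULL,
                         ci = c(0.025, 0.975)) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_group_factor(groups)
  if (N > ncol(scores)) stop("N exceeds the number of available PCs")
  X <- as.matrix(scores[, seq_len(N), drop = FALSE])
  fit <- suppressWarnings(
    MASS::lda(X, grouping = g, prior = rep(1 / nlevels(g), nlevels(g)),
              CV = TRUE))
  correct <- fit$class == g
  confusion <- table(true = g, predicted = fit$class)
  acc_res <- vapply(seq_len(resamples), function(r) {
    idx <- balanced_subsample(g)
    loo_lda_accuracy(X[idx, , drop = FALSE], droplevels(g[idx]))
  }, numeric(1))
  ci_b <- stats::quantile(acc_res, ci, names = FALSE)
  structure(list(
    overall_accuracy = 100 * mean(correct),
    ci_low = 100 * ci_b[1], ci_high = 100 * ci_b[2],
    per_group_accuracy = 100 * tapply(correct, g, mean),
    confusion = confusion,
    posterior = fit$posterior,
    mahalanobis = mahalanobis_distances(scores, groups, N),
    N = N, resamples = resamples),
    class = "cva_report")
}

#' @export
print.cva_report <- function(x, ...) {
  cat(sprintf("CVA classification (first %d PCs)\n", x$N))
  cat(sprintf("  overall LOO accuracy: %.1f%% (CI %.1f%%-%.1f%%, %d balanced resamples)\n",
              x$overall_accuracy, x$ci_low, x$ci_high, x$resamples))
  cat("  per group:",
      paste(sprintf("%s %.1f%%", names(x$per_group_accuracy),
                    x$per_group_accuracy), collapse = ", "), "\n")
  cat("  confusion matrix:\n")
  print(x$confusion)
  print(x$mahalanobis)
  invisible(x)
}

#' Predictive assignment of excluded specimens
#'
#' Groups that are too small to classify reliably (for equids, the handful
#' of Przewalski's horses) can be held out of the CVA and assigned
#' afterwards: over repeated balanced subsamples of the training groups an
#' LDA is fitted on the first N training PC scores and each excluded
#' specimen is assigned to a group; the identification probability is the
#' fraction of resampled fits assigning it to that group.
#'
#' @param train_scores PC scores of the training specimens.
#' @param train_groups their group labels.
#' @param new_scores scores of the excluded specimens, in the same PC space
#'   (see [project_scores()]).
#' @param N number of leading PCs.
#' @param resamples number of balanced resampled LDA fits (default 1000).
#' @param seed optional RNG seed.
#' @return A matrix (`excluded specimens x groups`) of identification
#'   probabilities; rows sum to 1.
#' @export
predict_excluded <- function(train_scores, train_groups, new_scores, N,
                             resamples = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_group_factor(train_groups)
  Xtr <- as.matrix(train_scores[, seq_len(N), drop = FALSE])
  Xnew <- as.matrix(new_scores)[, seq_len(N), drop = FALSE]
  votes <- matrix(0L, nrow(Xnew), nlevels(g),
                  dimnames = list(rownames(Xnew), levels(g)))
  for (r in seq_len(resamples)) {
    idx <- balanced_subsample(g)
    fit <- suppressWarnings(
      MASS::lda(Xtr[idx, , drop = FALSE], grouping = droplevels(g[idx]),
                prior = rep(1 / nlevels(g), nlevels(g))))
    pred <- stats::predict(fit, Xnew)$class
    for (i in seq_len(nrow(Xnew)))
      votes[i, as.character(pred[i])] <- votes[i, as.character(pred[i])] + 1L
  }
  votes / resamples
}
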