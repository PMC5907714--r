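# Likelihood-based comparison of cranial modularity hypotheses.
#
# The data enter as a landmark correlation matrix: for every landmark pair
# the congruence coefficient of their coordinate deviation vectors across
# specimens and axes, in absolute value. Competing modularity models
# partition the unique correlations into sets (within-module and
# between-module, pooled or separate according to the model variant); each
# set gets a single correlation parameter rho fitted by maximum likelihood
# under a Gaussian model on Fisher-z transformed correlations, and models
# are ranked by small-sample-corrected AICc.

## ---- correlation matrix ---------------------------------------------------

#' Landmark correlation matrix (congruence coefficients)
#'
#' For each pair of landmarks, the congruence coefficient of their
#' coordinate deviation vectors: deviations from the mean landmark position
#' are stacked across specimens and coordinate axes, and the pair's
#' correlation is their inner product normalized by the product of their
#' norms, taken in absolute value. The diagonal is 1. A `k`-landmark matrix
#' has `k (k - 1) / 2` unique subdiagonal entries (1891 for the 62-landmark
#' cranial scheme).
#'
#' @param coords GPA-aligned coordinates (`k x m x n` array, or a
#'   [gpa()] / [symmetric_component()] result).
#' @return An object of class `landmark_correlations`: `values` (`k x k`,
#'   symmetric, entries in `[0, 1]`), `n_corr`, `sample_size`.
#' @export
landmark_correlation_matrix <- function(coords) {
  if (inherits(coords, "symmetry_decomposition")) coords <- coords$symmetric
  if (inherits(coords, "gpa")) coords <- coords$aligned
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  k <- dim(coords)[1]; m <- dim(coords)[2]; n <- dim(coords)[3]
  if (n < 4) stop("at least 4 specimens are required")
  mean_shape <- apply(coords, c(1, 2), mean)
  dev <- sweep(coords, c(1, 2), mean_shape)
  # rows: landmarks; columns: deviations stacked over axes and specimens
  D <- matrix(aperm(dev, c(1, 2, 3)), nrow = k)
  norms <- sqrt(rowSums(D^2))
  zero <- which(norms < .Machine$double.eps^0.5)
  if (length(zero))
    stop("landmark ", zero[1], " has zero variance across specimens")
  R <- abs(tcrossprod(D / norms))
  diag(R) <- 1
  R <- pmin(R, 1)
  structure(list(values = R, n_corr = k * (k - 1L) / 2L,
                 sample_size = n, k = k),
            class = "landmark_correlations")
}

#' @export
print.landmark_correlations <- function(x, ...) {
  off <- x$values[lower.tri(x$values)]
  cat(sprintf(
    "Landmark correlation matrix: %d landmarks, %d unique correlations (n = %d)\n",
    x$k, x$n_corr, x$sample_size))
  cat(sprintf("  |r|: mean %.3f, range %.3f-%.3f\n", mean(off), min(off),
              max(off)))
  invisible(x)
}

## ---- hypotheses and model set ---------------------------------------------

#' Construct a modularity hypothesis
#'
#' @param name hypothesis name.
#' @param assignment character (or factor) vector of length k mapping each
#'   landmark to a module label; every landmark belongs to exactly one
#'   module.
#' @return An object of class `module_hypothesis`.
#' @export
module_hypothesis <- function(name, assignment) {
  assignment <- as.character(assignment)
  if (anyNA(assignment) || any(!nzchar(assignment)))
    stop("every landmark must be assigned to a module")
  structure(list(name = name, assignment = assignment,
                 modules = sort(unique(assignment)),
                 k = length(assignment)),
            class = "module_hypothesis")
}

#' @export
print.module_hypothesis <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("Modularity hypothesis '%s': %d landmarks, %d modules (%s)\n",
              x$name, x$k, length(tab),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a module-assignment file
#'
#' Two-column plain text: `landmark module`, one line per landmark, `#`
#' comments allowed.
#'
#' @param path path to the file.
#' @param name hypothesis name (default: file name).
#' @return A [module_hypothesis()].
#' @export
read_module_hypothesis <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("landmark", "module"),
                           colClasses = c("integer", "character"))
  assignment <- character(max(tab$landmark))
  assignment[tab$landmark] <- tab$module
  module_hypothesis(name, assignment)
}

#' Bundled cranial modularity hypotheses
#'
#' The four hypotheses evaluated for the 62-landmark equid cranium:
#' tissue origin (neural crest vs paraxial mesoderm), the six mammalian
#' cranial modules (anterior oral-nasal, cranial base, cranial vault,
#' molar, orbit, zygomatic-pterygoid), six functional modules, and a
#' horse-specific face/neurocranium split. The bundled landmark-to-module
#' tables are synthetic reconstructions from the anatomical definitions of
#' the landmarks, shipped as `hypothesis_*_synthetic.txt` under
#' `extdata`; replace them with measured assignment tables where available.
#'
#' @return A named list of four [module_hypothesis()] objects.
#' @export
cranium_hypotheses <- function() {
  files <- c(tissue_origin = "hypothesis_tissue_origin_synthetic.txt",
             six_modules = "hypothesis_goswami_six_modules_synthetic.txt",
             functional = "hypothesis_functional_modules_synthetic.txt",
             horse_specific = "hypothesis_horse_specific_synthetic.txt")
  out <- lapply(names(files), function(nm)
    read_module_hypothesis(system.file("extdata", files[[nm]],
                                       package = "morphomod",
                                       mustWork = TRUE), name = nm))
  stats::setNames(out, names(files))
}

# Partition the unique correlation entries (i < j) of a k x k matrix into
# the sets implied by one model. Returns a named list of index vectors
# into the lower-triangle entries, dropping sets with no members.
model_correlation_sets <- function(hypothesis, variant, k) {
  pairs <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)  # row > col
  mod_i <- hypothesis$assignment[pairs[, 1]]
  mod_j <- hypothesis$assignment[pairs[, 2]]
  within <- mod_i == mod_j
  lab <- switch(variant,
    null = rep("all", nrow(pairs)),
    a = ifelse(within, "within", "between"),
    b = ifelse(within, "within",
               paste0("between.", pmin(mod_i, mod_j), "-", pmax(mod_i, mod_j))),
    c = ifelse(within, paste0("within.", mod_i), "between"),
    d = ifelse(within, paste0("within.", mod_i),
               paste0("between.", pmin(mod_i, mod_j), "-", pmax(mod_i, mod_j))),
    stop("unknown variant: ", variant))
  split(seq_len(nrow(pairs)), lab)
}

#' Build the standard modularity model set
#'
#' Expands each hypothesis into its four variants -- (a) pooled
#' within-module and pooled between-module correlation, (b) pooled within /
#' separate between-module-pair, (c) separate within / pooled between,
#' (d) separate within and between -- and adds the no-modularity null
#' (one correlation for everything). Four hypotheses yield the standard
#' 17-model comparison.
#'
#' @param hypotheses a list of [module_hypothesis()] objects.
#' @return A list of model specifications (`hypothesis`, `variant`, `name`).
#' @export
build_model_set <- function(hypotheses) {
  if (inherits(hypotheses, "module_hypothesis"))
    hypotheses <- list(hypotheses)
  models <- list(list(hypothesis = NULL, variant = "null",
                      name = "no_modularity"))
  for (h in hypotheses) for (v in c("a", "b", "c", "d"))
    models[[length(models) + 1L]] <-
      list(hypothesis = h, variant = v, name = paste0(h$name, ".", v))
  models
}

## ---- EMMLi-style likelihood fit -------------------------------------------

# Maximized Gaussian log-likelihood of Fisher-z correlations in one set,
# with rho on a grid. Returns list(rho, logL).
fit_rho_set <- function(z, sd_z, grid_rho, grid_z) {
  # sum over the set of dnorm(z_i; z_rho, sd): expand the quadratic once
  n <- length(z); sz <- sum(z); szz <- sum(z^2)
  ss <- szz - 2 * grid_z * sz + n * grid_z^2
  ll <- -n * log(sd_z * sqrt(2 * pi)) - ss / (2 * sd_z^2)
  best <- which.max(ll)
  list(rho = grid_rho[best], logL = ll[best])
}

#' Maximum-likelihood comparison of modularity models
#'
#' Fits every model in `models` to a landmark correlation matrix. Each
#' model partitions the unique correlations into sets; per set a single
#' correlation parameter rho is estimated by maximizing the Gaussian
#' likelihood of the Fisher-z transformed correlations (standard deviation
#' `1 / sqrt(n_like - 3)`, rho on a grid over `[0, 0.995]` in steps of
#' 0.001). The model log-likelihood sums over all correlations;
#' `K = (number of rho parameters) + 1`, and
#' `AICc = -2 logL + 2K + 2K(K+1) / (n_corr - K - 1)` with the number of
#' unique correlations as the sample size.
#'
#' @param corr a [landmark_correlation_matrix()] result, or a bare
#'   correlation matrix.
#' @param models a model list from [build_model_set()] (or a list of
#'   [module_hypothesis()] objects, expanded automatically).
#' @param n_like sample size for the Fisher-z likelihood (default: the
#'   specimen count carried by `corr`).
#' @return An object of class `emmli_fit`: `table` (one row per model with
#'   K, logL, AICc, dAICc, sorted by AICc), `rho` (per-model named lists of
#'   fitted correlations), `best` (name of the dAICc = 0 model).
#' @export
emmli_fit <- function(corr, models, n_like = NULL) {
  if (inherits(corr, "landmark_correlations")) {
    R <- corr$values
    if (is.null(n_like)) n_like <- corr$sample_size
  } else {
    R <- as.matrix(corr)
    if (is.null(n_like))
      stop("n_like must be given when corr is a bare matrix")
  }
  k <- nrow(R)
  if (inherits(models, "module_hypothesis") ||
      (is.list(models) && length(models) &&
       inherits(models[[1]], "module_hypothesis")))
    models <- build_model_set(models)
  r <- R[lower.tri(R)]
  n_corr <- length(r)
  z <- atanh(pmin(r, 0.999999))
  sd_z <- 1 / sqrt(n_like - 3)
  grid_rho <- seq(0, 0.995, by = 0.001)
  grid_z <- atanh(grid_rho)
  rows <- vector("list", length(models))
  rho_all <- vector("list", length(models))
  for (i in seq_along(models)) {
    mod <- models[[i]]
    if (mod$variant != "null" && mod$hypothesis$k != k)
      stop("hypothesis '", mod$hypothesis$name, "' covers ",
           mod$hypothesis$k, " landmarks, matrix has ", k)
    sets <- model_correlation_sets(mod$hypothesis, mod$variant, k)
    fits <- lapply(sets, function(idx)
      fit_rho_set(z[idx], sd_z, grid_rho, grid_z))
    K <- length(sets) + 1L
    if (K >= n_corr - 1L)
      stop("model '", mod$name, "': K = ", K,
           " too large for ", n_corr, " correlations (AICc undefined)")
    logL <- sum(vapply(fits, `[[`, numeric(1), "logL"))
    rows[[i]] <- data.frame(model = mod$name, K = K, logL = logL,
                            AICc = -2 * logL + 2 * K +
                              2 * K * (K + 1) / (n_corr - K - 1))
    rho_all[[i]] <- vapply(fits, `[[`, numeric(1), "rho")
  }
  tab <- do.call(rbind, rows)
  names(rho_all) <- tab$model
  tab$dAICc <- tab$AICc - min(tab$AICc)
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, rho = rho_all[ord], best = tab$model[1],
                 n_corr = n_corr, n_like = n_like),
            class = "emmli_fit")
}

#' @export
print.emmli_fit <- function(x, ...) {
  cat(sprintf("Modularity model comparison (%d correlations, likelihood n = %d)\n",
              x$n_corr, x$n_like))
  tab <- x$table
  tab$logL <- round(tab$logL, 2); tab$AICc <- round(tab$AICc, 2)
  tab$dAICc <- round(tab$dAICc, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

## ---- integration and module disparity -------------------------------------

#' Eigenvalue dispersion (relative eigenvalue standard deviation)
#'
#' Integration magnitude of a correlation matrix: the standard deviation of
#' its eigenvalues relative to the maximum attainable,
#' `psi = sqrt(sum((lambda - mean(lambda))^2) / p) / (mean(lambda) * sqrt(p - 1))`.
#' `psi = 0` when all eigenvalues are equal (no integration) and 1 when a
#' single eigenvalue carries all variance (complete integration).
#'
#' @param R a correlation matrix (p >= 2 variables), or a
#'   [landmark_correlation_matrix()] result.
#' @return A scalar in `[0, 1]`.
#' @export
eigenvalue_dispersion <- function(R) {
  if (inherits(R, "landmark_correlations")) R <- R$values
  R <- as.matrix(R)
  p <- nrow(R)
  if (p < 2) stop("eigenvalue dispersion needs at least 2 variables")
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lbar <- mean(lambda)
  sqrt(sum((lambda - lbar)^2) / p) / (lbar * sqrt(p - 1))
}

#' Module disparity (Procrustes distances to the module consensus)
#'
#' After module-wise superimposition, the Procrustes distance of every
#' specimen's module configuration to the module consensus; both the
#' maximum and the mean are reported (the comparison tables default to the
#' maximum).
#'
#' @param module_coords `k_mod x m x n` module coordinates, already
#'   superimposed (see [module_integration()] for the full per-module
#'   pipeline), or a [gpa()] result.
#' @return A named numeric vector `c(max = , mean = )`.
#' @export
module_disparity <- function(module_coords) {
  if (inherits(module_coords, "gpa")) module_coords <- module_coords$aligned
  n <- dim(module_coords)[3]
  consensus <- apply(module_coords, c(1, 2), mean)
  d <- vapply(seq_len(n), function(i)
    sqrt(sum((module_coords[, , i] - consensus)^2)), numeric(1))
  c(max = max(d), mean = mean(d))
}

#' Per-module integration and disparity
#'
#' For every module of a hypothesis: extract the module's landmarks from
#' the raw (or symmetric) configurations, re-superimpose them with their
#' own GPA, and compute the eigenvalue dispersion of the module's landmark
#' correlation matrix together with the module disparity.
#'
#' @param coords `k x m x n` coordinates (raw or aligned; each module is
#'   re-superimposed), or a dataset/gpa/symmetry object.
#' @param hypothesis a [module_hypothesis()].
#' @return An object of class `integration_report`: data frame with one
#'   row per module (`module`, `landmarks`, `psi`, `disparity_max`,
#'   `disparity_mean`) plus `average_psi` and `median_psi`.
#' @export
module_integration <- function(coords, hypothesis) {
  if (inherits(coords, "landmark_dataset")) coords <- coords$coords
  if (inherits(coords, "symmetry_decomposition")) coords <- coords$symmetric
  if (inherits(coords, "gpa")) coords <- coords$aligned
  stopifnot(inherits(hypothesis, "module_hypothesis"))
  if (dim(coords)[1] != hypothesis$k)
    stop("hypothesis covers ", hypothesis$k, " landmarks, data have ",
         dim(coords)[1])
  if (dim(coords)[3] < 3) stop("at least 3 specimens are required")
  rows <- lapply(hypothesis$modules, function(mod) {
    idx <- which(hypothesis$assignment == mod)
    if (length(idx) < 2)
      stop("module '", mod, "' has fewer than 2 landmarks")
    g <- gpa(coords[idx, , , drop = FALSE])
    psi <- eigenvalue_dispersion(landmark_correlation_matrix(g))
    disp <- module_disparity(g)
    data.frame(module = mod, landmarks = length(idx), psi = psi,
               disparity_max = disp["max"], disparity_mean = disp["mean"])
  })
  per_module <- do.call(rbind, rows)
  rownames(per_module) <- NULL
  structure(list(per_module = per_module,
                 average_psi = mean(per_module$psi),
                 median_psi = stats::median(per_module$psi),
                 hypothesis = hypothesis$name),
            class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  cat(sprintf("Module integration/disparity (hypothesis '%s')\n",
              x$hypothesis))
  df <- x$per_module
  df$psi <- round(df$psi, 3)
  df$disparity_max <- signif(df$disparity_max, 3)
  df$disparity_mean <- signif(df$disparity_mean, 3)
  print(df, row.names = FALSE)
  cat(sprintf("  psi: average %.3f, median %.3f\n", x$average_psi,
              x$median_psi))
  invisible(x)
}

#' Compare module integration between wild and domesticated subsets
#'
#' Splits the specimens into two pools (for equids: domesticated horses H
#' versus the wild P/D/Z), and computes [module_integration()] for each
#' pool under the same modularity hypothesis.
#'
#' @param coords coordinates as in [module_integration()].
#' @param groups group labels, one per specimen.
#' @param hypothesis a [module_hypothesis()] (normally the best-supported
#'   model's hypothesis).
#' @param wild_groups,domestic_groups group labels forming each pool
#'   (defaults `c("P", "D", "Z")` and `"H"`).
#' @return A list of class `wild_domestic_comparison` with elements
#'   `domestic` and `wild` ([module_integration()] reports) and `summary`.
#' @export
compare_wild_domestic <- function(coords, groups, hypothesis,
                                  wild_groups = c("P", "D", "Z"),
                                  domestic_groups = "H") {
  if (inherits(coords, "landmark_dataset")) {
    if (is.null(groups)) groups <- coords$meta$group
    coords <- coords$coords
  }
  if (inherits(coords, "symmetry_decomposition")) coords <- coords$symmetric
  if (inherits(coords, "gpa")) coords <- coords$aligned
  groups <- as.character(groups)
  take <- function(pool) {
    idx <- which(groups %in% pool)
    if (length(idx) < 3)
      stop("subset {", paste(pool, collapse = ","),
           "} has fewer than 3 specimens")
    module_integration(coords[, , idx, drop = FALSE], hypothesis)
  }
  dom <- take(domestic_groups)
  wld <- take(wild_groups)
  summary <- data.frame(
    subset = c("domestic", "wild"),
    n = c(sum(groups %in% domestic_groups), sum(groups %in% wild_groups)),
    average_psi = c(dom$average_psi, wld$average_psi),
    median_psi = c(dom$median_psi, wld$median_psi),
    average_disparity_max = c(mean(dom$per_module$disparity_max),
                              mean(wld$per_module$disparity_max)))
  structure(list(domestic = dom, wild = wld, summary = summary),
            class = "wild_domestic_comparison")
}

#' @export
print.wild_domestic_comparison <- function(x, ...) {
  print(x$domestic); print(x$wild)
  cat("Summary:\n")
  df <- x$summary
  df[, 3:5] <- round(df[, 3:5], 3)
  print(df, row.names = FALSE)
  invisible(x)
}
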