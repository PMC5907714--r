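# End-to-end orchestration of the study workflow: read/simulate ->
# (merge views) -> GPA -> symmetry decomposition -> PCA -> dimensionality
# selection -> Procrustes ANOVA -> CVA / predictive assignment ->
# disparity -> modularity. Every stochastic stage is seeded; the run is
# summarized by a machine-readable manifest so that replaying a config
# reproduces the bundle bit for bit.

#' Run the full morphometric pipeline
#'
#' Executes all stages applicable to the structure under study. Bilaterally
#' symmetric structures (cranium, mandible) are symmetrised after GPA and
#' all downstream analyses run on the symmetric component; tooth data
#' (2D, no object symmetry) skip the symmetrisation. Groups below
#' `exclude_below` specimens are excluded from the classification and
#' assigned afterwards by predictive LDA.
#'
#' @param dataset a [landmark_dataset()]; alternatively `config$simulate`
#'   may hold a [simulation_config()] to generate one.
#' @param config a list of settings:
#'   \describe{
#'     \item{structure}{`"cranium"`, `"mandible"` or `"tooth"`.}
#'     \item{pairing}{a [pairing_scheme()] (required unless tooth).}
#'     \item{hypotheses}{list of [module_hypothesis()] for the modularity
#'       stage (cranium only by default; `NULL` skips the stage).}
#'     \item{groups}{group labels (default: dataset metadata `group`).}
#'     \item{N_anova, N_cva}{PC-count overrides; default: the
#'       cross-validated selection.}
#'     \item{max_N, resamples, permutations}{stage parameters.}
#'     \item{exclude_below}{minimum group size for the CVA (default 6).}
#'     \item{wild_groups, domestic_groups}{pools for the integration
#'       comparison.}
#'     \item{seed}{master seed (default 1).}
#'     \item{out_dir}{if non-NULL, CSV/JSON outputs and a run manifest are
#'       written there.}
#'   }
#' @return A list of class `pipeline_result` with every stage's result
#'   (`gpa`, `symmetry`, `pca`, `selection`, `anova`, `cva`, `excluded`,
#'   `disparity`, `modularity`, `integration`) plus the `manifest`.
#' @export
run_pipeline <- function(dataset = NULL, config = list()) {
  defaults <- list(structure = "cranium", pairing = NULL, hypotheses = NULL,
                   groups = NULL, N_anova = NULL, N_cva = NULL,
                   max_N = 20L, resamples = 200L, permutations = 999L,
                   exclude_below = 6L, wild_groups = c("P", "D", "Z"),
                   domestic_groups = "H", seed = 1L, out_dir = NULL,
                   simulate = NULL)
  config <- utils::modifyList(defaults, config)
  symmetrise <- config$structure %in% c("cranium", "mandible")
  if (config$structure == "tooth" && !is.null(config$pairing))
    stop("tooth runs must not request symmetrisation")
  stage <- function(name, ...) message(sprintf("[%s] %s", name, sprintf(...)))

  if (is.null(dataset)) {
    if (is.null(config$simulate))
      stop("either a dataset or config$simulate must be provided")
    dataset <- generate_dataset(config$simulate)
    stage("simulate", "n=%d k=%d m=%d seed=%d", dataset$n, dataset$k,
          dataset$m, config$simulate$seed)
  }
  groups <- config$groups
  if (is.null(groups)) {
    if (is.null(dataset$meta) || is.null(dataset$meta$group))
      stop("no group labels: supply config$groups or dataset metadata")
    groups <- dataset$meta$group
  }
  groups <- as.character(groups)

  g_res <- gpa(dataset)
  stage("gpa", "converged=%s iterations=%d", g_res$converged,
        g_res$iterations)

  if (symmetrise) {
    if (is.null(config$pairing))
      stop(config$structure, " runs must supply a pairing scheme")
    sym <- symmetric_component(g_res, config$pairing)
    shape_coords <- sym$symmetric
    stage("symmetrise", "asymmetric SS=%.4g", sum(sym$asymmetric^2))
  } else {
    sym <- NULL
    shape_coords <- g_res$aligned
  }

  pca <- shape_pca(if (symmetrise) sym else g_res)
  stage("pca", "PC1-3=%.1f%%", 100 * sum(pca$variance_fractions[1:3]))

  gtab <- table(groups)
  small <- names(gtab)[gtab < config$exclude_below]
  train <- !(groups %in% small)
  train_groups <- groups[train]

  sel <- select_dimensions(pca$scores[train, , drop = FALSE], train_groups,
                           max_N = config$max_N,
                           resamples = config$resamples,
                           seed = config$seed + 1L)
  stage("select-n", "chosen N=%d", sel$chosen_N)
  N_anova <- if (is.null(config$N_anova)) sel$chosen_N else config$N_anova
  N_cva <- if (is.null(config$N_cva)) sel$chosen_N else config$N_cva

  anova <- procrustes_anova(pca$scores[train, , drop = FALSE], train_groups,
                            N = N_anova, permutations = config$permutations,
                            seed = config$seed + 2L)
  stage("anova", "F=%.3f p=%.4g (N=%d)", anova$F, anova$p, N_anova)

  cva <- cva_classify(pca$scores[train, , drop = FALSE], train_groups,
                      N = N_cva, resamples = config$resamples,
                      seed = config$seed + 3L)
  stage("classify", "accuracy=%.1f%% (N=%d)", cva$overall_accuracy, N_cva)

  excluded <- NULL
  if (length(small) && any(!train)) {
    excluded <- predict_excluded(pca$scores[train, , drop = FALSE],
                                 train_groups,
                                 pca$scores[!train, , drop = FALSE],
                                 N = N_cva, resamples = config$resamples,
                                 seed = config$seed + 4L)
    stage("predict", "%d excluded specimens from groups {%s}",
          sum(!train), paste(small, collapse = ","))
  }

  disparity <- partial_disparity(shape_coords, groups)
  stage("disparity", "total variance=%.4g", disparity$total_variance)

  modularity <- NULL; integration <- NULL
  if (!is.null(config$hypotheses)) {
    corr <- landmark_correlation_matrix(shape_coords)
    modularity <- emmli_fit(corr, build_model_set(config$hypotheses))
    stage("modularity", "best model=%s", modularity$best)
    best_hyp_name <- sub("\\.[abcd]$", "", modularity$best)
    hyp_names <- vapply(config$hypotheses, `[[`, "", "name")
    if (best_hyp_name %in% hyp_names) {
      best_hyp <- config$hypotheses[[match(best_hyp_name, hyp_names)]]
      integration <- compare_wild_domestic(shape_coords, groups, best_hyp,
                                           wild_groups = config$wild_groups,
                                           domestic_groups =
                                             config$domestic_groups)
      stage("integration", "psi domestic=%.3f wild=%.3f",
            integration$summary$average_psi[1],
            integration$summary$average_psi[2])
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("morphomod")),
    structure = config$structure, n = dataset$n, k = dataset$k,
    m = dataset$m, seed = config$seed, max_N = config$max_N,
    resamples = config$resamples, permutations = config$permutations,
    N_anova = N_anova, N_cva = N_cva, excluded_groups = small)

  result <- structure(
    list(dataset = dataset, gpa = g_res, symmetry = sym, pca = pca,
         selection = sel, anova = anova, cva = cva, excluded = excluded,
         disparity = disparity, modularity = modularity,
         integration = integration, manifest = manifest),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result,
                                                       config$out_dir)
  result
}

# write the tabular/JSON bundle for a pipeline run
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(result$disparity$partial, p("partial_disparity.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$cva$confusion), p("confusion.csv"),
                   row.names = FALSE)
  utils::write.csv(result$cva$mahalanobis$D, p("mahalanobis_D.csv"))
  utils::write.csv(result$selection$accuracy_by_N, p("dimension_selection.csv"),
                   row.names = FALSE)
  if (!is.null(result$modularity))
    utils::write.csv(result$modularity$table, p("modularity_models.csv"),
                     row.names = FALSE)
  if (!is.null(result$integration))
    utils::write.csv(rbind(cbind(subset = "domestic",
                                 result$integration$domestic$per_module),
                           cbind(subset = "wild",
                                 result$integration$wild$per_module)),
                     p("module_integration.csv"), row.names = FALSE)
  report <- list(
    anova = list(F = result$anova$F, p = result$anova$p,
                 N = result$anova$N),
    classification = list(overall = result$cva$overall_accuracy,
                          ci = c(result$cva$ci_low, result$cva$ci_high),
                          per_group = as.list(result$cva$per_group_accuracy)),
    excluded_posteriors = if (!is.null(result$excluded))
      as.data.frame(result$excluded),
    total_variance = result$disparity$total_variance,
    chosen_N = result$selection$chosen_N)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (", x$manifest$structure, "): n=", x$manifest$n,
      " k=", x$manifest$k, " m=", x$manifest$m, "\n", sep = "")
  print(x$selection); print(x$anova); print(x$cva); print(x$disparity)
  if (!is.null(x$modularity)) print(x$modularity)
  if (!is.null(x$integration)) print(x$integration$summary)
  invisible(x)
}

#' Recompute the published study statistics from the deposited data
#'
#' When the study's deposited landmark tables and module-assignment file
#' are available locally, this runs the full cranial (and optionally
#' mandibular) analysis on them and returns the headline statistics
#' (PC variance fractions, Procrustes variances, Foote partial
#' disparities, classification accuracies, best modularity model and its
#' AICc/logL, per-module integration). The data are not bundled with the
#' package; point `data_dir` at a directory containing
#' `cranium_landmarks.csv`, `mandible_landmarks.csv` (wide tables readable
#' by [read_landmark_table()]) and `module_assignments.txt`.
#'
#' @param data_dir directory holding the deposited files.
#' @param seed RNG seed for the resampled stages.
#' @return A nested list of computed statistics.
#' @export
reproduce_study_values <- function(data_dir, seed = 1L) {
  need <- file.path(data_dir, c("cranium_landmarks.csv",
                                "mandible_landmarks.csv"))
  if (!all(file.exists(need)))
    stop("deposited landmark tables not found under ", data_dir)
  cranium <- read_landmark_table(need[1], dims = 3)
  mandible <- read_landmark_table(need[2], dims = 3)
  hyp_file <- file.path(data_dir, "module_assignments.txt")
  hypotheses <- if (file.exists(hyp_file))
    list(read_module_hypothesis(hyp_file, "six_modules"))
  else cranium_hypotheses()
  cr <- run_pipeline(cranium, list(structure = "cranium",
                                   pairing = cranium_pairing(),
                                   hypotheses = hypotheses, seed = seed))
  md <- run_pipeline(mandible, list(structure = "mandible",
                                    pairing = mandible_pairing(),
                                    seed = seed))
  list(
    cranium = list(
      pc_fractions = cr$pca$variance_fractions[1:3],
      total_variance = cr$disparity$total_variance,
      partial_disparity = cr$disparity$partial,
      accuracy = cr$cva$overall_accuracy,
      best_model = cr$modularity$best,
      model_table = cr$modularity$table,
      integration = cr$integration$summary),
    mandible = list(
      total_variance = md$disparity$total_variance,
      partial_disparity = md$disparity$partial,
      accuracy = md$cva$overall_accuracy))
}
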