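# Synthetic landmark data with the statistical structure the analyses
# assume: bilaterally symmetric mean shapes, group mean offsets, modular
# (block-correlated) symmetric shape deviations, and independent
# asymmetric noise, digitized in an arbitrary frame (random rigid motion
# and scale per specimen) so that superimposition is genuinely exercised.

#' Configuration for the synthetic landmark generator
#'
#' @param k number of landmarks.
#' @param m dimension (2 or 3).
#' @param pairing a [pairing_scheme()]; by default a scheme with
#'   `floor(k/2)` bilateral pairs and the rest midline.
#' @param groups data frame with columns `label`, `n`, `offset` (magnitude
#'   of the group's symmetric mean-shape offset, in units of the
#'   unit-centroid-size base shape) and optionally `family` (groups in one
#'   family share an offset direction). Default: one group of 20, offset 0.
#' @param module_map integer/character vector of length k assigning each
#'   landmark to a module (default: six blocks of bilateral pairs, echoing
#'   the six-module cranial structure, with mirrored pairs kept together
#'   and midline landmarks in the last block; fewer blocks when there are
#'   fewer pairs).
#' @param rho_within,rho_between compound-symmetry correlations of the
#'   landmark deviations within and between modules; modular structure
#'   requires `rho_within > rho_between`.
#' @param noise_sd standard deviation of the (symmetric) landmark
#'   deviations.
#' @param asymmetry_sd standard deviation of the independent asymmetric
#'   coordinate noise (0 = perfectly symmetric shapes).
#' @param seed RNG seed; the generated dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(k = 20L, m = 3L, pairing = NULL, groups = NULL,
                              module_map = NULL, rho_within = 0.6,
                              rho_between = 0.2, noise_sd = 0.02,
                              asymmetry_sd = 0.005, seed = 1L) {
  k <- as.integer(k); m <- as.integer(m)
  if (is.null(pairing)) {
    npair <- k %/% 2L
    pairing <- pairing_scheme(cbind(seq_len(npair), npair + seq_len(npair)),
                              if (2L * npair < k) (2L * npair + 1L):k
                              else integer(0), k)
  }
  if (pairing$k != k) stop("pairing scheme does not cover k landmarks")
  if (is.null(groups))
    groups <- data.frame(label = "A", n = 20L, offset = 0)
  stopifnot(all(c("label", "n", "offset") %in% names(groups)),
            all(groups$n >= 1))
  if (is.null(module_map)) {
    # three blocks of bilateral pairs (midline landmarks join the last);
    # with only two modules Procrustes centring aliases the two module
    # factors into one +/- contrast and the |r| block signal vanishes
    np <- nrow(pairing$paired)
    # at least two pairs per block: one-pair modules carry no shape
    # variation of their own once re-superimposed
    nb <- max(2L, min(6L, np %/% 2L))
    block <- max(1L, ceiling(np / nb))
    module_map <- rep(paste0("M", nb), k)  # midline joins the last block
    for (r in seq_len(np))
      module_map[pairing$paired[r, ]] <-
        paste0("M", min(1L + (r - 1L) %/% block, nb))
  }
  if (length(module_map) != k) stop("module_map must have length k")
  if (rho_within <= rho_between)
    warning("rho_within <= rho_between: generated data are not modular")
  structure(list(k = k, m = m, pairing = pairing, groups = groups,
                 module_map = as.character(module_map),
                 rho_within = rho_within, rho_between = rho_between,
                 noise_sd = noise_sd, asymmetry_sd = asymmetry_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' The bundled equid preset
#'
#' Mimics the cranial study design: 62 landmarks in 3D with the cranial
#' bilateral pairing, four groups with strongly unbalanced sizes
#' (H 133, Z 47, D 31, P 5), six modules following the mammalian
#' six-module hypothesis, and stronger within- than between-module
#' correlation. Group mean offsets give the four groups distinct mean
#' shapes of realistic magnitude (a few percent of centroid size), with
#' the two caballine groups (H, P) closest together.
#'
#' @param seed RNG seed.
#' @return A [simulation_config()].
#' @export
equid_preset <- function(seed = 1L) {
  hyp <- cranium_hypotheses()$six_modules
  simulation_config(
    k = 62L, m = 3L, pairing = cranium_pairing(),
    groups = data.frame(label = c("H", "Z", "D", "P"),
                        n = c(133L, 47L, 31L, 5L),
                        offset = c(0.012, 0.014, 0.012, 0.005),
                        family = c("caballine", "Z", "D", "caballine")),
    module_map = hyp$assignment,
    rho_within = 0.6, rho_between = 0.2,
    noise_sd = 0.005, asymmetry_sd = 0.00125, seed = seed)
}

# symmetric base shape: paired landmarks mirrored across {axis1 = 0},
# midline landmarks on the plane
symmetric_base_shape <- function(k, m, pairing) {
  base <- matrix(NA_real_, k, m)
  for (r in seq_len(nrow(pairing$paired))) {
    v <- c(stats::runif(1, 0.2, 1), stats::rnorm(m - 1))
    base[pairing$paired[r, 1], ] <- v
    v[1] <- -v[1]
    base[pairing$paired[r, 2], ] <- v
  }
  for (i in pairing$midline) base[i, ] <- c(0, stats::rnorm(m - 1))
  base <- sweep(base, 2, colMeans(base))
  base / sqrt(sum(base^2))
}

# Cholesky factor of the block compound-symmetry landmark correlation
block_correlation_chol <- function(module_map, rho_within, rho_between) {
  k <- length(module_map)
  C <- matrix(rho_between, k, k)
  for (mod in unique(module_map)) {
    idx <- module_map == mod
    C[idx, idx] <- rho_within
  }
  diag(C) <- 1
  chol(C)
}

# project a deviation field onto the reflection-invariant subspace
symmetrize_field <- function(D, pairing, axis = 1L) {
  (D + reflect_relabel(D, pairing, axis)) / 2
}

#' Generate a synthetic landmark dataset
#'
#' Builds a symmetric base shape respecting the pairing scheme, adds a
#' symmetric mean-shape offset per group, draws per-specimen shape
#' deviations with block (modular) landmark correlation projected onto the
#' symmetric subspace, adds independent asymmetric coordinate noise, and
#' finally "digitizes" each specimen in its own frame (random rotation,
#' translation and scale). Deterministic given the configuration seed.
#'
#' @param config a [simulation_config()].
#' @return A [landmark_dataset()] with metadata columns `specimen_id` and
#'   `group` (plus decoded ID-string fields styled like museum records).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  k <- config$k; m <- config$m; pairing <- config$pairing
  base <- symmetric_base_shape(k, m, pairing)
  L <- block_correlation_chol(config$module_map, config$rho_within,
                              config$rho_between)
  glabs <- as.character(config$groups$label)
  # groups in the same family share their mean-offset direction (e.g. the
  # caballine horses), scaled by each group's own offset magnitude
  fams <- if ("family" %in% names(config$groups))
    as.character(config$groups$family) else glabs
  fam_dirs <- lapply(unique(fams), function(f) {
    O <- symmetrize_field(matrix(stats::rnorm(k * m), k, m), pairing)
    O / sqrt(sum(O^2))
  })
  names(fam_dirs) <- unique(fams)
  offsets <- lapply(seq_along(glabs), function(gi)
    fam_dirs[[fams[gi]]] * config$groups$offset[gi])
  n <- sum(config$groups$n)
  coords <- array(NA_real_, c(k, m, n))
  group <- character(n)
  ids <- character(n)
  museums <- names(id_code_tables()$museum)
  horse_breeds <- setdiff(names(id_code_tables()$breed), "aaa")
  i <- 0L
  for (gi in seq_along(glabs)) {
    for (j in seq_len(config$groups$n[gi])) {
      i <- i + 1L
      group[i] <- glabs[gi]
      # symmetric modular deviation field
      D <- crossprod(L, matrix(stats::rnorm(k * m), k, m)) * config$noise_sd
      D <- symmetrize_field(D, pairing, 1L)
      shape <- base + offsets[[gi]] + D +
        matrix(stats::rnorm(k * m, sd = config$asymmetry_sd), k, m)
      # arbitrary digitizing frame
      Q <- optimal_rotation(matrix(stats::rnorm(m * m), m, m), diag(m))
      s <- exp(stats::rnorm(1, log(100), 0.1))
      t_vec <- stats::rnorm(m, sd = 50)
      coords[, , i] <- sweep(s * shape %*% Q, 2, t_vec, `+`)
      grp <- glabs[gi]
      id_grp <- if (grp %in% c("H", "D", "P", "Z")) grp else "Z"
      breed <- if (id_grp == "H") sample(horse_breeds, 1) else "aaa"
      morph <- if (id_grp == "H") sample(c("W", "F", "C", "P"), 1) else "A"
      ids[i] <- paste(sample(museums, 1), sprintf("%04d", i), id_grp,
                      breed, morph, sep = "_")
    }
  }
  meta <- data.frame(specimen_id = ids, group = group,
                     stringsAsFactors = FALSE)
  landmark_dataset(coords, ids = ids, meta = meta)
}

#' Split a dataset into dorsal and ventral digitizing views
#'
#' Emulates two-session digitizing: each configuration is split into two
#' overlapping views sharing the reference landmarks, and the ventral view
#' is expressed in its own frame via a random rigid transform. The
#' ground-truth transforms are returned so that [merge_views()] can be
#' validated against them.
#'
#' @param dataset a [landmark_dataset()].
#' @param dorsal_ids,ventral_ids global landmark numbers of each view
#'   (defaults: first/second half, both extended by `ref_ids`).
#' @param ref_ids reference landmarks shared by both views (>= 3).
#' @param seed optional RNG seed for the ventral-frame transforms.
#' @return A list with per-specimen lists `dorsal`, `ventral` (coordinate
#'   matrices), `dorsal_ids`, `ventral_ids`, `ref_ids`, and `truth`
#'   (per-specimen `rotation`/`translation` carrying the ventral frame
#'   into the dorsal frame).
#' @export
generate_two_view <- function(dataset, dorsal_ids = NULL, ventral_ids = NULL,
                              ref_ids = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (!is.null(seed)) set.seed(seed)
  k <- dataset$k; m <- dataset$m
  if (is.null(ref_ids)) ref_ids <- if (k >= 33) c(1L, 2L, 33L) else 1:3
  if (is.null(dorsal_ids))
    dorsal_ids <- sort(unique(c(seq_len(k %/% 2), ref_ids)))
  if (is.null(ventral_ids))
    ventral_ids <- sort(unique(c((k %/% 2 + 1L):k, ref_ids)))
  shared <- intersect(dorsal_ids, ventral_ids)
  if (length(intersect(ref_ids, shared)) < 3L)
    stop("views share fewer than 3 reference landmarks")
  n <- dataset$n
  dorsal <- ventral <- truth <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- dataset$coords[, , i]
    Q <- optimal_rotation(matrix(stats::rnorm(m * m), m, m), diag(m))
    t_vec <- stats::rnorm(m, sd = 25)
    dorsal[[i]] <- cc[dorsal_ids, , drop = FALSE]
    # ventral view stored in its own digitizing frame
    ventral[[i]] <- sweep(cc[ventral_ids, , drop = FALSE] %*% Q, 2, t_vec, `+`)
    # merge_views should recover the inverse map (Q^T, -t Q^T)
    truth[[i]] <- list(rotation = t(Q),
                       translation = -as.vector(t_vec %*% t(Q)))
  }
  list(dorsal = dorsal, ventral = ventral, dorsal_ids = dorsal_ids,
       ventral_ids = ventral_ids, ref_ids = ref_ids, truth = truth,
       ids = dataset$ids)
}
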