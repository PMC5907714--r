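# Shared fixtures: tiny configurations and quick synthetic datasets.

# right triangle and a vertically stretched copy; classic superimposition
# test pair
triangle_A <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
triangle_B <- matrix(c(0, 0, 1, 0, 0, 2), ncol = 2, byrow = TRUE)

# apply a random similarity transform (rotation, translation, scale) to a
# k x m configuration
random_similarity <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(x)
  Q <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  s <- exp(rnorm(1, 0, 0.5))
  t_vec <- rnorm(m, sd = 5)
  sweep(s * x %*% Q, 2, t_vec, `+`)
}

# small bilaterally symmetric dataset for symmetry/ordination tests
quick_sym_dataset <- function(n_per = c(A = 8, B = 8), k = 12, m = 3,
                              offset = 0.05, seed = 1, asymmetry_sd = 0.005) {
  cfg <- simulation_config(
    k = k, m = m, seed = seed,
    groups = data.frame(label = names(n_per), n = as.integer(n_per),
                        offset = rep(offset, length(n_per))),
    noise_sd = 0.02, asymmetry_sd = asymmetry_sd)
  list(config = cfg, dataset = generate_dataset(cfg))
}

# brute-force partial Procrustes distance between two 2D configurations:
# centre, scale to unit size, minimize over a fine grid of rotation angles
grid_procrustes_distance_2d <- function(a, b, n_grid = 20000) {
  pre <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- pre(a); b <- pre(b)
  th <- seq(0, 2 * pi, length.out = n_grid)
  best <- Inf
  for (t in th) {
    R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
    best <- min(best, sum((a %*% R - b)^2))
  }
  sqrt(best)
}
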