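# Landmark correlations, modularity model comparison, integration.

test_that("a 62-landmark matrix has exactly 1891 unique correlations", {
  cfg <- equid_preset(seed = 51)
  cfg$groups$n <- c(8L, 4L, 4L, 2L)  # small n, same landmark scheme
  d <- generate_dataset(cfg)
  corr <- landmark_correlation_matrix(gpa(d))
  expect_equal(corr$n_corr, 1891L)
  expect_equal(corr$n_corr, sum(lower.tri(corr$values)))
  expect_true(all(corr$values >= 0 & corr$values <= 1))
  expect_equal(diag(corr$values), rep(1, 62))
})

test_that("identically displaced landmarks correlate perfectly", {
  set.seed(52)
  n <- 30
  coords <- array(rnorm(6 * 2 * n, sd = 0.1), c(6, 2, n))
  base <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 2, 0, 2, 1), 6, 2, byrow = TRUE)
  for (i in seq_len(n)) {
    coords[, , i] <- base + coords[, , i]
    coords[2, , i] <- coords[1, , i] + c(1, 0)  # rides along with landmark 1
  }
  R <- landmark_correlation_matrix(coords)$values
  expect_equal(R[1, 2], 1, tolerance = 1e-12)
})

test_that("zero-variance landmarks are reported by index", {
  coords <- array(rnorm(24), c(4, 2, 5))
  coords[3, , ] <- 0.5
  expect_error(landmark_correlation_matrix(coords), "landmark 3")
})

test_that("null-noise correlations match the independent-vectors expectation", {
  set.seed(53)
  k <- 15; m <- 3; n <- 500
  coords <- array(rnorm(k * m * n), c(k, m, n))
  R <- landmark_correlation_matrix(coords)$values
  off <- R[lower.tri(R)]
  # |r| of two independent centred Gaussian vectors of dimension ~ m(n-1):
  # approximately half-normal with sd 1/sqrt(d)
  d_eff <- m * (n - 1)
  expect_lt(abs(mean(off) - sqrt(2 / (pi * d_eff))), 0.005)
})

test_that("model variants partition correlations with the right parameter counts", {
  hyp <- module_hypothesis("h", rep(c("A", "B", "C"), times = c(4, 4, 4)))
  fitset <- build_model_set(list(hyp))
  expect_equal(length(fitset), 5L)  # null + a-d
  corr <- diag(12)
  corr[lower.tri(corr)] <- runif(66, 0.1, 0.9)
  corr <- corr + t(corr); diag(corr) <- 1
  fit <- emmli_fit(corr, fitset, n_like = 50)
  K <- fit$table$K[match(c("no_modularity", "h.a", "h.b", "h.c", "h.d"),
                         fit$table$model)]
  # 3 modules: a = 2 sets, b = 1 + 3 between-pairs, c = 3 + 1, d = 3 + 3
  expect_equal(K, c(2L, 3L, 5L, 5L, 7L))
  expect_equal(sum(fit$table$dAICc == 0), 1L)
  expect_true(all(fit$table$dAICc >= 0))
})

test_that("nested variants never lose log-likelihood", {
  set.seed(54)
  for (rep in 1:5) {
    C <- matrix(0.3, 12, 12)
    C[1:6, 1:6] <- 0.6; C[7:12, 7:12] <- 0.5; diag(C) <- 1
    X <- matrix(rnorm(60 * 12), 60, 12) %*% chol(C)
    hyp <- module_hypothesis("h", rep(c("A", "B"), each = 6))
    fit <- emmli_fit(abs(cor(X)), list(hyp), n_like = 60)
    ll <- setNames(fit$table$logL, fit$table$model)
    expect_gte(ll["h.d"], ll["h.a"] - 1e-9)
    expect_gte(ll["h.d"], ll["h.b"] - 1e-9)
    expect_gte(ll["h.d"], ll["h.c"] - 1e-9)
    expect_gte(ll["h.c"], ll["h.a"] - 1e-9)
    expect_gte(ll["h.b"], ll["h.a"] - 1e-9)
    expect_gte(ll["h.a"], ll["no_modularity"] - 1e-9)
  }
})

test_that("uniform correlations leave the null within 2 AICc of any variant", {
  R <- matrix(0.4, 10, 10); diag(R) <- 1
  hyp <- module_hypothesis("h", rep(c("A", "B"), each = 5))
  fit <- emmli_fit(R, list(hyp), n_like = 100)
  null_aicc <- fit$table$AICc[fit$table$model == "no_modularity"]
  expect_true(all(null_aicc <= fit$table$AICc + 2 + 1e-9))
})

test_that("eigenvalue dispersion hits its bounds and invariances", {
  expect_equal(eigenvalue_dispersion(diag(7)), 0)
  expect_equal(eigenvalue_dispersion(matrix(1, 7, 7)), 1)
  expect_error(eigenvalue_dispersion(matrix(1, 1, 1)), "at least 2")
  set.seed(55)
  C <- matrix(0.5, 8, 8); diag(C) <- 1
  X <- matrix(rnorm(100 * 8), 100, 8) %*% chol(C)
  R <- abs(cor(X))
  psi <- eigenvalue_dispersion(R)
  expect_gte(psi, 0); expect_lte(psi, 1)
  perm <- sample(8)
  expect_equal(eigenvalue_dispersion(R[perm, perm]), psi, tolerance = 1e-12)
  # uniform coordinate scaling leaves the correlation matrix unchanged
  expect_equal(eigenvalue_dispersion(abs(cor(3.7 * X))), psi,
               tolerance = 1e-12)
})

test_that("module disparity handles identical and single-outlier cases", {
  base <- matrix(c(0, 0, 2, 0, 1, 2, 0, 1), 4, 2)
  coords <- array(rep(base, 6), c(4, 2, 6))
  expect_equal(module_disparity(coords), c(max = 0, mean = 0))
  # one outlier at distance d from the others' common position: the
  # consensus shifts by d/n, so max = d(n-1)/n and mean = 2d(n-1)/n^2
  n <- 6; d <- 0.3
  out <- coords
  out[1, 1, n] <- out[1, 1, n] + d
  md <- module_disparity(out)
  expect_equal(md[["max"]], d * (n - 1) / n, tolerance = 1e-12)
  expect_equal(md[["mean"]], 2 * d * (n - 1) / n^2, tolerance = 1e-12)
  expect_gte(md[["max"]], md[["mean"]])
})

test_that("module integration reports per-module psi and disparity coherently", {
  qs <- quick_sym_dataset(n_per = c(A = 20), seed = 56, offset = 0)
  s <- symmetric_component(gpa(qs$dataset), qs$config$pairing)
  hyp <- module_hypothesis("gen", qs$config$module_map)
  rep1 <- module_integration(s, hyp)
  expect_equal(nrow(rep1$per_module), length(unique(qs$config$module_map)))
  expect_true(all(rep1$per_module$psi >= 0 & rep1$per_module$psi <= 1))
  expect_true(all(rep1$per_module$disparity_max >=
                  rep1$per_module$disparity_mean))
})

test_that("identical subsets give identical wild/domestic reports", {
  qs <- quick_sym_dataset(n_per = c(H = 10, P = 10), seed = 57, offset = 0)
  s <- symmetric_component(gpa(qs$dataset), qs$config$pairing)
  hyp <- module_hypothesis("gen", qs$config$module_map)
  # same specimens in both pools: reports must coincide
  cmp <- compare_wild_domestic(s$symmetric, rep("H", 20), hyp,
                               wild_groups = "H", domestic_groups = "H")
  expect_equal(cmp$domestic$per_module, cmp$wild$per_module)
})

test_that("bundled hypothesis files cover all 62 landmarks and build 17 models", {
  hyps <- cranium_hypotheses()
  expect_equal(length(hyps), 4L)
  for (h in hyps) {
    expect_equal(h$k, 62L)
    expect_true(all(nzchar(h$assignment)))
  }
  expect_equal(length(hyps$six_modules$modules), 6L)
  expect_equal(sort(hyps$six_modules$modules),
               c("AON", "CB", "CV", "MR", "ORB", "ZP"))
  expect_equal(length(build_model_set(hyps)), 17L)
})
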