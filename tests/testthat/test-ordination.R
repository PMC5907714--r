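# PCA, dimensionality selection, Procrustes ANOVA, CVA and prediction.

test_that("PCA basics: degenerate data, variance fractions, ordering", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4)
  p <- shape_pca(X)
  expect_lt(max(p$eigenvalues), 1e-24)

  qs <- quick_sym_dataset(seed = 21)
  p2 <- shape_pca(symmetric_component(gpa(qs$dataset), qs$config$pairing))
  expect_equal(sum(p2$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(p2$eigenvalues) <= 1e-12))
  expect_error(shape_pca(X[1, , drop = FALSE]), "at least 2")
})

test_that("projection into a fitted PC space matches the training scores", {
  qs <- quick_sym_dataset(seed = 22)
  s <- symmetric_component(gpa(qs$dataset), qs$config$pairing)
  p <- shape_pca(s)
  proj <- project_scores(p, s$symmetric)
  expect_equal(proj, p$scores, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("well-separated clusters give perfect accuracy at N = 2", {
  set.seed(31)
  X <- rbind(matrix(rnorm(25 * 6), 25, 6),
             sweep(matrix(rnorm(25 * 6), 25, 6), 2,
                   c(12, 12, 0, 0, 0, 0), `+`))
  g <- rep(c("A", "B"), each = 25)
  sel <- select_dimensions(X, g, max_N = 6, resamples = 100, seed = 1)
  expect_equal(sel$chosen_N, 2L)
  expect_equal(sel$accuracy_by_N$accuracy[sel$accuracy_by_N$N == 2], 1)
})

test_that("dimension selection rejects single groups and caps max_N", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(select_dimensions(X, rep("A", 10)), "2 groups")
  g <- rep(c("A", "B"), each = 5)
  expect_warning(select_dimensions(X, g, max_N = 50, resamples = 5,
                                   seed = 1), "capped")
})

test_that("pure-noise groups classify at chance level", {
  # average the cross-validated accuracy over independent noise datasets:
  # a single dataset's LOO accuracy is itself a noisy draw around chance
  set.seed(32)
  g <- rep(c("A", "B", "C"), each = 15)
  acc <- replicate(25, {
    X <- matrix(rnorm(45 * 4), 45, 4)
    sel <- select_dimensions(X, g, max_N = 3, resamples = 1)
    sel$accuracy_by_N$accuracy
  })
  means <- rowMeans(acc)
  # chance is 1/3 for three balanced groups; LOO LDA sits at or slightly
  # below it (the left-out point pulls its own group mean away), so the
  # scientifically important bound is the upper one
  expect_true(all(means < 1 / 3 + 0.05))
  expect_true(all(means > 1 / 3 - 0.12))
})

test_that("permutation ANOVA detects strong separation and respects its bound", {
  set.seed(33)
  X <- rbind(matrix(rnorm(20 * 3), 20, 3),
             matrix(rnorm(20 * 3, mean = 5), 20, 3))
  g <- rep(c("A", "B"), each = 20)
  a <- procrustes_anova(X, g, N = 3, permutations = 999, seed = 3)
  expect_lte(a$p, 0.001)
  expect_equal(a$p, 1 / 1000)  # lower bound 1/(permutations+1)
  expect_error(procrustes_anova(X, c(g[-1], "C"), N = 3), "size 1")
})

test_that("pseudo-F agrees with an independent distance-based implementation", {
  skip_if_not_installed("vegan")
  set.seed(34)
  X <- matrix(rnorm(36 * 5), 36, 5)
  g <- factor(rep(c("A", "B", "C"), each = 12))
  mine <- procrustes_anova(X, g, N = 5, permutations = 9, seed = 1)$F
  ref <- vegan::adonis2(dist(X) ~ g, permutations = 2)$F[1]
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("Mahalanobis distances: trivial, analytic and affine-invariant cases", {
  set.seed(35)
  # self-distance is zero and the matrix is symmetric
  X <- matrix(rnorm(30 * 3), 30, 3)
  g <- rep(c("A", "B"), each = 15)
  md <- mahalanobis_distances(X, g, 3)
  expect_equal(diag(md$D2), c(A = 0, B = 0))
  expect_equal(md$D2, t(md$D2))

  # univariate closed form D = |mu1 - mu2| / pooled sd
  x <- c(rnorm(40), rnorm(40, 3))
  gg <- rep(c("A", "B"), each = 40)
  mu <- tapply(x, gg, mean)
  pooled <- sqrt((sum((x[1:40] - mu[1])^2) +
                  sum((x[41:80] - mu[2])^2)) / 78)
  md1 <- mahalanobis_distances(matrix(x, ncol = 1), gg, 1)
  expect_equal(md1$D["A", "B"], abs(mu[1] - mu[2]) / pooled,
               tolerance = 1e-12, ignore_attr = TRUE)

  # invariance under an invertible affine transform of the score space
  A <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  Xt <- sweep(X %*% A, 2, c(1, -2, 5), `+`)
  md2 <- mahalanobis_distances(Xt, g, 3)
  expect_equal(md$D2, md2$D2, tolerance = 1e-8)
})

test_that("CVA report is internally consistent and accurate when groups separate", {
  set.seed(36)
  n <- 30
  X <- rbind(matrix(rnorm(n * 4), n, 4),
             sweep(matrix(rnorm(n * 4), n, 4), 2, c(8, 0, 0, 0), `+`),
             sweep(matrix(rnorm(n * 4), n, 4), 2, c(0, 8, 0, 0), `+`))
  g <- rep(c("A", "B", "C"), each = n)
  rep1 <- cva_classify(X, g, N = 4, resamples = 100, seed = 4)
  expect_gte(rep1$overall_accuracy, 95)
  expect_equal(rowSums(rep1$confusion), table(g), ignore_attr = TRUE)
  expect_equal(rowSums(rep1$posterior), rep(1, 3 * n), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(rep1$ci_low <= rep1$overall_accuracy + 1e-9)
  # LOO accuracy is deterministic; the CI is seed-reproducible
  rep2 <- cva_classify(X, g, N = 4, resamples = 100, seed = 4)
  expect_identical(rep1$overall_accuracy, rep2$overall_accuracy)
  expect_identical(c(rep1$ci_low, rep1$ci_high),
                   c(rep2$ci_low, rep2$ci_high))
})

test_that("singular pooled covariance advises a smaller N", {
  X <- cbind(rnorm(20), rnorm(20))
  X <- cbind(X, X[, 1] + X[, 2])  # exactly collinear
  g <- rep(c("A", "B"), each = 10)
  expect_error(mahalanobis_distances(X, g, 3), "smaller N")
})

test_that("predictive assignment gives certainty at a group mean and splits midway", {
  set.seed(37)
  n <- 25
  Xa <- matrix(rnorm(n * 3, sd = 0.5), n, 3)
  Xb <- sweep(matrix(rnorm(n * 3, sd = 0.5), n, 3), 2, c(10, 0, 0), `+`)
  X <- rbind(Xa, Xb)
  g <- rep(c("A", "B"), each = n)
  at_mean <- matrix(colMeans(Xa), 1)
  midway <- matrix(colMeans(Xa) / 2 + colMeans(Xb) / 2, 1)
  post <- predict_excluded(X, g, rbind(at_mean, midway), N = 3,
                           resamples = 400, seed = 5)
  expect_equal(unname(post[1, "A"]), 1)
  expect_equal(unname(post[2, "A"]), 0.5, tolerance = 0.3)
  expect_equal(rowSums(post), c(1, 1), ignore_attr = TRUE)
})
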