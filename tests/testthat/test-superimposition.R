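# GPA, view merging and the object-symmetry decomposition.

test_that("identical and similarity-transformed shapes superimpose to distance zero", {
  tri <- triangle_A
  d <- landmark_dataset(list(tri, tri), ids = c("a", "b"))
  g <- gpa(d)
  expect_lt(procrustes_distance(g$aligned[, , 1], g$aligned[, , 2],
                                align = FALSE), 1e-12)
  expect_lt(procrustes_variance(g), 1e-24)

  # scaled x2, rotated 90 degrees, translated
  R90 <- matrix(c(0, 1, -1, 0), 2, 2)
  tri2 <- sweep(2 * tri %*% R90, 2, c(3, -1), `+`)
  g2 <- gpa(landmark_dataset(list(tri, tri2), ids = c("a", "b")))
  expect_lt(procrustes_distance(g2$aligned[, , 1], g2$aligned[, , 2],
                                align = FALSE), 1e-12)
})

test_that("Procrustes distance matches a brute-force rotation grid search", {
  expect_equal(procrustes_distance(triangle_A, triangle_B),
               grid_procrustes_distance_2d(triangle_A, triangle_B),
               tolerance = 1e-5)
  # a second, asymmetric pair
  set.seed(8)
  a <- matrix(rnorm(10), 5, 2)
  b <- matrix(rnorm(10), 5, 2)
  expect_equal(procrustes_distance(a, b),
               grid_procrustes_distance_2d(a, b), tolerance = 1e-5)
})

test_that("GPA is invariant to arbitrary similarity transforms of the inputs", {
  qs <- quick_sym_dataset(seed = 5)
  d <- qs$dataset
  g1 <- gpa(d)
  set.seed(99)
  jittered <- d$coords
  for (i in seq_len(d$n)) jittered[, , i] <- random_similarity(d$coords[, , i])
  g2 <- gpa(landmark_dataset(jittered, ids = d$ids))
  # pairwise aligned distances are a rotation-invariant summary
  pd <- function(g) {
    n <- dim(g$aligned)[3]
    outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      procrustes_distance(g$aligned[, , i], g$aligned[, , j])))
  }
  expect_equal(pd(g1), pd(g2), tolerance = 1e-6)
})

test_that("GPA residual sum of squares never increases across iterations", {
  for (seed in 1:5) {
    qs <- quick_sym_dataset(seed = seed, offset = 0.1)
    g <- gpa(qs$dataset)
    expect_true(all(diff(g$rss) <= 1e-12))
    expect_true(g$converged)
  }
})

test_that("aligned configurations are centred with unit centroid size", {
  g <- gpa(quick_sym_dataset(seed = 6)$dataset)
  for (i in seq_len(g$n)) {
    expect_lt(max(abs(colMeans(g$aligned[, , i]))), 1e-9)
    expect_equal(centroid_size(g$aligned[, , i]), 1, tolerance = 1e-9)
  }
  expect_equal(g$consensus, apply(g$aligned, c(1, 2), mean))
})

test_that("degenerate configurations are rejected", {
  flat <- matrix(1, 4, 2)
  expect_error(gpa(landmark_dataset(list(flat, flat))), "degenerate")
})

test_that("merge_views recovers known rigid transforms and geometry", {
  qs <- quick_sym_dataset(seed = 7)
  d <- qs$dataset
  tv <- generate_two_view(d, seed = 17)
  for (i in c(1, 5)) {
    mg <- merge_views(tv$dorsal[[i]], tv$ventral[[i]], tv$dorsal_ids,
                      tv$ventral_ids, tv$ref_ids)
    expect_equal(mg$rotation, tv$truth[[i]]$rotation, tolerance = 1e-9)
    expect_equal(mg$translation, tv$truth[[i]]$translation,
                 tolerance = 1e-9)
    expect_equal(mg$coords, d$coords[mg$ids, , i], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_lt(mg$ref_rms, 1e-9)
  }
  # ventral already in the dorsal frame: identity transform
  cc <- d$coords[, , 1]
  mg0 <- merge_views(cc[1:6, ], cc[c(1:3, 7:12), ], 1:6, c(1:3, 7:12),
                     ref_ids = 1:3)
  expect_equal(mg0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(mg0$translation, rep(0, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mg0$coords, cc, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("collinear reference landmarks are rejected", {
  line <- cbind(0:3, 0, 0)
  dorsal <- rbind(line, c(1, 2, 3))
  ventral <- rbind(line, c(0, 5, 1))
  expect_error(merge_views(dorsal, ventral, 1:5, c(1:4, 6),
                           ref_ids = 1:4), "collinear")
})

test_that("symmetric + asymmetric reconstructs the aligned coordinates exactly", {
  qs <- quick_sym_dataset(seed = 9)
  s <- symmetric_component(gpa(qs$dataset), qs$config$pairing)
  expect_equal(s$symmetric + s$asymmetric, s$aligned, tolerance = 1e-12)
})

test_that("the symmetric component is a fixed point of reflect-and-relabel", {
  qs <- quick_sym_dataset(seed = 10)
  p <- qs$config$pairing
  s <- symmetric_component(gpa(qs$dataset), p)
  for (i in seq_len(s$n)) {
    sym <- s$symmetric[, , i]
    refl <- sym
    refl[, 1] <- -refl[, 1]
    refl <- refl[p$permutation, ]
    expect_equal(refl, sym, tolerance = 1e-9)
  }
})

test_that("mirror-symmetric configurations have zero asymmetric component", {
  qs <- quick_sym_dataset(seed = 11, asymmetry_sd = 0)
  s <- symmetric_component(gpa(qs$dataset), qs$config$pairing)
  expect_lt(max(abs(s$asymmetric)), 1e-6)
})

test_that("asymmetric magnitude grows monotonically with injected displacement", {
  base_qs <- quick_sym_dataset(seed = 12, asymmetry_sd = 0)
  d <- base_qs$dataset
  p <- base_qs$config$pairing
  asym_ss <- sapply(c(0, 0.02, 0.05, 0.1), function(delta) {
    coords <- d$coords
    # displace one member of the first bilateral pair on every specimen
    coords[p$paired[1, 1], 2, ] <- coords[p$paired[1, 1], 2, ] + delta * 100
    s <- symmetric_component(gpa(landmark_dataset(coords, ids = d$ids)), p)
    sum(s$asymmetric^2)
  })
  expect_true(all(diff(asym_ss) > 0))
})

test_that("pairing schemes validate their partition and read from file", {
  expect_error(pairing_scheme(cbind(1, 2), c(2, 3), 3), "repeated")
  expect_error(pairing_scheme(cbind(1, 2), 4, 4), "partition")
  cp <- cranium_pairing()
  expect_equal(cp$k, 62L)
  expect_equal(nrow(cp$paired), 26L)
  expect_equal(length(cp$midline), 10L)
  # the interleaved palate pairs and the vomer-flanking pair
  expect_true(any(cp$paired[, 1] == 40 & cp$paired[, 2] == 42))
  expect_true(any(cp$paired[, 1] == 41 & cp$paired[, 2] == 43))
  expect_true(any(cp$paired[, 1] == 49 & cp$paired[, 2] == 51))
  mp <- mandible_pairing()
  expect_equal(mp$k, 24L)
  expect_equal(length(mp$midline), 2L)
})
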