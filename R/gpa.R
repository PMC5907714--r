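# Generalized Procrustes analysis.
#
# Partial Procrustes superimposition: every configuration is centred,
# scaled to unit centroid size, and rotated (proper rotations only --
# reflections are never used here, so handedness is preserved) to the
# running consensus; the consensus is the arithmetic mean of the aligned
# configurations. Iteration stops when the consensus change falls below
# `tol` (default 1e-10) or after `max_iter` iterations.

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the size measure removed by GPA.
#'
#' @param x a `k x m` coordinate matrix.
#' @return A positive scalar.
#' @export
centroid_size <- function(x) {
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

# centre at the origin and scale to unit centroid size
to_preshape <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(x^2))
  if (cs < .Machine$double.eps^0.5)
    stop("degenerate configuration: all landmarks coincide")
  list(coords = x / cs, cs = cs)
}

# optimal proper rotation Q minimizing ||A Q - B||_F (Kabsch).
# Reflections are excluded: det(Q) is forced to +1.
optimal_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  m <- ncol(A)
  s$u %*% diag(c(rep(1, m - 1), d), m) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Superimposes all configurations of a dataset by iterative translation,
#' scaling to unit centroid size, and rotation to the consensus, minimizing
#' the summed squared distances between matching landmarks. Only proper
#' rotations are used.
#'
#' @param x a [landmark_dataset()] or a `k x m x n` coordinate array.
#' @param tol convergence tolerance on the consensus change
#'   (root-mean-square, default `1e-10`).
#' @param max_iter maximum number of iterations (default 100).
#' @return An object of class `gpa`:
#' \describe{
#'   \item{aligned}{`k x m x n` aligned coordinates (centroid at the origin,
#'     unit centroid size).}
#'   \item{consensus}{arithmetic mean shape of the aligned coordinates.}
#'   \item{centroid_sizes}{original centroid sizes.}
#'   \item{rss}{summed squared residuals around the consensus at each
#'     iteration (non-increasing).}
#'   \item{iterations, converged}{iteration count and convergence flag.}
#' }
#' @examples
#' d <- generate_dataset(simulation_config(k = 12, m = 2, seed = 1))
#' g <- gpa(d)
#' g
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  ids <- NULL; meta <- NULL
  if (inherits(x, "landmark_dataset")) {
    ids <- x$ids; meta <- x$meta; x <- x$coords
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  k <- dim(x)[1]; m <- dim(x)[2]; n <- dim(x)[3]
  if (n < 2) stop("GPA needs at least 2 configurations")
  aligned <- array(NA_real_, dim(x), dimnames = dimnames(x))
  cs <- numeric(n)
  for (i in seq_len(n)) {
    p <- to_preshape(x[, , i])
    aligned[, , i] <- p$coords
    cs[i] <- p$cs
  }
  # initial consensus: first preshape (any choice works; rotation follows)
  consensus <- aligned[, , 1]
  rss <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*%
        optimal_rotation(aligned[, , i], consensus)
    new_consensus <- apply(aligned, c(1, 2), mean)
    rss <- c(rss, sum(sweep(aligned, c(1, 2), new_consensus)^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = cs, rss = rss, iterations = iter,
                 converged = converged, k = k, m = m, n = n,
                 ids = ids, meta = meta),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("GPA: %d specimens, %d landmarks, %dD\n", x$n, x$k, x$m))
  cat(sprintf("  converged: %s after %d iterations (residual SS %.6g)\n",
              x$converged, x$iterations, x$rss[length(x$rss)]))
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  print(object)
  cat(sprintf("  centroid size: %.4g - %.4g (median %.4g)\n",
              min(object$centroid_sizes), max(object$centroid_sizes),
              stats::median(object$centroid_sizes)))
  cat(sprintf("  Procrustes variance: %.6g\n",
              procrustes_variance(object$aligned)))
  invisible(object)
}

#' @export
plot.gpa <- function(x, axes = c(1, 2), ...) {
  a <- x$aligned
  plot(NA, xlim = range(a[, axes[1], ]), ylim = range(a[, axes[2], ]),
       xlab = paste("axis", axes[1]), ylab = paste("axis", axes[2]),
       asp = 1, main = "Aligned landmarks", ...)
  for (i in seq_len(x$n))
    graphics::points(a[, axes[1], i], a[, axes[2], i], pch = 16,
                     col = grDevices::grey(0.7, 0.4), cex = 0.5)
  graphics::points(x$consensus[, axes[1]], x$consensus[, axes[2]],
                   pch = 21, bg = "black", cex = 0.9)
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Centres and scales both configurations to unit centroid size, rotates the
#' first onto the second with the optimal proper rotation, and returns the
#' root summed squared landmark distance (partial Procrustes distance).
#'
#' @param a,b `k x m` coordinate matrices.
#' @param align superimpose first? Set `FALSE` to measure the raw distance
#'   between already-aligned configurations.
#' @return A non-negative scalar.
#' @export
procrustes_distance <- function(a, b, align = TRUE) {
  if (align) {
    a <- to_preshape(a)$coords
    b <- to_preshape(b)$coords
    a <- a %*% optimal_rotation(a, b)
  }
  sqrt(sum((a - b)^2))
}
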