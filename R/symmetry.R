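# Object-symmetry decomposition of bilateral landmark configurations.
#
# A structure with internal (object) symmetry, such as a skull, is compared
# with its own mirror image: each configuration is reflected (first
# coordinate axis negated) and relabelled (left/right landmark pairs
# swapped), the originals and reflections are superimposed jointly, and the
# symmetric component of each specimen is the average of its original with
# its reflected copy. What remains is the asymmetric component. Only the
# symmetric component feeds the downstream ordination, classification,
# disparity and modularity analyses.

# reflect (negate `axis`) and relabel (swap bilateral pairs)
reflect_relabel <- function(x, pairing, axis = 1L) {
  out <- x
  out[, axis] <- -out[, axis]
  out[pairing$permutation, , drop = FALSE]
}

# Rotation W putting the consensus M into the canonical orientation in
# which its symmetry plane is {axis1 = 0}, i.e. reflect_relabel(M W) = M W.
# Derivation: with Q the optimal rotation carrying reflect_relabel(M) onto
# M, the condition reads Q^T F = W F W^T with F = diag(-1, 1, ...), a
# Householder reflection I - 2 w w^T; w is the eigenvector of the
# symmetrized Q^T F with eigenvalue closest to -1, and W is any proper
# rotation with first column w.
canonical_symmetry_rotation <- function(M, pairing, axis = 1L) {
  m <- ncol(M)
  Mr <- reflect_relabel(M, pairing, axis)
  Q <- optimal_rotation(Mr, M)
  Fm <- diag(m); Fm[axis, axis] <- -1
  S <- (t(Q) %*% Fm + Fm %*% Q) / 2
  e <- eigen(S, symmetric = TRUE)
  w <- e$vectors[, which.min(e$values)]
  W <- qr.Q(qr(cbind(w, diag(m))))[, seq_len(m), drop = FALSE]
  W[, 1] <- w  # qr may flip the sign of the leading column
  if (det(W) < 0) W[, m] <- -W[, m]
  # move the reflection axis into position `axis`
  if (axis != 1L) {
    perm <- seq_len(m); perm[c(1L, axis)] <- c(axis, 1L)
    W <- W[, perm, drop = FALSE]
    if (det(W) < 0) W[, if (axis == m) 1L else m] <- -W[, if (axis == m) 1L else m]
  }
  W
}

#' Symmetric and asymmetric shape components
#'
#' Decomposes GPA-aligned configurations of an object-symmetric structure
#' into symmetric and asymmetric components. The reflected-and-relabelled
#' copy of every specimen is added to the sample, originals and reflections
#' are jointly superimposed, the joint consensus is rotated so its symmetry
#' plane coincides with the coordinate plane, and each specimen's symmetric
#' component is the reflection-invariant average of its original with its
#' reflected copy. The asymmetric component is the residual, so
#' `symmetric + asymmetric` reconstructs the aligned coordinates exactly.
#'
#' @param result a [gpa()] result (or a [landmark_dataset()], which is
#'   superimposed first).
#' @param pairing a [pairing_scheme()] partitioning all landmarks into
#'   bilateral pairs and midline points.
#' @param axis coordinate axis negated by the reflection (default 1).
#' @return An object of class `symmetry_decomposition`:
#'   `aligned`, `symmetric`, `asymmetric` (`k x m x n` arrays, with
#'   `symmetric + asymmetric == aligned`), `consensus` (symmetric mean
#'   shape), `pairing`, plus carried-over `ids`/`meta`.
#' @export
symmetric_component <- function(result, pairing, axis = 1L) {
  if (inherits(result, "landmark_dataset")) result <- gpa(result)
  stopifnot(inherits(result, "gpa"), inherits(pairing, "pairing_scheme"))
  if (pairing$k != result$k)
    stop("pairing scheme is for ", pairing$k, " landmarks, data have ",
         result$k)
  k <- result$k; m <- result$m; n <- result$n
  doubled <- array(NA_real_, c(k, m, 2 * n))
  doubled[, , seq_len(n)] <- result$aligned
  for (i in seq_len(n))
    doubled[, , n + i] <- reflect_relabel(result$aligned[, , i], pairing, axis)
  joint <- gpa(doubled)
  W <- canonical_symmetry_rotation(joint$consensus, pairing, axis)
  orig <- array(NA_real_, c(k, m, n), dimnames = dimnames(result$aligned))
  refl <- array(NA_real_, c(k, m, n))
  for (i in seq_len(n)) {
    orig[, , i] <- joint$aligned[, , i] %*% W
    refl[, , i] <- joint$aligned[, , n + i] %*% W
  }
  symm <- orig
  for (i in seq_len(n)) {
    s <- (orig[, , i] + refl[, , i]) / 2
    # exact projection onto the reflection-invariant subspace
    symm[, , i] <- (s + reflect_relabel(s, pairing, axis)) / 2
  }
  asym <- orig - symm
  structure(list(aligned = orig, symmetric = symm, asymmetric = asym,
                 consensus = apply(symm, c(1, 2), mean),
                 pairing = pairing, axis = axis, k = k, m = m, n = n,
                 ids = result$ids, meta = result$meta),
            class = "symmetry_decomposition")
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  sym_ss <- sum(sweep(x$symmetric, c(1, 2), apply(x$symmetric, c(1, 2), mean))^2)
  asy_ss <- sum(x$asymmetric^2)
  cat(sprintf("Symmetry decomposition: %d specimens, %d landmarks, %dD\n",
              x$n, x$k, x$m))
  cat(sprintf("  symmetric SS %.6g, asymmetric SS %.6g\n", sym_ss, asy_ss))
  invisible(x)
}
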