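# Merging separately digitized views of one specimen.
#
# Crania are digitized in two sessions (dorsal side up, then ventral side
# up) with a set of reference landmarks captured in both. Because both
# views are the same physical specimen in the same units, the ventral view
# is mapped into the dorsal frame by a least-squares *rigid* transform
# (rotation + translation, no scaling) fitted on the shared references.

#' Merge two digitizing views of one specimen
#'
#' Fits the least-squares rigid transform carrying the ventral view's
#' reference landmarks onto the dorsal view's, applies it to the whole
#' ventral view, drops the ventral copies of the references, and assembles
#' the union configuration in ascending landmark order. The root-mean-square
#' misfit over the reference landmarks is returned as a digitizing-error
#' diagnostic.
#'
#' @param dorsal,ventral coordinate matrices of the two views.
#' @param dorsal_ids,ventral_ids integer vectors giving the global landmark
#'   number of each row.
#' @param ref_ids reference landmarks present in both views (default the
#'   cranial scheme's `c(1, 2, 33)`); at least 3, non-collinear.
#' @return A list of class `merged_views`: `coords` (union configuration),
#'   `ids` (global landmark numbers, ascending), `rotation`, `translation`
#'   (the fitted transform mapping ventral into dorsal frame), and
#'   `ref_rms` (RMS reference misfit).
#' @export
merge_views <- function(dorsal, ventral, dorsal_ids, ventral_ids,
                        ref_ids = c(1L, 2L, 33L)) {
  dorsal <- as.matrix(dorsal); ventral <- as.matrix(ventral)
  stopifnot(nrow(dorsal) == length(dorsal_ids),
            nrow(ventral) == length(ventral_ids))
  if (length(ref_ids) < 3L)
    stop("at least 3 reference landmarks are required")
  if (!all(ref_ids %in% dorsal_ids) || !all(ref_ids %in% ventral_ids))
    stop("reference landmarks must be present in both views")
  rd <- dorsal[match(ref_ids, dorsal_ids), , drop = FALSE]
  rv <- ventral[match(ref_ids, ventral_ids), , drop = FALSE]
  cd <- colMeans(rd); cv <- colMeans(rv)
  A <- sweep(rv, 2, cv); B <- sweep(rd, 2, cd)
  sv <- svd(crossprod(A, B))$d
  if (sv[2] < 1e-8 * max(sv[1], .Machine$double.eps))
    stop("reference landmarks are collinear or coincident")
  R <- optimal_rotation(A, B)
  t_vec <- cd - as.vector(cv %*% R)
  map <- function(x) sweep(x %*% R, 2, t_vec, `+`)
  ref_rms <- sqrt(mean(rowSums((map(rv) - rd)^2)))
  vent_keep <- !(ventral_ids %in% ref_ids)
  ids <- c(dorsal_ids, ventral_ids[vent_keep])
  if (anyDuplicated(ids))
    stop("views share non-reference landmarks: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  coords <- rbind(dorsal, map(ventral[vent_keep, , drop = FALSE]))
  ord <- order(ids)
  structure(list(coords = coords[ord, , drop = FALSE], ids = ids[ord],
                 rotation = R, translation = t_vec, ref_rms = ref_rms),
            class = "merged_views")
}

#' @export
print.merged_views <- function(x, ...) {
  cat(sprintf("Merged views: %d landmarks, reference RMS misfit %.3g\n",
              nrow(x$coords), x$ref_rms))
  invisible(x)
}
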