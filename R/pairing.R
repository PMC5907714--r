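# Bilateral landmark pairing schemes for object-symmetric structures.

#' Construct a bilateral pairing scheme
#'
#' A pairing scheme declares which landmarks form left/right bilateral pairs
#' and which lie on the midline (sagittal) plane. Together the paired and
#' midline landmarks must partition `1..k` with no index repeated; this is
#' what the object-symmetry decomposition ([symmetric_component()]) needs to
#' reflect and relabel a configuration.
#'
#' @param paired two-column integer matrix; each row one (left, right) pair.
#' @param midline integer vector of midline landmark indices.
#' @param k total number of landmarks.
#' @return An object of class `pairing_scheme` with elements `paired`,
#'   `midline`, `k` and `permutation` (the relabelling that swaps sides).
#' @export
pairing_scheme <- function(paired, midline, k) {
  paired <- matrix(as.integer(paired), ncol = 2)
  midline <- as.integer(midline)
  all_idx <- c(as.vector(paired), midline)
  if (anyDuplicated(all_idx))
    stop("pairing is not a partition: landmark index repeated")
  if (!setequal(all_idx, seq_len(k)) || length(all_idx) != k)
    stop("pairing must partition landmarks 1..k exactly")
  perm <- seq_len(k)
  perm[paired[, 1]] <- paired[, 2]
  perm[paired[, 2]] <- paired[, 1]
  structure(list(paired = paired, midline = midline, k = as.integer(k),
                 permutation = perm),
            class = "pairing_scheme")
}

#' @export
print.pairing_scheme <- function(x, ...) {
  cat(sprintf("Pairing scheme: %d landmarks, %d bilateral pairs, %d midline\n",
              x$k, nrow(x$paired), length(x$midline)))
  invisible(x)
}

#' Read a pairing scheme from a two-column config file
#'
#' The file holds one line per landmark: `landmark partner`, where
#' `partner = 0` marks a midline landmark. Each bilateral pair appears on
#' both of its lines (symmetrically); lines starting with `#` are comments.
#'
#' @param path path to the config file.
#' @return A [pairing_scheme()].
#' @export
read_pairing <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("landmark", "partner"))
  k <- max(tab$landmark)
  mid <- tab$landmark[tab$partner == 0L]
  pr <- tab[tab$partner != 0L & tab$landmark < tab$partner, , drop = FALSE]
  pairing_scheme(as.matrix(pr), mid, k)
}

#' Write a pairing scheme config file
#'
#' @param pairing a [pairing_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairing <- function(pairing, path) {
  stopifnot(inherits(pairing, "pairing_scheme"))
  partner <- rep(0L, pairing$k)
  partner[pairing$paired[, 1]] <- pairing$paired[, 2]
  partner[pairing$paired[, 2]] <- pairing$paired[, 1]
  utils::write.table(data.frame(seq_len(pairing$k), partner), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bundled equid cranium pairing (62 landmarks)
#'
#' The cranial landmark scheme has 26 bilateral pairs and 10 midline
#' landmarks (nasion, occipital triangle, nuchal crest, foramen magnum,
#' incisive and palatine midline points, vomer). Note two interleaved pairs
#' on the palate: (40, 42) anterior second premolar and (41, 43) posterior
#' third molar, and the pair (49, 51) flanking the midline vomer point 50.
#'
#' @return A [pairing_scheme()] with `k = 62`.
#' @export
cranium_pairing <- function() {
  read_pairing(system.file("extdata", "cranium_pairing.txt",
                           package = "morphomod", mustWork = TRUE))
}

#' Bundled equid mandible pairing (24 landmarks)
#'
#' Eleven bilateral pairs plus two midline landmarks (the point between the
#' first incisors and the posterior midline tip of the mandible).
#'
#' @return A [pairing_scheme()] with `k = 24`.
#' @export
mandible_pairing <- function() {
  read_pairing(system.file("extdata", "mandible_pairing.txt",
                           package = "morphomod", mustWork = TRUE))
}
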