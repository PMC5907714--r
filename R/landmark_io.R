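# Landmark and metadata input/output.
#
# Two on-disk formats are supported: the TPSDig dialect of the TPS format
# (2D tooth outlines digitized from photographs) and wide tabular files of
# raw 3D digitizer coordinates, one specimen per row, with an ID string
# encoding museum, accession, group, breed and morphotype.

## ---- code tables ----------------------------------------------------------

.morphomod_museums <- c(
  A = "Argentina", B = "Berlin", H = "Halle", K = "Kiel", V = "Vienna"
)

.morphomod_groups <- c(
  H = "horse", D = "donkey", P = "Przewalski's", Z = "zebra"
)

.morphomod_breeds <- c(
  aaa = "not a domesticated horse",
  ahb = "Ancient Breed (Roman period)", ano = "Anglo-Norman", arb = "Arab",
  bif = "Birkenfelder", blg = "Belgian Draft", bos = "Bosnian Pony",
  cds = "Clydesdale", exm = "Exmoor Pony", fab = "Falabella",
  gbh = "Galician Farm Horse", grb = "Grisons (Graubündner)",
  grp = "German Riding Pony", han = "Hannoverian", hny = "Hackney",
  hol = "Holstein", hun = "Hungarian", huz = "Huzule",
  ice = "Icelandic Horse", ind = "Indian Pony", kdr = "Kladrubian",
  kon = "Konik", kos = "Kosarian", lpz = "Lipizzan", mon = "Mongolian",
  nor = "Norik", odb = "Oldenburgian", piz = "Pinzgau",
  pll = "Polish Farm Horse", scp = "Scottish Pony", ses = "Seneca Sarajevo",
  she = "Shetland Pony", shi = "Shire", stm = "Styrian", suf = "Suffolk",
  tbh = "English Thoroughbred", tog = "Togo Pony", trk = "Trakehner",
  wel = "Welsh"
)

.morphomod_morphotypes <- c(
  A = "not a domesticated horse", W = "medium horse", F = "Light horse",
  C = "Draft horse", P = "Pony"
)

#' Code tables used in specimen ID strings
#'
#' Returns the lookup tables that decode the museum, group, breed and
#' morphotype fields of a specimen identifier (see [parse_id_string()]).
#'
#' @return A named list of named character vectors
#'   (`museum`, `group`, `breed`, `morphotype`); names are the codes,
#'   values the decoded labels.
#' @export
id_code_tables <- function() {
  list(
    museum = .morphomod_museums,
    group = .morphomod_groups,
    breed = .morphomod_breeds,
    morphotype = .morphomod_morphotypes
  )
}

## ---- dataset container ----------------------------------------------------

#' Construct a landmark dataset
#'
#' A `landmark_dataset` bundles the landmark configurations of a set of
#' specimens sharing a common landmark scheme: a `k x m x n` coordinate
#' array (k landmarks, m = 2 or 3 dimensions, n specimens) plus optional
#' per-specimen metadata.
#'
#' @param coords numeric array `k x m x n`, or a list of `k x m` matrices.
#' @param ids character vector of n unique specimen identifiers.
#' @param meta optional data frame of n rows of specimen metadata.
#' @return An object of class `landmark_dataset` with elements `coords`,
#'   `ids`, `meta`, `k`, `m`, `n`.
#' @export
landmark_dataset <- function(coords, ids = NULL, meta = NULL) {
  if (is.list(coords)) {
    if (length(coords) == 0L) {
      out <- structure(
        list(coords = array(numeric(0), c(0, 0, 0)), ids = character(0),
             meta = NULL, k = 0L, m = 0L, n = 0L),
        class = "landmark_dataset")
      return(out)
    }
    dims <- vapply(coords, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all configurations must share the same (k, m)")
    coords <- array(unlist(coords), c(dims[1, 1], dims[2, 1], length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  k <- dim(coords)[1]; m <- dim(coords)[2]; n <- dim(coords)[3]
  if (n > 0 && k < 3) stop("at least 3 landmarks are required")
  if (n > 0 && !(m %in% c(2L, 3L))) stop("dimension m must be 2 or 3")
  if (any(!is.finite(coords)))
    stop("missing or non-finite coordinates are not supported")
  if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal the number of specimens")
  if (anyDuplicated(ids)) stop("specimen ids must be unique")
  dimnames(coords)[[3]] <- ids
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != n) stop("metadata rows must match number of specimens")
  }
  structure(list(coords = coords, ids = ids, meta = meta,
                 k = as.integer(k), m = as.integer(m), n = as.integer(n)),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("Landmark dataset: %d specimens, %d landmarks, %dD\n",
              x$n, x$k, x$m))
  if (!is.null(x$meta) && "group" %in% names(x$meta)) {
    tab <- table(x$meta$group)
    cat("Groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# internal: n x (k*m) flat matrix, landmark-major (x1 y1 [z1] x2 y2 ...)
flatten_coords <- function(coords) {
  k <- dim(coords)[1]; m <- dim(coords)[2]; n <- dim(coords)[3]
  out <- t(apply(coords, 3, function(cc) as.vector(t(cc))))
  dim(out) <- c(n, k * m)
  rownames(out) <- dimnames(coords)[[3]]
  out
}

unflatten_coords <- function(flat, m) {
  n <- nrow(flat); k <- ncol(flat) / m
  stopifnot(k == round(k))
  arr <- array(NA_real_, c(k, m, n))
  for (i in seq_len(n)) arr[, , i] <- matrix(flat[i, ], k, m, byrow = TRUE)
  dimnames(arr)[[3]] <- rownames(flat)
  arr
}

## ---- ID strings -----------------------------------------------------------

#' Parse a specimen identifier string
#'
#' Specimen identifiers concatenate museum, accession, group, breed and
#' morphotype codes (default delimiter `"_"`), e.g. `"B_123_H_arb_F"` for an
#' Arab light horse from the Berlin collection. Codes are decoded against
#' the tables in [id_code_tables()]. Two consistency rules are enforced:
#' only domesticated horses (group `H`) carry a real breed code (all others
#' are `aaa`), and only non-horses carry morphotype `A`.
#'
#' @param id character vector of identifier strings.
#' @param delim field delimiter (default `"_"`).
#' @return A data frame with columns `specimen_id`, `museum`, `accession`,
#'   `group`, `breed`, `morphotype` (codes) and `museum_label`,
#'   `group_label`, `breed_label`, `morphotype_label` (decoded).
#' @examples
#' parse_id_string("B_123_H_arb_F")
#' parse_id_string("V_9_D_aaa_A")
#' @export
parse_id_string <- function(id, delim = "_") {
  tabs <- id_code_tables()
  parts <- strsplit(as.character(id), delim, fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 5L
  if (any(bad))
    stop("malformed ID string (expected 5 fields): ",
         paste(id[bad], collapse = ", "))
  fld <- function(i) vapply(parts, `[[`, "", i)
  museum <- fld(1); accession <- fld(2); group <- fld(3)
  breed <- fld(4); morph <- fld(5)
  check <- function(code, table, what) {
    unknown <- !(code %in% names(table))
    if (any(unknown))
      stop(sprintf("unknown %s code '%s'; valid codes: %s", what,
                   code[which(unknown)[1]],
                   paste(names(table), collapse = ", ")))
  }
  check(museum, tabs$museum, "museum")
  check(group, tabs$group, "group")
  check(breed, tabs$breed, "breed")
  check(morph, tabs$morphotype, "morphotype")
  if (any((group == "H") != (breed != "aaa")))
    stop("group 'H' must (and only 'H' may) carry a breed code other than 'aaa'")
  if (any((group != "H") != (morph == "A")))
    stop("morphotype 'A' must (and only then) accompany a non-horse group")
  data.frame(
    specimen_id = as.character(id), museum = museum, accession = accession,
    group = group, breed = breed, morphotype = morph,
    museum_label = unname(tabs$museum[museum]),
    group_label = unname(tabs$group[group]),
    breed_label = unname(tabs$breed[breed]),
    morphotype_label = unname(tabs$morphotype[morph]),
    stringsAsFactors = FALSE
  )
}

## ---- TPS ------------------------------------------------------------------

#' Read a TPS landmark file
#'
#' Parses the TPSDig dialect: records begin with `LM=<n>`, followed by n
#' whitespace-separated coordinate lines, optionally followed by `IMAGE=`,
#' `ID=` and `SCALE=` lines. When `SCALE=` is present the coordinates are
#' multiplied by it at read time; the stored y-axis convention is preserved
#' (no flip).
#'
#' @param path path to a TPS file.
#' @return A [landmark_dataset()] (2D). An empty file yields an empty dataset.
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(landmark_dataset(list()))
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L)
    stop("not a TPS file: no LM= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  ids <- character(length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    nlm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1],
                                           ignore.case = TRUE)))
    if (is.na(nlm)) stop(sprintf("record %d: unreadable LM= count", r))
    keyed <- grepl("^[A-Za-z]+\\s*=", block[-1])
    coord_lines <- block[-1][!keyed]
    if (length(coord_lines) != nlm)
      stop(sprintf(
        "record %d: LM=%d but %d coordinate lines found", r, nlm,
        length(coord_lines)))
    xy <- do.call(rbind, lapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(v) != 2L || any(is.na(v)))
        stop(sprintf("record %d: malformed coordinate line '%s'", r, l))
      v
    }))
    key_lines <- block[-1][keyed]
    getkey <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), key_lines, ignore.case = TRUE,
                  value = TRUE)
      if (length(hit)) sub("^[A-Za-z]+\\s*=\\s*", "", hit[1]) else NA_character_
    }
    scale <- getkey("SCALE")
    if (!is.na(scale)) xy <- xy * as.numeric(scale)
    id <- getkey("ID")
    if (is.na(id)) id <- getkey("IMAGE")
    if (is.na(id)) id <- sprintf("record%03d", r)
    configs[[r]] <- xy
    ids[r] <- id
  }
  landmark_dataset(configs, ids = ids)
}

#' Write a TPS landmark file
#'
#' Inverse of [read_tps()]: one `LM=` record per specimen, coordinates in
#' full precision, `ID=` lines carrying the specimen identifiers. No
#' `SCALE=` lines are written (coordinates are stored as held in memory),
#' so `read_tps(write_tps(x))` round-trips exactly.
#'
#' @param dataset a [landmark_dataset()] with `m = 2`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (dataset$n > 0 && dataset$m != 2L)
    stop("TPS files store 2D landmarks only")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dataset$n)) {
    cc <- dataset$coords[, , i]
    writeLines(sprintf("LM=%d", dataset$k), con)
    writeLines(paste(format(cc[, 1], digits = 17, trim = TRUE),
                     format(cc[, 2], digits = 17, trim = TRUE)), con)
    writeLines(sprintf("ID=%s", dataset$ids[i]), con)
  }
  invisible(path)
}

## ---- tabular --------------------------------------------------------------

#' Read a wide landmark table
#'
#' Reads delimited text with one specimen per row: an identifier column
#' followed by `k * dims` coordinate columns. Two column layouts are
#' supported: `"interleaved"` (x1 y1 \[z1\] x2 y2 ...; the default, matching
#' raw digitizer exports) and `"blocked"` (all x, then all y, then all z).
#' Identifier strings are decoded with [parse_id_string()] unless
#' `parse_ids = FALSE`.
#'
#' @param path path to a delimited file (delimiter sniffed from the
#'   extension: `.csv` comma, otherwise whitespace/tab).
#' @param dims landmark dimensionality m (2 or 3).
#' @param layout `"interleaved"` or `"blocked"` coordinate column order.
#' @param id_col index of the identifier column (default 1).
#' @param parse_ids decode specimen metadata from the identifiers?
#' @param delim optional explicit field delimiter.
#' @return A [landmark_dataset()]; metadata attached when `parse_ids`.
#' @export
read_landmark_table <- function(path, dims, layout = c("interleaved", "blocked"),
                                id_col = 1L, parse_ids = TRUE, delim = NULL) {
  layout <- match.arg(layout)
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[id_col]])
  num <- as.matrix(tab[, -id_col, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")  # bad cells caught below
  if (ncol(num) %% dims != 0L)
    stop("coordinate column count ", ncol(num),
         " is not a multiple of dims = ", dims)
  k <- ncol(num) %/% dims
  bad <- which(rowSums(!is.finite(num)) > 0)
  if (length(bad))
    stop("specimen '", ids[bad[1]], "' has missing or non-numeric coordinates")
  configs <- vector("list", nrow(num))
  for (i in seq_len(nrow(num))) {
    configs[[i]] <- if (layout == "interleaved")
      matrix(num[i, ], k, dims, byrow = TRUE)
    else
      matrix(num[i, ], k, dims, byrow = FALSE)
  }
  meta <- if (parse_ids) parse_id_string(ids) else NULL
  landmark_dataset(configs, ids = ids, meta = meta)
}

#' Write a wide landmark table
#'
#' Inverse of [read_landmark_table()] for the interleaved layout; writes
#' full-precision coordinates so the round trip is lossless.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output path (`.csv` written comma-separated, otherwise
#'   tab-separated).
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  flat <- flatten_coords(dataset$coords)
  ax <- c("x", "y", "z")[seq_len(dataset$m)]
  colnames(flat) <- paste0("L", rep(seq_len(dataset$k), each = dataset$m),
                           "_", rep(ax, dataset$k))
  df <- data.frame(ID_String = dataset$ids, flat, check.names = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # format() keeps 17 significant digits so read/write round trips exactly
  for (j in seq_along(df)[-1]) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export specimen metadata as CSV
#'
#' @param dataset a [landmark_dataset()] with metadata.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (is.null(dataset$meta)) stop("dataset carries no metadata")
  utils::write.csv(dataset$meta, path, row.names = FALSE)
  invisible(path)
}
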