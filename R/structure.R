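#' Load a macromolecular structure from PDB or mmCIF
#'
#' Thin wrapper around bio3d's coordinate readers that normalises the atom
#' records into a tidy table and separates metal sites. By default only
#' alternate location `A` (or blank) is kept, waters are dropped, and
#' hydrogens are ignored; atoms with occupancy below 0.5 are retained but
#' flagged.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param altloc Alternate-location identifier to keep (besides blank).
#' @param drop_waters Drop HOH/WAT residues (default `TRUE`).
#' @return A `structure_model` object: a list with `atoms` (tibble: `chain`,
#'   `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `o`, `b`,
#'   `low_occupancy`) and `metals` (same columns, one row per metal atom).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           altloc = "A", drop_waters = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
                     stop("cannot infer coordinate format from extension '",
                          ext, "'; pass format explicitly", call. = FALSE))
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    stop("no atom records found in ", format, " file '", path, "'",
         call. = FALSE)
  }
  as_structure_model(pdb$atom, altloc = altloc, drop_waters = drop_waters)
}

#' Build a structure model from an atom table
#'
#' @param atoms A data frame of atom records with at least `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`; missing `chain`, `insert`, `elesy`, `o`, `b`
#'   and `alt` columns are filled with defaults.
#' @inheritParams read_structure
#' @return A `structure_model`.
#' @export
as_structure_model <- function(atoms, altloc = "A", drop_waters = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  defaults <- list(chain = "A", insert = NA_character_, alt = NA_character_,
                   o = 1, b = 0, elesy = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  if (all(is.na(atoms$elesy))) {
    atoms$elesy <- substr(gsub("[0-9']", "", atoms$elety), 1, 1)
  }
  atoms <- dplyr::filter(atoms,
                         is.na(.data$alt) | .data$alt %in% c("", altloc))
  if (drop_waters) {
    atoms <- dplyr::filter(atoms, !.data$resid %in% c("HOH", "WAT", "DOD"))
  }
  atoms <- dplyr::filter(atoms, toupper(.data$elesy) != "H")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  atoms <- dplyr::mutate(atoms, low_occupancy = .data$o < 0.5)
  is_metal <- toupper(atoms$elesy) %in%
    c("ZN", "MG", "MN", "FE", "CU", "NI", "CO", "CA", "NA", "K") &
    atoms$resid %in% c("ZN", "MG", "MN", "FE", "CU", "NI", "CO", "CA", "NA", "K")
  keep <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b", "low_occupancy")
  structure(list(atoms = atoms[!is_metal, keep],
                 metals = atoms[is_metal, keep]),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
      "residues,", nrow(x$metals), "metal atom(s)\n")
  invisible(x)
}

#' Extract ordered C-alpha coordinates for a residue span
#'
#' @param struct A `structure_model`.
#' @param span Length-2 integer vector `c(start, end)` of author residue
#'   numbers (inclusive), or `NULL` for all residues.
#' @param chain Chain identifier, or `NULL` for the first chain.
#' @return A numeric matrix (n x 3) with residue numbers as rownames, in
#'   ascending residue order.
#' @export
ca_coords <- function(struct, span = NULL, chain = NULL) {
  a <- struct$atoms
  chain <- chain %||% a$chain[1]
  a <- dplyr::filter(a, .data$chain == !!chain, .data$elety == "CA")
  if (!is.null(span)) a <- dplyr::filter(a, .data$resno >= span[1], .data$resno <= span[2])
  a <- dplyr::arrange(a, .data$resno)
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Write a structure model as a PDB file
#'
#' @param struct A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  all_atoms <- dplyr::bind_rows(struct$atoms, struct$metals)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(all_atoms[, c("x", "y", "z")]))),
    resno = all_atoms$resno, resid = all_atoms$resid,
    eleno = seq_len(nrow(all_atoms)), elety = all_atoms$elety,
    chain = all_atoms$chain, o = all_atoms$o, b = all_atoms$b,
    elesy = all_atoms$elesy
  )
  invisible(path)
}
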