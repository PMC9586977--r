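#' Score the conserved-residue ortholog checklist
#'
#' Candidate structural orthologs of the tandem zf-C3HC + Rsm1 fold are
#' evaluated against 18 conservation criteria: for each of the two modules,
#' the \U03B1A arginine anchor, a Ser/Thr three residues downstream of it,
#' the `G\U03A9` turn dipeptide, the four Zn-coordinating residues with
#' family-consistent spacing (Cys, Cys at spacer 1--3, His at spacer 10--160,
#' Cys), the exact 3-residue His-to-Cys spacer, and an aromatic residue
#' within three positions after the last cysteine. Each criterion is
#' evaluated independently, so a single substitution or a missing entry
#' lowers the count by at most the criteria that reference it.
#'
#' @param residue_map A tibble with columns `module` (`"zf_C3HC"` or
#'   `"Rsm1"`), `role` (one of `"R"`, `"ST"`, `"G"`, `"OmegaG"`, `"C1"`,
#'   `"C2"`, `"H"`, `"C3"`, `"OmegaF"`), `residue` (one-letter code, `NA`
#'   when absent) and `position` (1-based index, `NA` when absent). Omitted
#'   roles count as absent; duplicate module/role keys are an error.
#' @param aromatics Characters accepted as \U03A9 (default F, W, Y).
#' @return A list of class `checklist_report`: `criteria` (tibble with
#'   `module`, `criterion`, `satisfied`), `satisfied_count`, `total` (18).
#' @examples
#' ortholog_checklist(scpml39_residue_map())$satisfied_count  # 18
#' @export
ortholog_checklist <- function(residue_map, aromatics = c("F", "W", "Y")) {
  stopifnot(all(c("module", "role", "residue", "position") %in% names(residue_map)))
  key <- paste(residue_map$module, residue_map$role)
  if (anyDuplicated(key)) {
    stop("duplicate criterion keys in residue map: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  residue_map$residue <- toupper(residue_map$residue)
  # X and gap characters never satisfy a criterion
  residue_map$residue[residue_map$residue %in% c("X", "-", ".")] <- NA_character_

  crit <- purrr::map_dfr(c("zf_C3HC", "Rsm1"), function(mod) {
    m <- residue_map[residue_map$module == mod, , drop = FALSE]
    get <- function(role) {
      row <- m[m$role == role, , drop = FALSE]
      if (nrow(row) == 0) list(res = NA_character_, pos = NA_integer_)
      else list(res = row$residue[1], pos = as.integer(row$position[1]))
    }
    r <- get("R"); st <- get("ST"); g <- get("G"); og <- get("OmegaG")
    c1 <- get("C1"); c2 <- get("C2"); h <- get("H"); c3 <- get("C3")
    of <- get("OmegaF")
    sp <- function(a, b) if (is.na(a$pos) || is.na(b$pos) || b$pos <= a$pos)
      NA_integer_ else spacer_length(a$pos, b$pos)
    s12 <- sp(c1, c2); s2h <- sp(c2, h); sh3 <- sp(h, c3)
    tibble::tibble(
      module = mod,
      criterion = c("arg_anchor", "st_plus3", "g_omega", "c1", "c2", "h", "c3",
                    "h_c3_spacer", "post_c3_aromatic"),
      satisfied = c(
        identical(r$res, "R"),
        isTRUE(st$res %in% c("S", "T")) && !is.na(r$pos) && !is.na(st$pos) &&
          st$pos == r$pos + 3L,
        identical(g$res, "G") && isTRUE(og$res %in% aromatics) &&
          !is.na(g$pos) && !is.na(og$pos) && og$pos == g$pos + 1L,
        identical(c1$res, "C"),
        identical(c2$res, "C") && isTRUE(s12 >= 1L) && isTRUE(s12 <= 3L),
        identical(h$res, "H") && isTRUE(s2h >= 10L) && isTRUE(s2h <= 160L),
        identical(c3$res, "C"),
        isTRUE(sh3 == 3L),
        isTRUE(of$res %in% aromatics) && !is.na(c3$pos) && !is.na(of$pos) &&
          of$pos > c3$pos && of$pos <= c3$pos + 3L
      )
    )
  })
  structure(
    list(criteria = crit,
         satisfied_count = sum(crit$satisfied),
         total = nrow(crit)),
    class = "checklist_report"
  )
}

#' @export
print.checklist_report <- function(x, ...) {
  cat("Ortholog conservation checklist: ", x$satisfied_count, "/", x$total,
      " criteria met\n", sep = "")
  failed <- x$criteria[!x$criteria$satisfied, , drop = FALSE]
  if (nrow(failed) > 0) {
    cat("unmet:", paste(failed$module, failed$criterion, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a checklist residue map from explicit positions
#'
#' Convenience constructor pairing the nine checklist roles of one module
#' with residue identities and 1-based positions.
#'
#' @param module `"zf_C3HC"` or `"Rsm1"`.
#' @param residues,positions Vectors of length 9 in role order `R`, `ST`,
#'   `G`, `OmegaG`, `C1`, `C2`, `H`, `C3`, `OmegaF`; use `NA` for absent.
#' @return A 9-row tibble suitable for [ortholog_checklist()].
#' @export
residue_map_row <- function(module, residues, positions) {
  roles <- c("R", "ST", "G", "OmegaG", "C1", "C2", "H", "C3", "OmegaF")
  stopifnot(length(residues) == 9, length(positions) == 9)
  tibble::tibble(module = module, role = roles,
                 residue = as.character(residues),
                 position = as.integer(positions))
}

#' Reference residue maps for known tandem-fold proteins
#'
#' Residue maps of proteins with the tandem zf-C3HC + Rsm1 architecture,
#' keyed by the published residue numbering: budding-yeast Pml39 (the
#' reference fold), fission-yeast Rsm1, and human NIPA/ZC3HC1. All three
#' satisfy the full 18-criterion checklist; note that the NIPA zf-C3HC module
#' carries a single residue between its first two cysteines, a non-canonical
#' C-x1-C spacing that the default grammar range (1--3) deliberately admits.
#'
#' @return An 18-row residue-map tibble.
#' @export
scpml39_residue_map <- function() {
  dplyr::bind_rows(
    residue_map_row("zf_C3HC",
                    c("R", "S", "G", "W", "C", "C", "H", "C", "W"),
                    c(89, 92, 118, 119, 134, 137, 172, 176, 178)),
    residue_map_row("Rsm1",
                    c("R", "T", "G", "Y", "C", "C", "H", "C", "Y"),
                    c(202, 205, 256, 257, 268, 271, 288, 292, 294))
  )
}

#' @rdname scpml39_residue_map
#' @export
sprsm1_residue_map <- function() {
  dplyr::bind_rows(
    residue_map_row("zf_C3HC",
                    c("R", "T", "G", "W", "C", "C", "H", "C", "W"),
                    c(49, 52, 74, 75, 85, 88, 126, 130, 132)),
    residue_map_row("Rsm1",
                    c("R", "S", "G", "W", "C", "C", "H", "C", "W"),
                    c(156, 159, 204, 205, 216, 219, 241, 245, 247))
  )
}

#' @rdname scpml39_residue_map
#' @export
hsnipa_residue_map <- function() {
  dplyr::bind_rows(
    residue_map_row("zf_C3HC",
                    c("R", "T", "G", "W", "C", "C", "H", "C", "W"),
                    c(81, 84, 106, 107, 118, 120, 152, 156, 158)),
    residue_map_row("Rsm1",
                    c("R", "S", "G", "W", "C", "C", "H", "C", "W"),
                    c(185, 188, 255, 256, 272, 275, 425, 429, 431))
  )
}
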