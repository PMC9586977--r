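#' Spacer grammar for the BIR-like CCHC zinc finger
#'
#' The BIR-like clan (canonical BIR, zf-C3HC and Rsm1 families) is defined by
#' a Cys-Cys-His-Cys zinc-binding motif with family-specific spacing between
#' the four Zn-coordinating residues. In the spacer notation
#' `C-x(a)-C-x(b)-H-x(c)-C`, a spacer counts the residues strictly between two
#' ligands. The canonical BIR consensus is `C-x2-C-x16-H-x6-C`; zf-C3HC and
#' Rsm1 share a shortened His-to-Cys linker, `C-x2-C-xn-H-x3-C`. The
#' His-to-Cys spacer (6 vs 3) is the hard family discriminator; the first two
#' spacers are ranges, wide enough to admit known family members, including
#' orthologs with a single residue between the first two cysteines and with a
#' ~135-residue insertion between the second cysteine and the histidine.
#'
#' @param family One of `"canonical_BIR"`, `"zf_C3HC"`, `"Rsm1"`.
#' @param c1_c2 Optional length-2 integer vector overriding the allowed range
#'   of the Cys1-Cys2 spacer (default 1--3).
#' @param c2_h Optional length-2 integer vector overriding the allowed range
#'   of the Cys2-His spacer (default 10--160).
#' @param h_c3 Optional single integer overriding the exact His-Cys3 spacer
#'   (default 6 for canonical BIR, 3 otherwise).
#'
#' @return A one-row tibble with columns `family`, `c1_c2_min`, `c1_c2_max`,
#'   `c2_h_min`, `c2_h_max`, `h_c3`.
#' @examples
#' znf_grammar("zf_C3HC")
#' znf_grammar("canonical_BIR")$h_c3  # 6
#' @export
znf_grammar <- function(family = c("canonical_BIR", "zf_C3HC", "Rsm1"),
                        c1_c2 = NULL, c2_h = NULL, h_c3 = NULL) {
  if (length(family) == 1 && !family %in% c("canonical_BIR", "zf_C3HC", "Rsm1")) {
    stop("unknown ZnF family '", family,
         "'; expected one of canonical_BIR, zf_C3HC, Rsm1", call. = FALSE)
  }
  family <- match.arg(family)
  c1_c2 <- c1_c2 %||% c(1L, 3L)
  c2_h <- c2_h %||% c(10L, 160L)
  h_c3 <- h_c3 %||% if (family == "canonical_BIR") 6L else 3L
  stopifnot(length(c1_c2) == 2, length(c2_h) == 2, length(h_c3) == 1,
            all(c1_c2 >= 0), all(c2_h >= 0), h_c3 >= 0,
            c1_c2[1] <= c1_c2[2], c2_h[1] <= c2_h[2])
  tibble::tibble(
    family = family,
    c1_c2_min = as.integer(c1_c2[1]), c1_c2_max = as.integer(c1_c2[2]),
    c2_h_min = as.integer(c2_h[1]), c2_h_max = as.integer(c2_h[2]),
    h_c3 = as.integer(h_c3)
  )
}

#' Number of residues strictly between two sequence positions
#'
#' Spacer arithmetic used throughout the motif grammar: with 1-based residue
#' indices `i < j`, the spacer is `j - i - 1`. For example, Zn-coordinating
#' residues at positions 137 and 172 are separated by a 34-residue spacer.
#'
#' @param i,j 1-based residue indices, `j > i` elementwise (recycled).
#' @return Integer vector of spacer lengths.
#' @examples
#' spacer_length(137, 172)  # 34
#' spacer_length(172, 176)  # 3
#' @export
spacer_length <- function(i, j) {
  if (any(j <= i)) stop("spacer_length() requires j > i", call. = FALSE)
  as.integer(j - i - 1L)
}

# 20-letter alphabet; X tolerated in input but never matches C/H or anchors
.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")

.seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(.aa_alphabet, "X"))
  if (length(bad) > 0) {
    stop("sequence contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars
}

#' Scan a protein sequence for CCHC zinc-finger motifs
#'
#' Enumerates all index quadruples (C1, C2, H, C3) whose inter-ligand spacers
#' satisfy a family grammar. All candidates are reported, including
#' overlapping ones; filtering (e.g. keeping the best-scoring match per
#' region) is left to the caller. `X` is tolerated in the sequence but never
#' matches a coordinating position.
#'
#' @param sequence Amino-acid string (single record).
#' @param grammar A grammar tibble from [znf_grammar()].
#' @return A tibble with one row per match: `c1`, `c2`, `h`, `c3` (1-based
#'   indices), spacers `c1_c2`, `c2_h`, `h_c3`, and `family`; rows sorted by
#'   ascending `c1`, then `c2`, then `h`.
#' @examples
#' s <- paste(rep("A", 60), collapse = "")
#' substr(s, 10, 10) <- "C"; substr(s, 13, 13) <- "C"
#' substr(s, 48, 48) <- "H"; substr(s, 52, 52) <- "C"
#' scan_znf(s, znf_grammar("zf_C3HC"))
#' @export
scan_znf <- function(sequence, grammar) {
  if (nchar(sequence) == 0) return(.empty_match(grammar$family))
  chars <- .seq_chars(sequence)
  cpos <- which(chars == "C")
  hpos <- which(chars == "H")
  if (length(cpos) < 3 || length(hpos) < 1) return(.empty_match(grammar$family))

  out <- list()
  for (c1 in cpos) {
    c2s <- cpos[cpos > c1 &
                  (cpos - c1 - 1L) >= grammar$c1_c2_min &
                  (cpos - c1 - 1L) <= grammar$c1_c2_max]
    for (c2 in c2s) {
      hs <- hpos[hpos > c2 &
                   (hpos - c2 - 1L) >= grammar$c2_h_min &
                   (hpos - c2 - 1L) <= grammar$c2_h_max]
      for (h in hs) {
        c3 <- h + grammar$h_c3 + 1L
        if (c3 <= length(chars) && chars[c3] == "C") {
          out[[length(out) + 1L]] <- c(c1, c2, h, c3)
        }
      }
    }
  }
  if (length(out) == 0) return(.empty_match(grammar$family))
  m <- do.call(rbind, out)
  res <- tibble::tibble(
    c1 = as.integer(m[, 1]), c2 = as.integer(m[, 2]),
    h = as.integer(m[, 3]), c3 = as.integer(m[, 4])
  )
  res <- dplyr::mutate(res,
    c1_c2 = spacer_length(.data$c1, .data$c2),
    c2_h = spacer_length(.data$c2, .data$h),
    h_c3 = spacer_length(.data$h, .data$c3),
    family = grammar$family
  )
  dplyr::arrange(res, .data$c1, .data$c2, .data$h)
}

.empty_match <- function(family = character(0)) {
  tibble::tibble(
    c1 = integer(0), c2 = integer(0), h = integer(0), c3 = integer(0),
    c1_c2 = integer(0), c2_h = integer(0), h_c3 = integer(0),
    family = character(0)
  )
}
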