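#' Locate the conserved BIR-like anchor motifs around a zinc-finger match
#'
#' Beyond the CCHC zinc finger, BIR-like modules share three sequence
#' anchors: the `Rxx(S/T)\U03A9` motif in helix \U03B1A (an arginine, a
#' serine/threonine three residues downstream, and optionally an aromatic at
#' +4), an invariant `G\U03A9` dipeptide in the sharp turn between helix
#' \U03B1B and strand \U03B21, and a final aromatic residue shortly after the
#' last Zn-coordinating cysteine, which packs against helix \U03B1B like a
#' lid. Anchors are searched relative to the zinc-finger match: the nearest
#' `Rxx(S/T)` upstream of C1 within `upstream_window` residues (falling back
#' to the nearest bare arginine when no full motif exists), the last
#' `G\U03A9` between the arginine (or window start) and C1, and the first
#' aromatic within `post_c3_window` residues after C3. An absent anchor is a
#' result (an `NA` position), not an error.
#'
#' @param sequence Amino-acid string.
#' @param match One-row tibble from [scan_znf()] (columns `c1`, `c2`, `h`,
#'   `c3`).
#' @param upstream_window Residues upstream of C1 searched for the arginine
#'   anchor. The default (100) spans the distance from the \U03B1A' arginine
#'   to the first cysteine in known Rsm1 modules, where a long insertion
#'   separates them.
#' @param aromatics Characters accepted as \U03A9 (default F, W, Y).
#' @param post_c3_window Residues after C3 searched for the final aromatic.
#' @return A one-row tibble with columns `r_pos`, `st_pos`, `omega_a_pos`,
#'   `g_pos`, `omega_g_pos`, `final_omega_pos` (1-based indices, `NA` when
#'   absent).
#' @export
find_anchors <- function(sequence, match, upstream_window = 100,
                         aromatics = c("F", "W", "Y"), post_c3_window = 3) {
  chars <- .seq_chars(sequence)
  stopifnot(nrow(match) == 1, match$c3 <= length(chars))
  c1 <- match$c1
  lo <- max(1L, c1 - as.integer(upstream_window))

  r_pos <- NA_integer_; st_pos <- NA_integer_; omega_a_pos <- NA_integer_
  up <- seq(lo, c1 - 1L)
  rs <- up[chars[up] == "R"]
  if (length(rs) > 0) {
    # prefer the nearest upstream Arg completing Rxx(S/T); else nearest Arg
    full <- rs[rs + 3L < c1 & chars[rs + 3L] %in% c("S", "T")]
    r_pos <- if (length(full) > 0) max(full) else max(rs)
    if (r_pos + 3L < c1 && chars[r_pos + 3L] %in% c("S", "T")) {
      st_pos <- r_pos + 3L
    }
    if (r_pos + 4L < c1 && chars[r_pos + 4L] %in% aromatics) {
      omega_a_pos <- r_pos + 4L
    }
  }

  g_pos <- NA_integer_; omega_g_pos <- NA_integer_
  g_lo <- if (!is.na(r_pos)) r_pos + 1L else lo
  if (g_lo < c1 - 1L) {
    gw <- seq(g_lo, c1 - 2L)
    gs <- gw[chars[gw] == "G" & chars[gw + 1L] %in% aromatics]
    if (length(gs) > 0) {
      g_pos <- max(gs)  # the last G-aromatic before the zinc finger
      omega_g_pos <- g_pos + 1L
    }
  }

  final_omega_pos <- NA_integer_
  post <- seq(match$c3 + 1L, min(length(chars), match$c3 + as.integer(post_c3_window)))
  post <- post[post > match$c3]
  om <- post[chars[post] %in% aromatics]
  if (length(om) > 0) final_omega_pos <- min(om)

  tibble::tibble(r_pos = r_pos, st_pos = st_pos, omega_a_pos = omega_a_pos,
                 g_pos = g_pos, omega_g_pos = omega_g_pos,
                 final_omega_pos = final_omega_pos)
}

#' Classify a zinc-finger match into a BIR-like family module
#'
#' A His-to-Cys spacer of 6 identifies a canonical BIR module. With the
#' shortened spacer of 3, zf-C3HC and Rsm1 are distinguished by the distance
#' from the \U03B1A arginine anchor to the `G\U03A9` dipeptide: the Rsm1
#' module carries an extra helix (\U03B1AB') and a Ser-rich insertion in that
#' interval, so a distance above `insertion_threshold` calls Rsm1 (in the
#' reference fold the distances are 29 for zf-C3HC and 54 for Rsm1). When the
#' arginine anchor is absent the call falls back to the Cys2-His spacer:
#' above the same threshold (as in orthologs carrying a long insertion before
#' the histidine) the module is called Rsm1, otherwise zf-C3HC.
#'
#' The module span runs from the arginine anchor (or `c1 - span_upstream`
#' when absent) to the final aromatic (or `c3 + span_tail` when absent),
#' clamped to the sequence.
#'
#' @inheritParams find_anchors
#' @param anchors Optional anchor tibble from [find_anchors()]; computed if
#'   missing.
#' @param insertion_threshold Residue distance above which the
#'   arginine-to-G\U03A9 interval indicates the Rsm1 insertion (default 40).
#' @param span_upstream,span_tail Span padding: `span_upstream` substitutes
#'   for an absent arginine anchor (default 45, the arginine-to-Cys1 offset
#'   in the reference fold); `span_tail` extends the span past the final
#'   aromatic (default 15, bracketing the observed 11--17 residue
#'   carboxy-terminal extents of the reference modules).
#' @return A one-row tibble: `kind`, `span_start`, `span_end`, the match
#'   columns, the anchor columns, and `score` (fraction of the 9 per-module
#'   conservation criteria met).
#' @export
classify_module <- function(sequence, match, anchors = NULL,
                            insertion_threshold = 40,
                            span_upstream = 45, span_tail = 15,
                            upstream_window = 100,
                            aromatics = c("F", "W", "Y")) {
  chars <- .seq_chars(sequence)
  stopifnot(nrow(match) == 1)
  if (!(match$c1 < match$c2 && match$c2 < match$h && match$h < match$c3) ||
      chars[match$c1] != "C" || chars[match$c2] != "C" ||
      chars[match$h] != "H" || chars[match$c3] != "C") {
    stop("match does not satisfy the CCHC grammar", call. = FALSE)
  }
  if (is.null(anchors)) {
    anchors <- find_anchors(sequence, match, upstream_window = upstream_window,
                            aromatics = aromatics)
  }

  h_c3 <- spacer_length(match$h, match$c3)
  if (h_c3 == 6L) {
    kind <- "canonical_BIR"
  } else {
    if (!is.na(anchors$r_pos) && !is.na(anchors$g_pos)) {
      kind <- if (anchors$g_pos - anchors$r_pos > insertion_threshold)
        "Rsm1" else "zf_C3HC"
    } else {
      # anchor-free fallback: a long Cys2-His spacer marks the Rsm1 insertion
      kind <- if (spacer_length(match$c2, match$h) > insertion_threshold)
        "Rsm1" else "zf_C3HC"
    }
  }

  span_start <- if (!is.na(anchors$r_pos)) anchors$r_pos else
    max(1L, match$c1 - as.integer(span_upstream))
  span_end <- if (!is.na(anchors$final_omega_pos))
    min(length(chars), anchors$final_omega_pos + as.integer(span_tail)) else
    min(length(chars), match$c3 + as.integer(span_tail))

  crit <- module_criteria(chars, match, anchors, kind, aromatics = aromatics)
  dplyr::bind_cols(
    tibble::tibble(kind = kind, span_start = as.integer(span_start),
                   span_end = as.integer(span_end)),
    match[, c("c1", "c2", "h", "c3", "c1_c2", "c2_h", "h_c3")],
    anchors,
    tibble::tibble(score = mean(crit$satisfied))
  )
}

# the 9 per-module conservation criteria, evaluated independently
module_criteria <- function(chars, match, anchors, kind,
                            aromatics = c("F", "W", "Y"),
                            c1_c2_range = c(1L, 3L), c2_h_range = c(10L, 160L)) {
  h_c3_expected <- if (kind == "canonical_BIR") 6L else 3L
  at <- function(pos) if (is.na(pos) || pos < 1 || pos > length(chars))
    NA_character_ else chars[pos]
  s12 <- spacer_length(match$c1, match$c2)
  s2h <- spacer_length(match$c2, match$h)
  tibble::tibble(
    criterion = c("arg_anchor", "st_plus3", "g_omega", "c1", "c2", "h", "c3",
                  "h_c3_spacer", "post_c3_aromatic"),
    satisfied = c(
      identical(at(anchors$r_pos), "R"),
      !is.na(anchors$r_pos) && !is.na(anchors$st_pos) &&
        anchors$st_pos == anchors$r_pos + 3L &&
        at(anchors$st_pos) %in% c("S", "T"),
      identical(at(anchors$g_pos), "G") &&
        isTRUE(at(anchors$omega_g_pos) %in% aromatics),
      identical(at(match$c1), "C"),
      identical(at(match$c2), "C") && s12 >= c1_c2_range[1] && s12 <= c1_c2_range[2],
      identical(at(match$h), "H") && s2h >= c2_h_range[1] && s2h <= c2_h_range[2],
      identical(at(match$c3), "C"),
      spacer_length(match$h, match$c3) == h_c3_expected,
      isTRUE(at(anchors$final_omega_pos) %in% aromatics)
    )
  )
}

#' Annotate all BIR-like modules in one sequence
#'
#' Scans a sequence under the requested family grammars, classifies every
#' match, and resolves overlapping candidates by keeping the
#' highest-conservation-score module (ties broken by the smaller first
#' cysteine index).
#'
#' @inheritParams classify_module
#' @param families Families to scan for (default all three).
#' @param keep_overlaps If `TRUE`, return all classified matches without
#'   overlap resolution.
#' @return A tibble of module annotations (one row per retained module),
#'   sorted by `span_start`.
#' @export
annotate_modules <- function(sequence, families = c("canonical_BIR", "zf_C3HC", "Rsm1"),
                             insertion_threshold = 40, upstream_window = 100,
                             aromatics = c("F", "W", "Y"), keep_overlaps = FALSE) {
  # zf_C3HC and Rsm1 share one grammar (h_c3 = 3); scan it once
  gs <- list()
  if ("canonical_BIR" %in% families) gs <- c(gs, list(znf_grammar("canonical_BIR")))
  if (any(c("zf_C3HC", "Rsm1") %in% families)) gs <- c(gs, list(znf_grammar("zf_C3HC")))
  hits <- dplyr::bind_rows(lapply(gs, function(g) scan_znf(sequence, g)))
  if (nrow(hits) == 0) return(.empty_annotation())
  ann <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    classify_module(sequence, hits[i, ], insertion_threshold = insertion_threshold,
                    upstream_window = upstream_window, aromatics = aromatics)
  })
  ann <- dplyr::filter(ann, .data$kind %in% families)
  if (nrow(ann) == 0) return(.empty_annotation())
  if (!keep_overlaps) ann <- resolve_overlaps(ann)
  dplyr::arrange(ann, .data$span_start)
}

.empty_annotation <- function() {
  dplyr::bind_cols(
    tibble::tibble(kind = character(0), span_start = integer(0), span_end = integer(0)),
    .empty_match()[, 1:7],
    tibble::tibble(r_pos = integer(0), st_pos = integer(0), omega_a_pos = integer(0),
                   g_pos = integer(0), omega_g_pos = integer(0),
                   final_omega_pos = integer(0), score = numeric(0))
  )
}

# greedy overlap resolution: best score first, then smaller c1
resolve_overlaps <- function(ann) {
  ord <- order(-ann$score, ann$c1)
  keep <- logical(nrow(ann))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (ann$span_start[i] <= ann$span_end[j] &&
          ann$span_end[i] >= ann$span_start[j]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  ann[keep, , drop = FALSE]
}

#' Call the tandem zf-C3HC + Rsm1 architecture (Pml39 fold)
#'
#' The Pml39 fold is a single structural domain formed by a zf-C3HC module
#' followed, N- to C-terminally, by an Rsm1 module. The call is positive iff
#' the annotations contain a zf-C3HC module whose span ends before the first
#' Zn-coordinating cysteine of a downstream Rsm1 module. A reversed
#' arrangement is reported but not called a Pml39 fold.
#'
#' @param sequence_id Identifier carried into the result.
#' @param annotations Module annotations from [annotate_modules()]
#'   (non-overlapping).
#' @return A one-row tibble: `sequence_id`, `is_pml39_fold`, the spans and
#'   scores of the participating modules (`NA` when missing), the combined
#'   `satisfied_count` out of `total` (18) conservation criteria, and a
#'   list-column `checklist` holding the per-criterion breakdown.
#' @export
detect_pml39_fold <- function(sequence_id, annotations) {
  zf <- dplyr::filter(annotations, .data$kind == "zf_C3HC")
  rs <- dplyr::filter(annotations, .data$kind == "Rsm1")
  pair <- NULL
  if (nrow(zf) > 0 && nrow(rs) > 0) {
    for (i in seq_len(nrow(zf))) {
      cand <- rs[rs$c1 > zf$span_end[i], , drop = FALSE]
      if (nrow(cand) > 0) { pair <- list(zf = zf[i, ], rsm1 = cand[1, ]); break }
    }
  }
  is_fold <- !is.null(pair)
  zf1 <- if (is_fold) pair$zf else if (nrow(zf) > 0) zf[1, ] else NULL
  rs1 <- if (is_fold) pair$rsm1 else if (nrow(rs) > 0) rs[1, ] else NULL

  n_crit <- function(a) if (is.null(a)) 0L else as.integer(round(a$score * 9))
  satisfied <- n_crit(zf1) + n_crit(rs1)
  tibble::tibble(
    sequence_id = sequence_id,
    is_pml39_fold = is_fold,
    zf_start = if (is.null(zf1)) NA_integer_ else zf1$span_start,
    zf_end = if (is.null(zf1)) NA_integer_ else zf1$span_end,
    zf_score = if (is.null(zf1)) NA_real_ else zf1$score,
    rsm1_start = if (is.null(rs1)) NA_integer_ else rs1$span_start,
    rsm1_end = if (is.null(rs1)) NA_integer_ else rs1$span_end,
    rsm1_score = if (is.null(rs1)) NA_real_ else rs1$score,
    satisfied_count = satisfied,
    total = 18L,
    checklist = list(dplyr::bind_rows(
      if (!is.null(zf1)) tibble::tibble(module = "zf_C3HC", annotation = list(zf1)),
      if (!is.null(rs1)) tibble::tibble(module = "Rsm1", annotation = list(rs1))
    ))
  )
}
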