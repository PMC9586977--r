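#' Scan a FASTA file (or named sequence vector) for BIR-like modules
#'
#' High-level, whole-file interface over [annotate_modules()] and
#' [detect_pml39_fold()]. `scan_fasta()` returns one row per retained module
#' annotation; `fold_call_fasta()` returns one row per sequence with the
#' tandem-architecture call.
#'
#' @param fasta Path to a FASTA file (plain or gzip) or a named character
#'   vector of amino-acid sequences.
#' @param ... Passed on to [annotate_modules()] (families, thresholds,
#'   aromatic alphabet, ...).
#' @return A tibble; `scan_fasta()` adds `sequence_id` to the annotation
#'   columns, `fold_call_fasta()` returns the fold-call columns of
#'   [detect_pml39_fold()].
#' @export
scan_fasta <- function(fasta, ...) {
  seqs <- .read_sequences(fasta)
  purrr::map_dfr(names(seqs), function(id) {
    ann <- annotate_modules(seqs[[id]], ...)
    if (nrow(ann) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(sequence_id = id), ann)
  })
}

#' @rdname scan_fasta
#' @export
fold_call_fasta <- function(fasta, ...) {
  seqs <- .read_sequences(fasta)
  purrr::map_dfr(names(seqs), function(id) {
    detect_pml39_fold(id, annotate_modules(seqs[[id]], ...))
  })
}

.read_sequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    set <- Biostrings::readAAStringSet(fasta)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  stopifnot(is.character(fasta))
  if (is.null(names(fasta)) || any(!nzchar(names(fasta)))) {
    names(fasta) <- paste0("seq", seq_along(fasta))
  }
  fasta
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  lines <- unlist(purrr::imap(seqs, function(s, id) {
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(nchar(s), seq(1, nchar(s), width) + width - 1))
    c(paste0(">", id), body)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
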