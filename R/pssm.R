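#' PSSM profile objects
#'
#' A `pssm_profile` holds one protein's position-specific scoring matrix
#' (PSSM): an N x 20 matrix of per-position amino-acid scores, where N is the
#' sequence length. Columns are always stored in the canonical alphabetical
#' residue order `ACDEFGHIKLMNPQRSTVWY`, whatever order the source file used;
#' the file's own column order is kept in `residue_order` so profiles from
#' different sources are directly comparable downstream.
#'
#' @param matrix Numeric N x 20 matrix (rows = positions, columns = residues
#'   in `residue_order`).
#' @param sequence Character scalar, the amino-acid sequence (length N).
#' @param protein_id Character scalar identifier.
#' @param residue_order 20-letter string giving the column order of `matrix`.
#' @param source One of `"psiblast_ascii"`, `"dayhoff_fallback"`,
#'   `"synthetic"`.
#'
#' @return An object of class `pssm_profile` with fields `protein_id`,
#'   `matrix` (canonically ordered, residue colnames), `residue_order`,
#'   `sequence` and `source`.
#' @export
pssm_profile <- function(matrix, sequence, protein_id = "protein",
                         residue_order = paste(AA_CANONICAL, collapse = ""),
                         source = "psiblast_ascii") {
  ord <- strsplit(residue_order, "")[[1]]
  if (length(ord) != 20L || !setequal(ord, AA_CANONICAL)) {
    abort("`residue_order` must be a permutation of the 20 standard amino-acid letters.")
  }
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (ncol(matrix) != 20L) {
    abort(sprintf("PSSM must have 20 columns, got %d.", ncol(matrix)))
  }
  if (nrow(matrix) < 1L) abort("PSSM must have at least one row.")
  if (!all(is.finite(matrix))) abort("PSSM contains non-finite entries.")
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) != nrow(matrix)) {
    abort(sprintf("Sequence length (%d) does not match PSSM rows (%d).",
                  nchar(sequence), nrow(matrix)))
  }
  # reorder columns into the canonical alphabet once, on ingest
  matrix <- matrix[, match(AA_CANONICAL, ord), drop = FALSE]
  colnames(matrix) <- AA_CANONICAL
  rownames(matrix) <- NULL
  structure(
    list(protein_id = as.character(protein_id), matrix = matrix,
         residue_order = residue_order, sequence = sequence, source = source),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d positions x 20 residues (source: %s)\n",
              x$protein_id, nrow(x$matrix), x$source))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the plain-text matrix that PSI-BLAST writes with `-out_ascii_pssm`:
#' a header line listing the 20-residue column order, then one row per
#' sequence position holding the position index, the query residue, 20
#' integer log-odds scores and 20 weighted-percentage columns. Only the
#' log-odds block is kept; the percentage block (and the two per-position
#' statistics some builds append) is ignored.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Identifier for the profile; defaults to the file name
#'   without extension.
#' @return A [pssm_profile()].
#' @export
parse_psiblast_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) abort(sprintf("PSSM file not found: %s", path))
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  header_idx <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) %in% c(20L, 40L) && all(toks %in% AA_CANONICAL)) {
      header_idx <- i
      break
    }
  }
  if (is.na(header_idx)) {
    abort("Malformed PSSM: no header line with a 20-residue column order found.")
  }
  hdr <- strsplit(trimws(lines[[header_idx]]), "\\s+")[[1]][1:20]
  if (!setequal(hdr, AA_CANONICAL)) {
    abort(sprintf("Malformed PSSM header at line %d: not a permutation of the 20 residues.",
                  header_idx))
  }

  rows <- list(); seq_chars <- character()
  for (i in seq((header_idx + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[[i]])
    if (!grepl("^[0-9]+\\s+[A-Za-z]", ln)) break   # footer or blank ends the block
    toks <- strsplit(ln, "\\s+")[[1]]
    pos <- as.integer(toks[[1]])
    res <- toks[[2]]
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (anyNA(vals) || !length(vals) %in% c(40L, 42L)) {
      abort(sprintf("Malformed PSSM row at position %d (line %d): expected 40 numeric fields, got %d.",
                    pos, i, sum(!is.na(vals))))
    }
    rows[[length(rows) + 1L]] <- vals[1:20]
    seq_chars <- c(seq_chars, toupper(res))
  }
  if (length(rows) == 0L) abort("Malformed PSSM: no data rows found (empty matrix).")

  pssm_profile(do.call(rbind, rows), paste(seq_chars, collapse = ""),
               protein_id = protein_id,
               residue_order = paste(hdr, collapse = ""),
               source = "psiblast_ascii")
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Emits a file that [parse_psiblast_pssm()] reads back to an identical
#' profile (matrix, sequence, and column order all round-trip). The
#' percentage block is written as zeros; non-integer scores are written with
#' full precision so synthetic profiles survive the round trip exactly.
#'
#' @param profile A [pssm_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  ord <- strsplit(profile$residue_order, "")[[1]]
  m <- profile$matrix[, match(ord, AA_CANONICAL), drop = FALSE]
  fmt_num <- function(x) {
    ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
           formatC(x, digits = 17, format = "g"))
  }
  res <- strsplit(profile$sequence, "")[[1]]
  body <- vapply(seq_len(nrow(m)), function(a) {
    paste(c(sprintf("%5d %s", a, res[[a]]),
            sprintf("%6s", fmt_num(m[a, ])), rep("  0", 20L)),
          collapse = " ")
  }, character(1))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed",
    paste0("      ", paste(sprintf("%6s", c(ord, ord)), collapse = " ")),
    body, ""
  ), path)
  invisible(path)
}

#' Amino-acid substitution matrices
#'
#' `substitution_matrix()` wraps a 20 x 20 score matrix with its residue
#' order; `dayhoff_matrix()` returns the Dayhoff-derived PAM250 log-odds
#' mutation matrix (from Biostrings) restricted to the 20 standard residues,
#' the matrix used to build fallback PSSMs for sequences that lack a
#' PSI-BLAST profile.
#'
#' @param scores Numeric 20 x 20 matrix indexed by `residue_order`.
#' @param residue_order 20-letter string naming rows/columns of `scores`.
#' @param name Matrix name.
#' @return A `substitution_matrix` object (fields `name`, `scores` in
#'   canonical order, `residue_order`).
#' @export
substitution_matrix <- function(scores, residue_order = paste(AA_CANONICAL, collapse = ""),
                                name = "custom") {
  ord <- strsplit(residue_order, "")[[1]]
  if (length(ord) != 20L || !setequal(ord, AA_CANONICAL)) {
    abort("`residue_order` must be a permutation of the 20 standard amino-acid letters.")
  }
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (!all(dim(scores) == c(20L, 20L)) || !all(is.finite(scores))) {
    abort("`scores` must be a finite 20 x 20 matrix.")
  }
  perm <- match(AA_CANONICAL, ord)
  scores <- scores[perm, perm, drop = FALSE]
  dimnames(scores) <- list(AA_CANONICAL, AA_CANONICAL)
  structure(list(name = name, scores = scores,
                 residue_order = paste(AA_CANONICAL, collapse = "")),
            class = "substitution_matrix")
}

#' @rdname substitution_matrix
#' @export
dayhoff_matrix <- function() {
  pam <- get(utils::data("PAM250", package = "Biostrings",
                         envir = environment())[[1]], envir = environment())
  substitution_matrix(pam[AA_CANONICAL, AA_CANONICAL],
                      name = "PAM250")
}

#' Fallback PSSM from a bare sequence via a mutation matrix
#'
#' When no PSI-BLAST profile is available, a profile is built by scoring each
#' position against a substitution matrix: with a single sequence the
#' per-position residue frequencies collapse to an indicator, so row alpha of
#' the matrix is simply the substitution-matrix row of the residue at alpha.
#' `'X'` (unknown residue) yields a zero row.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet plus `'X'`.
#' @param subst A [substitution_matrix()]; defaults to [dayhoff_matrix()].
#' @param protein_id Identifier.
#' @return A [pssm_profile()] with `source = "dayhoff_fallback"`.
#' @export
dayhoff_pssm <- function(sequence, subst = dayhoff_matrix(),
                         protein_id = "protein") {
  stopifnot(inherits(subst, "substitution_matrix"))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) abort("`sequence` must be non-empty.")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c(AA_CANONICAL, "X"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown residue(s) in sequence: %s", paste(bad, collapse = ", ")))
  }
  m <- matrix(0, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, AA_CANONICAL))
  known <- chars != "X"
  m[known, ] <- subst$scores[chars[known], , drop = FALSE]
  pssm_profile(m, sequence, protein_id = protein_id,
               source = "dayhoff_fallback")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(id = sub("\\s.*$", "", names(aa)),
                 sequence = as.character(aa))
}
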