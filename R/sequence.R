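#' Construct a protein sequence object
#'
#' A `protein_sequence` is a one-row-per-residue tibble carrying the
#' one-letter residue code and its index in the reference (wild-type)
#' numbering. Non-native N-terminal residues (for example an expression tag)
#' carry indices below `first_index` and are flagged in the `tag` column, so
#' downstream per-residue analyses can keep or drop them explicitly.
#'
#' @param residues character scalar or vector of one-letter residue codes.
#' @param id sequence identifier.
#' @param first_index reference numbering of the first *native* residue.
#' @param tag_length number of non-native N-terminal residues preceding the
#'   native sequence (>= 0). These receive indices `first_index - tag_length`
#'   to `first_index - 1`.
#' @return a tibble of class `protein_sequence` with columns `index`,
#'   `residue`, `tag`, and attributes `id`, `first_index`, `tag_length`.
#' @export
#' @examples
#' protein_sequence("MEL", id = "toy")
protein_sequence <- function(residues, id = "seq", first_index = 1L,
                             tag_length = 0L) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) abort("sequence must contain at least one residue")
  bad <- which(!residues %in% .aa_alphabet)
  if (length(bad) > 0L) {
    abort(sprintf("illegal residue code '%s' at position %d",
                  residues[bad[1]], bad[1]))
  }
  tag_length <- as.integer(tag_length)
  if (tag_length < 0L) abort("tag_length must be >= 0")
  if (tag_length > length(residues)) abort("tag_length exceeds sequence length")
  first_index <- as.integer(first_index)
  idx <- seq_along(residues) + (first_index - tag_length) - 1L
  out <- tibble(
    index = idx,
    residue = residues,
    tag = idx < first_index
  )
  structure(out,
            class = c("protein_sequence", class(out)),
            id = id, first_index = first_index, tag_length = tag_length)
}

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read the first record of a FASTA file as a protein sequence
#'
#' @param path path to a FASTA file with at least one record.
#' @inheritParams protein_sequence
#' @return a [protein_sequence()] tibble.
#' @export
load_sequence <- function(path, first_index = 1L, tag_length = 0L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1L) abort(sprintf("no FASTA records in '%s'", path))
  protein_sequence(as.character(set[[1]]),
                   id = names(set)[1],
                   first_index = first_index,
                   tag_length = tag_length)
}

#' The Im7 sequence with optional alanine substitutions
#'
#' Returns the 87-residue wild-type colicin E7 immunity protein (Im7)
#' sequence shipped with the package, optionally with point substitutions
#' applied (e.g. `c("L18A", "L19A", "L37A")` gives the triple variant whose
#' unfolded state is populated at equilibrium without denaturant).
#'
#' @param variants character vector of substitutions in `X<pos>Y` notation;
#'   the wild-type residue letter is checked against the sequence.
#' @return a [protein_sequence()] tibble.
#' @export
#' @examples
#' im7_sequence(c("L18A", "L19A", "L37A"))
im7_sequence <- function(variants = character()) {
  seq <- load_sequence(system.file("extdata", "im7.fasta", package = "ucoil"))
  res <- seq$residue
  for (v in variants) {
    m <- stringr::str_match(v, "^([A-Z])(\\d+)([A-Z])$")
    if (is.na(m[1, 1])) abort(sprintf("malformed substitution '%s'", v))
    pos <- as.integer(m[1, 3])
    if (pos < 1L || pos > length(res)) {
      abort(sprintf("substitution '%s' outside sequence", v))
    }
    if (res[pos] != m[1, 2]) {
      abort(sprintf("substitution '%s': position %d is '%s'", v, pos, res[pos]))
    }
    res[pos] <- m[1, 4]
  }
  id <- if (length(variants) == 0L) "im7_wild_type" else
    paste0("im7_", paste(variants, collapse = "-"))
  protein_sequence(res, id = id)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d residues (indices %d..%d%s)\n",
              attr(x, "id"), nrow(x), min(x$index), max(x$index),
              if (any(x$tag)) sprintf(", %d tag", sum(x$tag)) else ""))
  NextMethod()
}
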