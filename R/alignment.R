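#' Orthogroup alignment container
#'
#' Constructs the unit of all per-gene computation: a named set of aligned
#' amino acid sequences of equal length. Sequences are stored internally as
#' a species-by-site character matrix.
#'
#' @param sequences Named character vector of aligned sequences (one string
#'   per species), or a species-by-site character matrix with rownames.
#' @param id Orthogroup identifier.
#' @return An object of class `aa_alignment`.
#' @export
#' @examples
#' aln <- aa_alignment(c(spA = "MKV-", spB = "MKVL", spC = "MRVL"), id = "og1")
#' aln
aa_alignment <- function(sequences, id = "orthogroup") {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    stopifnot(is.character(sequences), !is.null(names(sequences)))
    n <- nchar(sequences)
    if (length(unique(n)) > 1) {
      stop("aligned sequences must all have the same length; got lengths ",
           paste(unique(n), collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    rownames(mat) <- names(sequences)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("species identifiers must be present and unique")
  }
  mat[] <- toupper(mat)
  bad <- !(mat %in% c(AA_RESIDUES, AA_GAP_CHARS))
  if (any(bad)) {
    stop("invalid alignment character(s): ",
         paste(unique(mat[bad]), collapse = ", "))
  }
  structure(list(id = id, seq = mat), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", x$id, ": ", nrow(x$seq), " species x ",
      ncol(x$seq), " sites\n", sep = "")
  invisible(x)
}

#' Number of species / alignment length
#'
#' @param aln An `aa_alignment`.
#' @return Integer count.
#' @export
n_species <- function(aln) nrow(aln$seq)

#' @rdname n_species
#' @export
n_sites <- function(aln) ncol(aln$seq)

#' @export
as.character.aa_alignment <- function(x, ...) {
  apply(x$seq, 1, paste, collapse = "")
}

# integer codes 1..20 / NA for downstream numeric work (0-based for C++)
encode_alignment <- function(aln) {
  codes <- matrix(match(aln$seq, AA_RESIDUES), nrow = nrow(aln$seq),
                  dimnames = dimnames(aln$seq))
  codes
}

#' Read / write one orthogroup alignment as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O returning / accepting
#' [aa_alignment()] objects. The orthogroup id defaults to the file name
#' without extension.
#'
#' @param path FASTA file path.
#' @param id Orthogroup identifier (read) .
#' @return `read_orthogroup()` returns an `aa_alignment`;
#'   `write_orthogroup()` returns `path` invisibly.
#' @export
read_orthogroup <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readAAStringSet(path)
  aa_alignment(stats::setNames(as.character(ss), names(ss)), id = id)
}

#' @rdname read_orthogroup
#' @param aln An `aa_alignment` to write.
#' @export
write_orthogroup <- function(aln, path) {
  ss <- Biostrings::AAStringSet(as.character.aa_alignment(aln))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
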