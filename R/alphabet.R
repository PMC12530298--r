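# Canonical residue order shared by all matrices, frequency vectors and
# integer encodings in the package (the order used by PAML-format files).
AA_RESIDUES <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Characters treated as missing data: the gap proper, alignment padding, and
# ambiguity / non-standard codes. Treating ambiguity codes as missing is the
# conservative choice: they carry no usable state under a 20-state model.
AA_GAP_CHARS <- c("-", ".", "B", "Z", "X", "J", "U", "O", "*", "?")

#' Amino acid alphabet used throughout the package
#'
#' Returns the ordered 20-residue alphabet (standard PAML/one-letter order
#' `ARNDCQEGHILKMFPSTWYV`) and the set of characters treated as missing data
#' (gaps and ambiguity codes).
#'
#' @return A list with elements `residues` (character vector of length 20)
#'   and `gap_chars` (characters treated as missing).
#' @export
#' @examples
#' aa_alphabet()$residues
aa_alphabet <- function() {
  list(residues = AA_RESIDUES, gap_chars = AA_GAP_CHARS)
}

# Map a character vector of single residues to 1..20 integer codes,
# NA for gaps/ambiguity. Unknown characters error.
encode_residues <- function(chars) {
  chars <- toupper(chars)
  codes <- match(chars, AA_RESIDUES)
  bad <- is.na(codes) & !(chars %in% AA_GAP_CHARS)
  if (any(bad)) {
    stop("unknown residue character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  codes
}
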