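#' Residue and secondary-structure alphabets
#'
#' `aa_alphabet()` returns the ordered 21-letter residue alphabet (the 20
#' standard amino acids plus `X` for any non-standard residue).
#' `ss8_states()` returns the eight DSSP secondary-structure categories
#' (alpha-helix H, 3-10 helix G, pi-helix I, strand E, beta-bridge B, turn T,
#' bend S, other L) and `ss3_states()` their coarse three-state reduction
#' (helix H, strand E, coil C).
#'
#' @return A character vector of single letters.
#' @examples
#' aa_alphabet()
#' ss8_states()
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

#' @rdname aa_alphabet
#' @export
ss8_states <- function() c("H", "G", "I", "E", "B", "T", "S", "L")

#' @rdname aa_alphabet
#' @export
ss3_states <- function() c("H", "E", "C")

# group mapping: helices (H,G,I) -> H, strands (E,B) -> E, the rest -> C
.ss8_to_ss3_map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
                     T = "C", S = "C", L = "C")

#' Collapse 8-state secondary structure labels to 3 states
#'
#' The eight DSSP categories are grouped into helix (`H`, `G`, `I` -> `H`),
#' strand (`E`, `B` -> `E`) and coil (`T`, `S`, `L` -> `C`).
#'
#' @param ss8 Character vector of 8-state label strings.
#' @return Character vector of the same lengths over the 3-state alphabet.
#' @examples
#' map_ss8_to_ss3("HGIEBTSL")
#' @export
map_ss8_to_ss3 <- function(ss8) {
  stopifnot(is.character(ss8))
  vapply(ss8, function(s) {
    if (is.na(s)) return(NA_character_)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- .ss8_to_ss3_map[chars]
    bad <- which(is.na(out))
    if (length(bad) > 0) {
      stop(sprintf(
        "invalid 8-state label '%s' at position %d (expected one of %s)",
        chars[bad[1]], bad[1], paste(ss8_states(), collapse = "")
      ), call. = FALSE)
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize a residue sequence onto the 21-letter alphabet
#'
#' Upper-cases the sequence and replaces every letter outside the 20 standard
#' amino acids (e.g. B, J, O, U, Z) with `X`.
#'
#' @param sequence Character vector of residue strings.
#' @return Character vector over the 21-letter alphabet.
#' @export
normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence))
  std <- setdiff(aa_alphabet(), "X")
  vapply(sequence, function(s) {
    if (is.na(s)) return(NA_character_)
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    chars[!(chars %in% std)] <- "X"
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a label/sequence string into characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.validate_states <- function(s, states, what = "label") {
  chars <- .chars(s)
  bad <- which(!(chars %in% states))
  if (length(bad) > 0) {
    stop(sprintf("invalid %s character '%s' at position %d",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(chars)
}
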