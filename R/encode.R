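#' One-hot encode a residue sequence
#'
#' Encodes a sequence as an L x 21 binary matrix over the 21-letter alphabet.
#' Non-standard letters are mapped to the `X` column first.
#'
#' @param sequence A single residue string.
#' @return An L x 21 binary matrix; each row sums to 1. Columns are named by
#'   the alphabet letters.
#' @examples
#' one_hot_encode("ACDG")
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("cannot one-hot encode an empty sequence", call. = FALSE)
  }
  ab <- aa_alphabet()
  chars <- .chars(normalize_sequence(sequence))
  idx <- match(chars, ab)
  m <- matrix(0L, nrow = length(chars), ncol = length(ab),
              dimnames = list(NULL, ab))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Load the default physicochemical descriptor table
#'
#' Seven literature-scale descriptors per residue letter: sheet probability,
#' helix probability, isoelectric point, hydrophobicity, van der Waals
#' volume, polarizability and graph shape index. Shipped as a plain CSV that
#' can be replaced by any table with the same layout.
#'
#' @param path Optional path to an alternative CSV (columns `letter` plus the
#'   seven descriptors).
#' @return A tibble with a `letter` column and 7 numeric descriptor columns,
#'   covering all 21 alphabet letters.
#' @export
physchem_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physchem_default.csv", package = "psspkit")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!("letter" %in% names(tab)) || ncol(tab) != 8) {
    stop("physicochemical table must have a `letter` column plus 7 descriptors",
         call. = FALSE)
  }
  missing <- setdiff(aa_alphabet(), tab$letter)
  if (length(missing) > 0) {
    stop(sprintf("physicochemical table is missing letters: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Encode a sequence with per-residue physicochemical descriptors
#'
#' @param sequence A single residue string.
#' @param table Descriptor table as returned by [physchem_table()].
#' @return An L x 7 numeric matrix, one descriptor row per residue.
#' @export
physchem_encode <- function(sequence, table = physchem_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  chars <- .chars(normalize_sequence(sequence))
  idx <- match(chars, table$letter)
  if (anyNA(idx)) {
    stop(sprintf("physicochemical table does not cover letter '%s'",
                 chars[which(is.na(idx))[1]]), call. = FALSE)
  }
  m <- as.matrix(table[idx, setdiff(names(table), "letter")])
  rownames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Assemble a per-record feature bundle
#'
#' Collects the per-residue feature matrices used as model input: one-hot
#' (L x 21), and optionally PSSM (L x 20), HMM (L x 30), physicochemical
#' (L x 7), language-model embedding (L x D) and the autoencoder's highly
#' targeted encoding (L x 4). All matrices must share the leading dimension
#' L = sequence length.
#'
#' @param sequence Residue string.
#' @param pssm,hmm,physchem,embedding,hta_encoding Optional numeric matrices.
#' @return A list of class `feature_bundle`.
#' @export
feature_bundle <- function(sequence, pssm = NULL, hmm = NULL,
                           physchem = NULL, embedding = NULL,
                           hta_encoding = NULL) {
  one_hot <- one_hot_encode(sequence)
  L <- nrow(one_hot)
  mats <- list(one_hot = one_hot, pssm = pssm, hmm = hmm,
               physchem = physchem, embedding = embedding,
               hta_encoding = hta_encoding)
  widths <- c(one_hot = 21L, pssm = 20L, hmm = 30L, physchem = 7L,
              embedding = NA_integer_, hta_encoding = NA_integer_)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (is.null(m)) next
    if (!is.matrix(m) || nrow(m) != L) {
      stop(sprintf("feature '%s' must be a matrix with %d rows", nm, L),
           call. = FALSE)
    }
    if (!is.na(widths[[nm]]) && ncol(m) != widths[[nm]]) {
      stop(sprintf("feature '%s' must have %d columns, got %d",
                   nm, widths[[nm]], ncol(m)), call. = FALSE)
    }
  }
  structure(c(mats, list(length = L)), class = "feature_bundle")
}
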