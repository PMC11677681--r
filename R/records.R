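#' Build a protein record corpus
#'
#' A corpus is a tibble with one row per protein chain and columns
#' `id` (character), `sequence` (residue string over the 21-letter alphabet),
#' `ss8` (optional 8-state label string, `NA` when absent) and `rsa`
#' (list-column of per-residue relative solvent accessibility fractions in
#' \[0, 1\], `NULL` when absent). All per-residue tracks must match the
#' sequence length exactly.
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of residue strings; normalized onto the
#'   21-letter alphabet (non-standard letters become `X`).
#' @param ss8 Optional character vector of 8-state label strings.
#' @param rsa Optional list of numeric vectors of per-residue RSA fractions.
#' @return A tibble of class `pssp_corpus`.
#' @examples
#' protein_records("p1", "ACDG", ss8 = "HHLL")
#' @export
protein_records <- function(id, sequence, ss8 = NULL, rsa = NULL) {
  stopifnot(is.character(id), is.character(sequence),
            length(id) == length(sequence))
  n <- length(id)
  sequence <- normalize_sequence(sequence)
  if (any(!nzchar(sequence) | is.na(sequence))) {
    stop("every record needs a non-empty sequence", call. = FALSE)
  }
  if (is.null(ss8)) ss8 <- rep(NA_character_, n)
  if (is.null(rsa)) rsa <- vector("list", n)
  if (!is.list(rsa)) rsa <- list(rsa)
  stopifnot(length(ss8) == n, length(rsa) == n)
  L <- nchar(sequence)
  for (i in seq_len(n)) {
    if (!is.na(ss8[i])) {
      if (nchar(ss8[i]) != L[i]) {
        stop(sprintf(
          "record '%s': ss8 length %d does not match sequence length %d",
          id[i], nchar(ss8[i]), L[i]), call. = FALSE)
      }
      .validate_states(ss8[i], ss8_states(), "ss8")
    }
    if (!is.null(rsa[[i]])) {
      if (length(rsa[[i]]) != L[i]) {
        stop(sprintf(
          "record '%s': rsa length %d does not match sequence length %d",
          id[i], length(rsa[[i]]), L[i]), call. = FALSE)
      }
      if (any(rsa[[i]] < 0 | rsa[[i]] > 1, na.rm = TRUE)) {
        stop(sprintf("record '%s': rsa values must lie in [0, 1]", id[i]),
             call. = FALSE)
      }
    }
  }
  out <- tibble::tibble(id = id, sequence = sequence, ss8 = ss8, rsa = rsa)
  class(out) <- c("pssp_corpus", class(out))
  out
}

#' @export
print.pssp_corpus <- function(x, ...) {
  cat(sprintf("# A protein corpus: %d record(s), %d residues total\n",
              nrow(x), sum(nchar(x$sequence))))
  NextMethod()
}

.assert_corpus <- function(records) {
  need <- c("id", "sequence")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("expected a corpus data frame with at least `id` and `sequence` columns",
         call. = FALSE)
  }
  invisible(records)
}

.assert_ss8 <- function(records) {
  .assert_corpus(records)
  if (!("ss8" %in% names(records)) || any(is.na(records$ss8))) {
    stop("all records must carry 8-state `ss8` labels for this operation",
         call. = FALSE)
  }
  invisible(records)
}
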