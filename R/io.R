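#' Read protein sequences from a FASTA file
#'
#' Identifiers are taken from the header up to the first whitespace;
#' sequences are upper-cased and letters outside the 20 standard amino acids
#' are replaced by `X`.
#'
#' @param path Path to a FASTA file.
#' @return A corpus tibble (see [protein_records()]) without label tracks.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("failed to parse FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(set) == 0) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  protein_records(id = ids, sequence = as.character(set))
}

#' Read a tabular per-residue label file
#'
#' Plain-text layout, one record per line:
#' `id  sequence  ss8  [rsa_1 rsa_2 ... rsa_L]`, whitespace-separated, with
#' the RSA fractions optional. Track lengths must agree with the sequence.
#'
#' @param path Path to the label file.
#' @return A corpus tibble with `ss8` and (where present) `rsa` tracks.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop(sprintf("empty label file: %s", path), call. = FALSE)
  parsed <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3) {
      stop(sprintf("label file line %d: expected at least id, sequence and ss8",
                   i), call. = FALSE)
    }
    rsa <- NULL
    if (length(f) > 3) {
      rsa <- suppressWarnings(as.numeric(f[-(1:3)]))
      if (anyNA(rsa)) {
        stop(sprintf("label file line %d (record '%s'): non-numeric RSA value",
                     i, f[1]), call. = FALSE)
      }
    }
    list(id = f[1], sequence = f[2], ss8 = f[3], rsa = rsa)
  })
  protein_records(
    id = vapply(parsed, `[[`, character(1), "id"),
    sequence = vapply(parsed, `[[`, character(1), "sequence"),
    ss8 = vapply(parsed, `[[`, character(1), "ss8"),
    rsa = lapply(parsed, `[[`, "rsa")
  )
}

#' Write a corpus as FASTA plus a tabular label file
#'
#' Emits `<stem>.fasta` and, when 8-state labels are present,
#' `<stem>.labels` in the layout read back by [read_labels()].
#'
#' @param records Corpus tibble.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, default `"corpus"`.
#' @return Invisibly, the paths written.
#' @export
write_corpus <- function(records, dir, stem = "corpus") {
  .assert_corpus(records)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(stem, ".fasta"))
  writeLines(paste0(">", records$id, "\n", records$sequence), fasta)
  paths <- fasta
  if ("ss8" %in% names(records) && !all(is.na(records$ss8))) {
    labels <- file.path(dir, paste0(stem, ".labels"))
    rows <- vapply(seq_len(nrow(records)), function(i) {
      base <- paste(records$id[i], records$sequence[i], records$ss8[i])
      r <- records$rsa[[i]]
      if (!is.null(r)) base <- paste(base, paste(sprintf("%.6f", r), collapse = " "))
      base
    }, character(1))
    writeLines(rows, labels)
    paths <- c(paths, labels)
  }
  invisible(paths)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard `psiblast -out_ascii_pssm` layout and returns the 20
#' log-odds columns (in PSI-BLAST column order) as an L x 20 matrix.
#'
#' @param path Path to the ASCII PSSM file.
#' @param squash If `TRUE`, apply the logistic squashing
#'   `1 / (1 + exp(-x))` to every value (scores are returned raw by default).
#' @return An L x 20 numeric matrix with the residue letters as row names.
#' @export
read_pssm <- function(path, squash = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  # data rows start with an integer position followed by a residue letter
  is_row <- grepl("^\\s*\\d+\\s+[A-Za-z]\\s+-?\\d", lines)
  if (!any(is_row)) {
    stop(sprintf("no PSSM data rows found in '%s'", path), call. = FALSE)
  }
  rows <- which(is_row)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = 20)
  letters_col <- character(length(rows))
  for (k in seq_along(rows)) {
    f <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    if (length(f) < 22) {
      stop(sprintf("PSSM line %d: expected 20 log-odds columns, found %d fields",
                   rows[k], length(f)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(v)) {
      stop(sprintf("PSSM line %d: non-numeric log-odds value", rows[k]),
           call. = FALSE)
    }
    vals[k, ] <- v
    letters_col[k] <- f[2]
  }
  if (squash) vals <- 1 / (1 + exp(-vals))
  rownames(vals) <- letters_col
  vals
}

#' Read an HH-suite .hhm profile
#'
#' Parses the HMM block of an HH-suite `.hhm` file: per residue, 20 match
#' emission values followed by 10 transition/diversity values (30 columns).
#' The dialect stores probabilities as `-1000 * log2(p)` with `*` marking
#' zero-probability entries.
#'
#' @param path Path to the `.hhm` file.
#' @param dequantize If `TRUE`, map stored values `x` to probabilities
#'   `2^(-x / 1000)`; `*` entries become 0. If `FALSE` (default), raw stored
#'   values are returned and `*` entries take `star_value`.
#' @param star_value Sentinel used for `*` entries when `dequantize = FALSE`
#'   (default 0).
#' @return An L x 30 numeric matrix (20 emissions, then 10 transitions).
#' @export
read_hhm <- function(path, dequantize = FALSE, star_value = 0) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  start <- grep("^HMM\\b", lines)
  if (length(start) == 0) {
    stop(sprintf("'%s' does not look like an HH-suite .hhm file (no HMM block)",
                 path), call. = FALSE)
  }
  end <- grep("^//", lines)
  if (length(end) == 0) {
    stop(sprintf("'%s': missing terminating '//' record", path), call. = FALSE)
  }
  body <- lines[(start[1] + 3):(end[1] - 1)]  # skip the two HMM header rows + NULL-ish row
  body <- body[nzchar(trimws(body))]
  # residue groups come in pairs: emission line (letter pos 20 values ...)
  # then transition line (10 values)
  em_idx <- grep("^[A-Z-]\\s+\\d+\\s", body)
  if (length(em_idx) == 0) {
    stop(sprintf("'%s': no residue rows found in HMM block", path), call. = FALSE)
  }
  decode <- function(tok) {
    x <- ifelse(tok == "*", NA, suppressWarnings(as.numeric(tok)))
    if (dequantize) {
      out <- 2^(-x / 1000)
      out[is.na(x) & tok == "*"] <- 0
      out
    } else {
      x[tok == "*"] <- star_value
      x
    }
  }
  L <- length(em_idx)
  m <- matrix(NA_real_, nrow = L, ncol = 30)
  for (k in seq_len(L)) {
    f <- strsplit(trimws(body[em_idx[k]]), "\\s+")[[1]]
    if (length(f) < 22) {
      stop(sprintf("'%s': emission row %d has %d fields, expected >= 22",
                   path, k, length(f)), call. = FALSE)
    }
    em <- decode(f[3:22])
    tr_line <- body[em_idx[k] + 1]
    g <- strsplit(trimws(tr_line), "\\s+")[[1]]
    if (length(g) < 10) {
      stop(sprintf("'%s': transition row %d has %d fields, expected 10",
                   path, k, length(g)), call. = FALSE)
    }
    tr <- decode(g[1:10])
    m[k, ] <- c(em, tr)
  }
  if (anyNA(m)) m[is.na(m)] <- if (dequantize) 0 else star_value
  m
}

#' Read or write a plain-text numeric matrix
#'
#' Whitespace-separated values, one matrix row per line; used for embedding
#' features and exported encodings.
#'
#' @param path File path.
#' @param m Numeric matrix to write.
#' @return `read_matrix()` returns a numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 15, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
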