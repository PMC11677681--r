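#' Load the default maximum-ASA table
#'
#' Per-residue maximum accessible surface area (in square Angstrom) used to
#' normalize ASA into relative solvent accessibility; a literature
#' theoretical scale shipped as plain CSV, replaceable by any table with a
#' `letter` and a `max_asa` column.
#'
#' @param path Optional path to an alternative CSV.
#' @return A tibble with columns `letter` and `max_asa`.
#' @export
max_asa_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_asa_default.csv", package = "psspkit")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("letter", "max_asa") %in% names(tab))) {
    stop("max-ASA table needs `letter` and `max_asa` columns", call. = FALSE)
  }
  if (any(tab$max_asa <= 0)) {
    stop("max-ASA values must be strictly positive", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Relative solvent accessibility from absolute surface area
#'
#' `rsa_i = asa_i / max_asa(residue_i)`, clipped into \[0, 1\].
#'
#' @param asa Numeric vector of per-residue accessible surface areas (>= 0).
#' @param sequence Residue string of the same length.
#' @param table Maximum-ASA table, see [max_asa_table()].
#' @return Numeric vector of RSA fractions in \[0, 1\].
#' @export
rsa_from_asa <- function(asa, sequence, table = max_asa_table()) {
  chars <- .chars(normalize_sequence(sequence))
  stopifnot(length(asa) == length(chars))
  if (any(asa < 0, na.rm = TRUE)) stop("ASA values must be >= 0", call. = FALSE)
  mx <- table$max_asa[match(chars, table$letter)]
  if (anyNA(mx)) {
    stop(sprintf("max-ASA table does not cover letter '%s'",
                 chars[which(is.na(mx))[1]]), call. = FALSE)
  }
  pmin(pmax(asa / mx, 0), 1)
}

#' Binarize RSA into buried/exposed
#'
#' Residues with RSA less than or equal to the threshold are `"buried"`,
#' the rest `"exposed"` (the threshold itself is inclusive on the buried
#' side).
#'
#' @param rsa Numeric vector of RSA fractions in \[0, 1\].
#' @param threshold Buried/exposed cut point, default 0.15.
#' @return Factor with levels `buried`, `exposed`.
#' @export
rsa_binarize <- function(rsa, threshold = 0.15) {
  if (any(rsa < 0 | rsa > 1, na.rm = TRUE)) {
    stop("RSA fractions must lie in [0, 1]", call. = FALSE)
  }
  factor(ifelse(rsa <= threshold, "buried", "exposed"),
         levels = c("buried", "exposed"))
}

#' Contingency table of secondary structure against buried/exposed RSA
#'
#' Tallies every residue of a corpus into a 2 x 8 table (RSA bin by 8-state
#' category). Margins are always recomputed from the cells.
#'
#' @param records Corpus tibble whose records carry both `ss8` and `rsa`.
#' @param threshold Buried/exposed RSA cut point, default 0.15.
#' @return An integer matrix with rows `buried`/`exposed` and one column per
#'   8-state category, of class `pssp_contingency`.
#' @export
contingency_table <- function(records, threshold = 0.15) {
  .assert_ss8(records)
  if (any(vapply(records$rsa, is.null, logical(1)))) {
    stop("all records must carry per-residue RSA for the contingency table",
         call. = FALSE)
  }
  ss <- unlist(lapply(records$ss8, .chars))
  rsa <- unlist(records$rsa)
  bin <- rsa_binarize(rsa, threshold)
  tab <- table(bin, factor(ss, levels = ss8_states()))
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(rsa_bin = c("buried", "exposed"),
                              ss8 = ss8_states()))
  structure(m, class = c("pssp_contingency", "matrix", "array"))
}

#' Cramer's V association coefficient of a contingency table
#'
#' Expected counts are `E_ij = sum_i * sum_j / sum` and
#' `V = sqrt( sum_ij (O_ij - E_ij)^2 / E_ij / (sum * min(m - 1, n - 1)) )`,
#' with margins recomputed from the cells. Rows or columns whose margin is
#' zero (categories absent from the data) are dropped from the chi-square
#' sum with a warning.
#'
#' @param table A count matrix (m x n, counts >= 0).
#' @return The coefficient, a number in \[0, 1\].
#' @export
cramers_v <- function(table) {
  O <- unclass(as.matrix(table))
  storage.mode(O) <- "double"
  if (any(O < 0)) stop("contingency counts must be >= 0", call. = FALSE)
  rz <- rowSums(O) > 0
  cz <- colSums(O) > 0
  if (!all(rz) || !all(cz)) {
    warning(sprintf("dropping %d zero-margin row(s)/column(s) before Cramer's V",
                    sum(!rz) + sum(!cz)), call. = FALSE)
    O <- O[rz, cz, drop = FALSE]
  }
  if (min(dim(O)) < 2) {
    stop("Cramer's V needs at least 2 non-empty rows and columns", call. = FALSE)
  }
  n <- sum(O)
  if (n <= 0) stop("contingency table is empty", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / n
  chisq <- sum((O - E)^2 / E)
  sqrt(chisq / (n * (min(dim(O)) - 1)))
}

#' Published secondary-structure / RSA reference tally
#'
#' A large published tally (about 6.03 million residues from a
#' non-redundant, PDB-derived corpus) of 8-state secondary structure against
#' buried/exposed RSA at threshold 0.15, shipped with the package so the
#' association analysis can be reproduced without external data.
#'
#' @return A list with `counts` (2 x 8 integer matrix of class
#'   `pssp_contingency`) and `printed_margins` (the totals as published:
#'   `row`, `col`, `grand`), against which recomputed margins can be
#'   checked.
#' @export
ss_rsa_reference <- function() {
  path <- system.file("extdata", "ss_rsa_reference_counts.csv",
                      package = "psspkit")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  cells <- as.matrix(tab[tab$rsa_bin != "printed_sum", ss8_states()])
  rownames(cells) <- c("buried", "exposed")
  storage.mode(cells) <- "integer"
  printed_row <- tab$printed_sum[tab$rsa_bin != "printed_sum"]
  printed_col <- as.integer(tab[tab$rsa_bin == "printed_sum", ss8_states()])
  names(printed_col) <- ss8_states()
  list(
    counts = structure(cells, class = c("pssp_contingency", "matrix", "array")),
    printed_margins = list(
      row = stats::setNames(printed_row, c("buried", "exposed")),
      col = printed_col,
      grand = tab$printed_sum[tab$rsa_bin == "printed_sum"]
    )
  )
}

#' Association analysis between secondary structure and RSA
#'
#' Wraps [contingency_table()] and [cramers_v()] into a single analysis
#' object carrying observed counts, margins, expected counts and the
#' association coefficient.
#'
#' @param x A corpus tibble with `ss8` and `rsa` tracks, or a prebuilt count
#'   matrix.
#' @param threshold Buried/exposed RSA cut point (ignored for a matrix).
#' @return An object of class `pssp_association` with `counts`, `expected`,
#'   `margins` and `v`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
ss_rsa_association <- function(x, threshold = 0.15) {
  counts <- if (is.matrix(x)) x else contingency_table(x, threshold)
  O <- unclass(as.matrix(counts)); storage.mode(O) <- "double"
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  structure(list(
    counts = counts,
    expected = E,
    margins = list(row = rowSums(O), col = colSums(O), grand = n),
    v = cramers_v(counts),
    threshold = if (is.matrix(x)) NA_real_ else threshold
  ), class = "pssp_association")
}

#' @export
print.pssp_association <- function(x, ...) {
  cat(sprintf(
    "Secondary structure / RSA association: Cramer's V = %.4f (n = %s residues)\n",
    x$v, format(x$margins$grand, big.mark = ",")))
  print(unclass(x$counts))
  invisible(x)
}

#' Histogram of secondary-structure segment lengths
#'
#' Lengths of all maximal single-category segments in a corpus, binned into
#' intervals.
#'
#' @param records Corpus tibble with `ss8` labels (or a character vector of
#'   label strings).
#' @param bin_edges Right-closed interval edges; the last interval is
#'   open-ended. Default: unit bins 1..11, then 12+.
#' @return A tibble with columns `bin`, `lower`, `upper` and `count`, of
#'   class `pssp_seglen_histogram`; total count equals the number of
#'   segments.
#' @export
segment_length_histogram <- function(records, bin_edges = c(1:11)) {
  labels <- if (is.data.frame(records)) .assert_ss8(records)$ss8 else records
  lens <- unlist(lapply(labels, function(s) extract_segments(s)$length))
  if (length(lens) == 0) {
    return(structure(tibble::tibble(bin = character(), lower = numeric(),
                                    upper = numeric(), count = integer()),
                     class = c("pssp_seglen_histogram", "tbl_df", "tbl",
                               "data.frame")))
  }
  edges <- sort(unique(bin_edges))
  lower <- c(min(1, edges[1]), edges + 1)
  upper <- c(edges, Inf)
  count <- vapply(seq_along(lower), function(i) {
    sum(lens >= lower[i] & lens <= upper[i])
  }, integer(1))
  out <- tibble::tibble(
    bin = ifelse(is.finite(upper),
                 ifelse(lower == upper, as.character(lower),
                        paste0(lower, "-", upper)),
                 paste0(lower, "+")),
    lower = lower, upper = upper, count = count
  )
  class(out) <- c("pssp_seglen_histogram", class(out))
  out
}
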