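#' Decompose a label string into maximal single-category segments
#'
#' @param labels A secondary-structure label string.
#' @return A tibble with columns `category`, `start`, `end` (1-based,
#'   inclusive) and `length`, in sequence order. Segments tile the sequence:
#'   adjacent segments differ in category and lengths sum to `nchar(labels)`.
#' @examples
#' extract_segments("HHHEE")
#' @export
extract_segments <- function(labels) {
  stopifnot(is.character(labels), length(labels) == 1)
  if (is.na(labels) || !nzchar(labels)) {
    stop("cannot extract segments from an empty label string", call. = FALSE)
  }
  r <- rle(.chars(labels))
  end <- cumsum(r$lengths)
  tibble::tibble(
    category = r$values,
    start = end - r$lengths + 1L,
    end = end,
    length = r$lengths
  )
}

.check_pair <- function(pred, obs) {
  stopifnot(is.character(pred), is.character(obs),
            length(pred) == 1, length(obs) == 1)
  if (!nzchar(obs) || !nzchar(pred)) {
    stop("labelings must be non-empty", call. = FALSE)
  }
  if (nchar(pred) != nchar(obs)) {
    stop(sprintf("length mismatch: predicted %d vs observed %d residues",
                 nchar(pred), nchar(obs)), call. = FALSE)
  }
  invisible(NULL)
}

#' Per-residue Q accuracy
#'
#' The fraction of residues whose predicted category matches the observed
#' one, times 100 (Q3 over the 3-state alphabet, Q8 over the 8-state one).
#' Vectors of strings are pooled: the numerator and denominator are summed
#' over all sequences, not averaged per sequence.
#'
#' @param pred,obs Character vectors of equal-length label strings.
#' @param states Category alphabet both strings must be drawn from.
#' @return A percentage in \[0, 100\].
#' @examples
#' q_accuracy("HHEC", "HHEE", states = ss3_states())
#' @export
q_accuracy <- function(pred, obs, states = ss8_states()) {
  stopifnot(length(pred) == length(obs), length(pred) >= 1)
  correct <- 0L; total <- 0L
  for (i in seq_along(pred)) {
    .check_pair(pred[i], obs[i])
    p <- .validate_states(pred[i], states, "predicted label")
    o <- .validate_states(obs[i], states, "observed label")
    correct <- correct + sum(p == o)
    total <- total + length(o)
  }
  100 * correct / total
}

# SOV numerator and normalizer for one sequence pair (Zemla-style
# segment-overlap definition). Returned separately so that multi-sequence
# scores pool sums rather than average per-sequence values. Works on plain
# run-length vectors; the tibble interface lives in extract_segments().
.sov_components <- function(pred, obs, states) {
  .check_pair(pred, obs)
  .validate_states(pred, states, "predicted label")
  .validate_states(obs, states, "observed label")
  ro <- rle(.chars(obs)); rp <- rle(.chars(pred))
  o_end <- cumsum(ro$lengths); o_start <- o_end - ro$lengths + 1L
  p_end <- cumsum(rp$lengths); p_start <- p_end - rp$lengths + 1L
  num <- 0
  N <- 0
  for (cat in states) {
    oi <- which(ro$values == cat)
    pi <- which(rp$values == cat)
    if (length(oi) == 0) next
    if (length(pi) == 0) {
      N <- N + sum(ro$lengths[oi])
      next
    }
    for (a in oi) {
      l1 <- ro$lengths[a]
      overlapped <- FALSE
      for (b in pi) {
        minov <- min(o_end[a], p_end[b]) - max(o_start[a], p_start[b]) + 1L
        if (minov <= 0L) next
        overlapped <- TRUE
        l2 <- rp$lengths[b]
        maxov <- max(o_end[a], p_end[b]) - min(o_start[a], p_start[b]) + 1L
        delta <- min(maxov - minov, minov, l1 %/% 2L, l2 %/% 2L)
        num <- num + (minov + delta) / maxov * l1
        N <- N + l1
      }
      if (!overlapped) N <- N + l1
    }
  }
  list(num = num, N = N)
}

#' Segment overlap score (SOV)
#'
#' Segment-level agreement between predicted and observed secondary
#' structure. For each category, every observed segment is compared with the
#' overlapping predicted segments of the same category; each pair contributes
#' `(minov + delta) / maxov * l(s1)` where `minov` is the overlap length,
#' `maxov` the extent of the union, `l(s1)` the observed segment length and
#' `delta = min(maxov - minov, minov, floor(l(s1)/2), floor(l(s2)/2))` an
#' allowance for boundary imprecision. The normalizer sums observed-segment
#' lengths over overlapping pairs plus the lengths of observed segments with
#' no same-category overlap. Vectors of strings are pooled by summing the
#' numerator and normalizer over sequences.
#'
#' @inheritParams q_accuracy
#' @return A percentage in \[0, 100\].
#' @examples
#' sov("HHHEEEEE", "HHHHEEEE")
#' @export
sov <- function(pred, obs, states = ss8_states()) {
  stopifnot(length(pred) == length(obs), length(pred) >= 1)
  num <- 0; N <- 0
  for (i in seq_along(pred)) {
    comp <- .sov_components(pred[i], obs[i], states)
    num <- num + comp$num
    N <- N + comp$N
  }
  if (N == 0) {
    stop("SOV is undefined: no observed segments in the given state set",
         call. = FALSE)
  }
  100 * num / N
}

#' Confusion matrix of observed versus predicted categories
#'
#' @inheritParams q_accuracy
#' @param normalized If `TRUE`, divide each row (observed category) by its
#'   sum; rows with no observations stay all-zero.
#' @return A square matrix indexed observed x predicted over `states`, of
#'   class `pssp_confusion`.
#' @export
confusion_matrix <- function(pred, obs, states = ss8_states(),
                             normalized = FALSE) {
  stopifnot(length(pred) == length(obs), length(pred) >= 1)
  m <- matrix(0, nrow = length(states), ncol = length(states),
              dimnames = list(observed = states, predicted = states))
  for (i in seq_along(pred)) {
    .check_pair(pred[i], obs[i])
    p <- factor(.validate_states(pred[i], states, "predicted label"),
                levels = states)
    o <- factor(.validate_states(obs[i], states, "observed label"),
                levels = states)
    m <- m + unclass(table(o, p))
  }
  if (normalized) {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  structure(m, class = c("pssp_confusion", "matrix", "array"))
}

#' Mark boundary residues of a labeling
#'
#' A residue is a boundary residue when it is (type 1) the first or last of
#' the sequence; (type 2) an interior residue whose two flanking residues
#' carry different categories; or (type 3) an interior residue whose flanks
#' agree with each other but differ from the residue itself.
#'
#' @param labels A secondary-structure label string.
#' @return A tibble with columns `position`, `label`, `boundary` (logical)
#'   and `type` (integer 1, 2 or 3; `NA` for non-boundary residues). When a
#'   residue satisfies several types the smallest type number is recorded.
#' @examples
#' boundary_mask("HEH")
#' @export
boundary_mask <- function(labels) {
  stopifnot(is.character(labels), length(labels) == 1, nzchar(labels))
  chars <- .chars(labels)
  L <- length(chars)
  type <- rep(NA_integer_, L)
  if (L >= 3) {
    for (i in 2:(L - 1)) {
      if (chars[i - 1] != chars[i + 1]) {
        type[i] <- 2L
      } else if (chars[i] != chars[i - 1]) {
        type[i] <- 3L
      }
    }
  }
  type[1] <- 1L
  type[L] <- 1L
  tibble::tibble(position = seq_len(L), label = chars,
                 boundary = !is.na(type), type = type)
}

#' Q accuracy restricted to boundary residues
#'
#' [q_accuracy()] computed only over the residues marked by
#' [boundary_mask()] applied to the observed labeling; sequences are pooled.
#'
#' @inheritParams q_accuracy
#' @return A percentage in \[0, 100\].
#' @export
boundary_accuracy <- function(pred, obs, states = ss8_states()) {
  stopifnot(length(pred) == length(obs), length(pred) >= 1)
  correct <- 0L; total <- 0L
  for (i in seq_along(pred)) {
    .check_pair(pred[i], obs[i])
    p <- .validate_states(pred[i], states, "predicted label")
    o <- .validate_states(obs[i], states, "observed label")
    mask <- boundary_mask(obs[i])$boundary
    correct <- correct + sum((p == o)[mask])
    total <- total + sum(mask)
  }
  if (total == 0) stop("no boundary residues to score", call. = FALSE)
  100 * correct / total
}

#' Evaluate predicted against observed secondary structure
#'
#' Pools Q accuracy, SOV, boundary accuracy, per-category recall and the
#' confusion matrix over a set of sequences. With 8-state inputs, the
#' 3-state metrics obtained through [map_ss8_to_ss3()] are reported as well.
#'
#' @param pred,obs Character vectors of label strings (equal lengths
#'   pairwise), or corpus tibbles carrying `ss8`.
#' @param states `"ss8"` or `"ss3"`: the alphabet of the inputs.
#' @return An object of class `pssp_evaluation` with elements `summary`
#'   (tibble of metric/value rows), `per_category` (tibble of per-category
#'   recall) and `confusion` (normalized confusion matrix). Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
evaluate_predictions <- function(pred, obs, states = c("ss8", "ss3")) {
  states <- match.arg(states)
  if (is.data.frame(pred)) pred <- .assert_ss8(pred)$ss8
  if (is.data.frame(obs)) obs <- .assert_ss8(obs)$ss8
  st <- if (states == "ss8") ss8_states() else ss3_states()
  q <- q_accuracy(pred, obs, st)
  s <- sov(pred, obs, st)
  b <- boundary_accuracy(pred, obs, st)
  conf <- confusion_matrix(pred, obs, st)
  recall <- ifelse(rowSums(conf) > 0, diag(conf) / rowSums(conf) * 100, NA_real_)
  summary <- tibble::tibble(
    metric = paste0(c("Q", "SOV", "boundary_Q"), nchar(paste(st, collapse = ""))),
    value = c(q, s, b)
  )
  per_category <- tibble::tibble(category = st, recall = unname(recall),
                                 n = unname(rowSums(conf)))
  out <- list(summary = summary, per_category = per_category,
              confusion = confusion_matrix(pred, obs, st, normalized = TRUE),
              counts = conf)
  if (states == "ss8") {
    e3 <- evaluate_predictions(map_ss8_to_ss3(pred), map_ss8_to_ss3(obs),
                               states = "ss3")
    out$summary <- dplyr::bind_rows(out$summary, e3$summary)
    out$ss3 <- e3
  }
  class(out) <- "pssp_evaluation"
  out
}

#' @export
print.pssp_evaluation <- function(x, ...) {
  cat("Secondary-structure evaluation (pooled over sequences)\n")
  df <- as.data.frame(x$summary)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s %6.2f\n", df$metric[i], df$value[i]))
  }
  invisible(x)
}
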