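test_that("segment extraction returns maximal runs tiling the sequence", {
  s <- extract_segments("HHHEE")
  expect_equal(s$category, c("H", "E"))
  expect_equal(s$start, c(1L, 4L))
  expect_equal(s$end, c(3L, 5L))
  expect_equal(s$length, c(3L, 2L))
  expect_equal(nrow(extract_segments("H")), 1L)
  expect_equal(extract_segments("HEHE")$length, rep(1L, 4))
  set.seed(7)
  for (i in 1:25) {
    lab <- random_labels(sample(1:40, 1), ss8_states())
    segs <- extract_segments(lab)
    expect_equal(sum(segs$length), nchar(lab))
    expect_true(all(segs$length >= 1))
    if (nrow(segs) > 1) {
      expect_true(all(segs$category[-1] != segs$category[-nrow(segs)]))
      expect_equal(segs$start[-1], segs$end[-nrow(segs)] + 1L)
    }
  }
})

test_that("Q accuracy counts correct residues, pooled over sequences", {
  expect_equal(q_accuracy("HHEE", "HHEE"), 100)
  expect_equal(q_accuracy("HHEC", "HHEE", states = ss3_states()), 75)
  expect_equal(q_accuracy("EEEE", "HHHH"), 0)
  # pooling: counts, not per-sequence averages
  expect_equal(q_accuracy(c("H", "EEEE"), c("H", "HHHH")), 100 * 1 / 5)
  expect_error(q_accuracy("HH", "H"), "length mismatch")
})

test_that("SOV matches hand cases and its defining identities", {
  expect_equal(sov("HHHH", "HHHH"), 100)
  expect_equal(sov("EEEE", "HHHH"), 0)
  # worked case: obs HHHHEEEE vs pred HHHEEEEE
  expect_equal(sov("HHHEEEEE", "HHHHEEEE"),
               oracle_sov("HHHEEEEE", "HHHHEEEE", ss8_states()))
  set.seed(11)
  for (i in 1:100) {
    x <- random_labels(sample(1:30, 1), ss8_states())
    expect_equal(sov(x, x), 100)
    expect_equal(q_accuracy(x, x), 100)
  }
})

test_that("SOV equals the brute-force oracle on exhaustive short pairs", {
  states <- c("H", "E")
  for (L in 1:6) {
    grid <- do.call(expand.grid, rep(list(states), L))
    strs <- apply(grid, 1, paste, collapse = "")
    for (obs in strs) {
      for (pred in strs) {
        expect_equal(sov(pred, obs, states), oracle_sov(pred, obs, states),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("SOV and Q are invariant under relabeling categories", {
  set.seed(13)
  perm <- sample(ss8_states())
  relabel <- function(s) {
    chartr(paste(ss8_states(), collapse = ""), paste(perm, collapse = ""), s)
  }
  for (i in 1:20) {
    obs <- random_labels(30, ss8_states())
    pred <- random_labels(30, ss8_states())
    expect_equal(sov(pred, obs), sov(relabel(pred), relabel(obs)))
    expect_equal(q_accuracy(pred, obs), q_accuracy(relabel(pred), relabel(obs)))
  }
})

test_that("3-state accuracy is never below 8-state accuracy", {
  set.seed(17)
  for (i in 1:200) {
    L <- sample(1:50, 1)
    obs <- random_labels(L, ss8_states())
    pred <- random_labels(L, ss8_states())
    q8 <- q_accuracy(pred, obs, ss8_states())
    q3 <- q_accuracy(map_ss8_to_ss3(pred), map_ss8_to_ss3(obs), ss3_states())
    expect_gte(q3, q8)
  }
})

test_that("confusion matrices conserve counts and normalize by row", {
  m <- confusion_matrix("HE", "EH", states = ss3_states())
  expect_equal(sum(m), 2)
  expect_equal(sum(diag(m)), 0)
  mp <- confusion_matrix("HHEE", "HHEE", states = ss3_states(),
                         normalized = TRUE)
  expect_equal(diag(mp), c(H = 1, E = 1, C = 0))
  set.seed(19)
  obs <- random_labels(60, ss8_states())
  pred <- random_labels(60, ss8_states())
  expect_equal(sum(confusion_matrix(pred, obs)), 60)
  mn <- confusion_matrix(pred, obs, normalized = TRUE)
  rs <- rowSums(mn)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})

test_that("boundary residues follow the three type rules", {
  m <- boundary_mask("HHHHH")
  expect_equal(sum(m$boundary), 2L)              # both ends only
  expect_equal(m$type[c(1, 5)], c(1L, 1L))
  expect_equal(sum(boundary_mask("H")$boundary), 1L)
  m3 <- boundary_mask("HEH")
  expect_true(all(m3$boundary))                  # ends + type-3 middle
  expect_equal(m3$type, c(1L, 3L, 1L))
  # type 2: flanks differ
  m4 <- boundary_mask("HHEL")
  expect_equal(m4$type, c(1L, 2L, 2L, 1L))
  # exactly two type-1 marks for every length >= 2
  set.seed(23)
  for (i in 1:20) {
    lab <- random_labels(sample(2:30, 1), ss8_states())
    expect_equal(sum(boundary_mask(lab)$type == 1, na.rm = TRUE), 2L)
  }
})

test_that("boundary accuracy scores only the masked positions", {
  expect_equal(boundary_accuracy("HHHHH", "HHHHH"), 100)
  # perfect on boundary residues, wrong in the interior
  expect_equal(boundary_accuracy("HEEEH", "HHHHH"), 100)
  # ten-residue hand case: obs HHHLLLEEEH
  obs <- "HHHLLLEEEH"
  bm <- boundary_mask(obs)
  pred <- "HHHLLLEEEE"   # wrong at final position (a boundary residue)
  marked <- which(bm$boundary)
  hand <- 100 * sum(strsplit(pred, "")[[1]][marked] ==
                      strsplit(obs, "")[[1]][marked]) / length(marked)
  expect_equal(boundary_accuracy(pred, obs), hand)
})

test_that("evaluation reports pool metrics and include the 3-state view", {
  rec <- tiny_corpus(8)
  ev <- evaluate_predictions(rec$ss8, rec$ss8)
  expect_equal(ev$summary$value[ev$summary$metric == "Q8"], 100)
  expect_equal(ev$summary$value[ev$summary$metric == "SOV8"], 100)
  expect_true(all(c("Q3", "SOV3") %in% ev$summary$metric))
  expect_equal(sum(ev$counts), sum(nchar(rec$ss8)))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  gl <- glance(ev)
  expect_equal(gl$Q8, 100)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})
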