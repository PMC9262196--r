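t0 <- as.POSIXct("2020-07-01 00:00:00", tz = "UTC")

test_that("tracker config validates thresholds", {
  cfg <- tracker_config()
  expect_equal(cfg$k_link, 0.5)
  expect_equal(cfg$k_merge, 0.25)
  expect_equal(cfg$max_gap_h, 12)
  expect_equal(cfg$min_vertices, 4)
  expect_error(tracker_config(k_link = 0.2, k_merge = 0.5), "k_merge")
  expect_error(tracker_config(max_gap_h = 0), "max_gap")
})

test_that("pass 1 links by thresholded argmax", {
  # one instance per frame, M = 0.7: single edge
  fr <- frames_fixture(list(cbind(id = 1, x = 10, y = 10),
                            cbind(id = 1, x = 12, y = 10)))
  sc <- matrix(0.7, 1, 1)
  g <- link_contiguous(fr, lookup_scorer(sc))
  expect_equal(nrow(g$edges), 1)
  # best candidate below threshold: no edge
  g <- link_contiguous(fr, lookup_scorer(matrix(0.4, 1, 1)))
  expect_equal(nrow(g$edges), 0)
  # two candidates 0.6 and 0.9: edge goes to the argmax
  fr <- frames_fixture(list(cbind(id = 1, x = 10, y = 10),
                            rbind(c(id = 1, x = 12, y = 10),
                                  c(id = 2, x = 30, y = 10))))
  sc <- matrix(c(0.6, 0.9), 1, 2)
  g <- link_contiguous(fr, lookup_scorer(sc))
  expect_equal(nrow(g$edges), 1)
  expect_equal(unname(g$vertices[[g$edges$to]]$id), 2L)
})

test_that("pass-1 conflicts resolve by descending score with both degrees <= 1", {
  # two instances prefer the same target; the higher score wins it and the
  # loser takes its next-best admissible candidate
  fr <- frames_fixture(list(rbind(c(id = 1, x = 0, y = 0),
                                  c(id = 2, x = 40, y = 0)),
                            rbind(c(id = 1, x = 2, y = 0),
                                  c(id = 2, x = 42, y = 0))))
  sc <- matrix(c(0.9, 0.7,
                 0.8, 0.6), 2, 2, byrow = TRUE) # rows: from; cols: to
  g <- link_contiguous(fr, lookup_scorer(sc))
  expect_equal(nrow(g$edges), 2)
  edge_ids <- apply(g$edges, 1, function(e)
    c(g$vertices[[e["from"]]]$id, g$vertices[[e["to"]]]$id))
  expect_true(any(edge_ids[1, ] == 1 & edge_ids[2, ] == 1))
  expect_true(any(edge_ids[1, ] == 2 & edge_ids[2, ] == 2))
  expect_true(all(chronotrap:::graph_in_deg(g) <= 1))
})

test_that("unsorted frames are rejected", {
  fr <- frames_fixture(list(cbind(id = 1, x = 0, y = 0),
                            cbind(id = 1, x = 0, y = 0)))
  expect_error(link_contiguous(rev(fr), lookup_scorer(matrix(1, 1, 1))),
               "time-ordered")
})

test_that("pass 2 bridges gaps under the 12 h limit, best first", {
  # tuboid A: frames 1-2; tuboid B: frames 5-6 (gap 3 frames, 1 h)
  mk_frames <- function(gap_min) {
    list(list(inst_square(0, 0, 10, 1L, t0, id = 1L)),
         list(inst_square(1, 0, 10, 2L, t0 + 1200, id = 2L)),
         list(), list(),
         list(inst_square(2, 0, 10, 5L, t0 + gap_min * 60, id = 3L)),
         list(inst_square(3, 0, 10, 6L, t0 + gap_min * 60 + 1200,
                          id = 4L)))
  }
  scorer <- function(m, n) if (abs(m$id - n$id) == 1) 0.8 else 0.6
  g <- link_contiguous(mk_frames(60), scorer)
  expect_equal(nrow(g$edges), 2)
  g2 <- bridge_gaps(g, scorer)
  expect_equal(nrow(g2$edges), 3) # tail of A joined to head of B
  # same topology but a 13 h gap: no bridge
  g <- link_contiguous(mk_frames(13 * 60), scorer)
  g2 <- bridge_gaps(g, scorer)
  expect_equal(nrow(g2$edges), 2)
})

test_that("pass 2 always connects the highest-scoring admissible pair first", {
  # one tail, two candidate heads scored 0.7 and 0.9
  frames <- list(
    list(inst_square(0, 0, 10, 1L, t0, id = 1L)),
    list(inst_square(1, 0, 10, 2L, t0 + 1200, id = 2L)),
    list(),
    list(inst_square(2, 0, 10, 4L, t0 + 3 * 1200, id = 3L),
         inst_square(30, 0, 10, 4L, t0 + 3 * 1200, id = 4L)),
    list(inst_square(3, 0, 10, 5L, t0 + 4 * 1200, id = 5L),
         inst_square(31, 0, 10, 5L, t0 + 4 * 1200, id = 6L)))
  scorer <- function(m, n) {
    key <- paste(m$id, n$id)
    if (key %in% c("1 2", "3 5", "4 6")) return(0.95) # within-tuboid links
    if (key == "2 3") return(0.7)
    if (key == "2 4") return(0.9)
    0
  }
  g <- bridge_gaps(link_contiguous(frames, scorer), scorer)
  bridge <- g$edges[g$edges$score %in% c(0.7, 0.9), ]
  expect_equal(nrow(bridge), 1)
  expect_equal(bridge$score, 0.9) # 0.9 won; 0.7 re-evaluated, but tail used
})

test_that("the conjoint predicate follows the time-interleaving definition", {
  tms <- function(v) list(times = t0 + v * 1200)
  expect_true(conjoint(tms(c(1, 3, 5)), tms(c(2, 4, 6))))
  expect_false(conjoint(tms(c(1, 2, 3)), tms(c(3, 4, 5)))) # coincident 3
  expect_false(conjoint(tms(c(1, 2)), tms(c(5, 6))))       # no overlap
  expect_true(conjoint(tms(c(2, 4)), tms(c(1, 3, 5))))     # nested
  expect_error(conjoint(tms(numeric(0)), tms(1)), "empty")
})

test_that("pass 3 merges interleaved tuboids when the mean score clears 0.25", {
  interleaved <- function(all_score) {
    frames <- lapply(1:6, function(f) {
      x <- if (f %% 2 == 1) 0 else 100
      list(inst_square(x + f, 0, 10, as.integer(f), t0 + f * 1200,
                       id = as.integer(f)))
    })
    scorer <- function(m, n) {
      same_parity <- (m$id %% 2) == (n$id %% 2)
      if (same_parity && abs(m$id - n$id) == 2) return(0.9)
      if (!same_parity) return(all_score)
      0
    }
    g <- link_contiguous(frames, scorer)
    g <- bridge_gaps(g, scorer)    # builds the two odd/even tuboids
    merge_conjoint(g, scorer, tracker_config(min_vertices = 3))
  }
  g <- interleaved(0.3)
  comp <- chronotrap:::graph_components(g)
  expect_equal(length(unique(comp)), 1) # merged into one 6-vertex tuboid
  tb <- extract_tuboids(g, tracker_config(min_vertices = 4))
  expect_length(tb, 1)
  expect_length(tb[[1]]$instances, 6)
  expect_equal(vapply(tb[[1]]$instances, function(i) i$id, integer(1)), 1:6)
  # below threshold: stays split
  g <- interleaved(0.2)
  expect_equal(length(unique(chronotrap:::graph_components(g))), 2)
})

test_that("pass 3 merges highest pair first and revisits the merged tuboid", {
  # three mutually conjoint singleton-chains A (frames 1,4), B (2,5), C (3,6)
  frames <- lapply(1:6, function(f)
    list(inst_square(f, 0, 10, as.integer(f), t0 + f * 1200,
                     id = as.integer(f))))
  pair_of <- function(id) ((id - 1) %% 3) + 1 # 1->A, 2->B, 3->C
  scorer <- function(m, n) {
    a <- pair_of(m$id); b <- pair_of(n$id)
    if (a == b) return(0.9)                       # within-chain links
    key <- paste(sort(c(a, b)), collapse = "")
    # cross-chain scores: below the 0.5 link/bridge threshold but above
    # the 0.25 merge threshold, with AB ranked first
    switch(key, "12" = 0.45, "23" = 0.35, "13" = 0.3)
  }
  cfg <- tracker_config(min_vertices = 2)
  g <- link_contiguous(frames, scorer)
  g <- bridge_gaps(g, scorer, cfg)
  expect_equal(length(unique(chronotrap:::graph_components(g))), 3)
  g <- merge_conjoint(g, scorer, cfg)
  # AB merged first (0.6), then (AB)C re-evaluated and merged (>= 0.25)
  expect_equal(length(unique(chronotrap:::graph_components(g))), 1)
  expect_true(all(chronotrap:::graph_in_deg(g) <= 1))
  expect_true(all(chronotrap:::graph_out_deg(g) <= 1))
})

test_that("tuboid extraction prunes small components and orders stably", {
  frames <- c(
    lapply(1:4, function(f)
      list(inst_square(0, 0, 10, as.integer(f), t0 + f * 1200, id = 1L))),
    lapply(5:7, function(f)
      list(inst_square(50, 0, 10, as.integer(f), t0 + (f + 20) * 1200,
                       id = 2L))))
  frames <- lapply(seq_along(frames), function(f) {
    lapply(frames[[f]], function(i) { i$frame_id <- as.integer(f); i })
  })
  scorer <- function(m, n) if (m$id == n$id) 0.9 else 0
  g <- link_contiguous(frames, scorer)
  tb <- extract_tuboids(g) # 4-vertex kept, 3-vertex dropped
  expect_length(tb, 1)
  expect_length(tb[[1]]$instances, 4)
  tb <- extract_tuboids(g, tracker_config(min_vertices = 3))
  expect_length(tb, 2)
  expect_true(tb[[1]]$start < tb[[2]]$start)
  empty <- chronotrap:::new_tracking_graph(list())
  expect_length(extract_tuboids(empty), 0)
})

test_that("greedy pass 1 equals the recursive argmax reference", {
  set.seed(21)
  for (rep in 1:60) {
    n_frames <- sample(2:5, 1)
    counts <- sample(0:6, n_frames, replace = TRUE)
    frames <- lapply(seq_len(n_frames), function(f) {
      if (counts[f] == 0) return(list())
      lapply(seq_len(counts[f]), function(k)
        inst_square(k * 25, f * 5, 10, as.integer(f), t0 + f * 1200,
                    id = as.integer(k)))
    })
    smats <- lapply(seq_len(n_frames - 1), function(f)
      matrix(runif(counts[f] * counts[f + 1]), counts[f], counts[f + 1]))
    scorer <- function(m, n) smats[[m$frame_id]][m$id, n$id]
    g <- link_contiguous(frames, scorer)
    for (f in seq_len(n_frames - 1)) {
      ref <- oracle_link_transition(frames[[f]], frames[[f + 1]], scorer,
                                    0.5)
      got <- g$edges[g$edges$from %in%
                       vapply(g$vertices, function(v)
                         if (v$frame_id == f) v$vid else -1L, integer(1)), ]
      got_pairs <- sort(paste(
        vapply(got$from, function(v) g$vertices[[v]]$id, integer(1)),
        vapply(got$to, function(v) g$vertices[[v]]$id, integer(1))))
      ref_pairs <- sort(paste(ref$from, ref$to))
      expect_identical(got_pairs, ref_pairs)
    }
  }
})

test_that("degree and forward-time invariants hold through all passes", {
  sc <- test_scene()
  head <- trained_test_head()
  scorer <- make_series_scorer(sc$series$frames, head)
  g <- link_contiguous(sc$dets, scorer)
  g <- bridge_gaps(g, scorer)
  g <- merge_conjoint(g, scorer)
  expect_true(all(chronotrap:::graph_in_deg(g) <= 1))
  expect_true(all(chronotrap:::graph_out_deg(g) <= 1))
  tfrom <- vapply(g$vertices[g$edges$from], function(v) as.numeric(v$time),
                  numeric(1))
  tto <- vapply(g$vertices[g$edges$to], function(v) as.numeric(v$time),
                numeric(1))
  expect_true(all(tto > tfrom))
})

test_that("tracking metrics quantify splits and fusions", {
  mk_tb <- function(id, truth_ids) {
    insts <- lapply(seq_along(truth_ids), function(k) {
      i <- inst_square(0, 0, 10, as.integer(k), t0 + k * 1200, id = k)
      i$truth_id <- truth_ids[k]
      i
    })
    structure(list(id = id, instances = insts,
                   times = t0 + seq_along(truth_ids) * 1200,
                   frames = seq_along(truth_ids),
                   start = as.numeric(t0) + 1200,
                   end = as.numeric(t0) + length(truth_ids) * 1200),
              class = "tuboid")
  }
  perfect <- list(mk_tb(1, rep("a", 5)), mk_tb(2, rep("b", 5)))
  m <- evaluate_tracking(perfect)
  expect_equal(m$purity, 1)
  expect_equal(m$completeness, 1)
  expect_equal(m$id_switches, 0)
  # one truth track split into halves
  split <- list(mk_tb(1, rep("a", 4)), mk_tb(2, rep("a", 4)))
  m <- evaluate_tracking(split)
  expect_lte(m$completeness, 0.5 + 1e-9)
  expect_equal(m$n_splits, 1)
  # two truth tracks fused
  fused <- list(mk_tb(1, c(rep("a", 4), rep("b", 4))))
  m <- evaluate_tracking(fused)
  expect_lt(m$purity, 1)
  expect_equal(m$n_merges, 1)
  expect_equal(m$id_switches, 1)
})

test_that("synthetic end-to-end tracking is deterministic and accurate", {
  sc <- test_scene()
  head <- trained_test_head()
  scorer <- make_series_scorer(sc$series$frames, head)
  tb1 <- track_series(sc$dets, scorer)
  tb2 <- track_series(sc$dets,
                      make_series_scorer(sc$series$frames, head))
  expect_equal(lapply(tb1, function(t) t$frames),
               lapply(tb2, function(t) t$frames))
  m <- evaluate_tracking(tb1)
  expect_gte(m$purity, 0.9)
  expect_gte(m$completeness, 0.9)
})
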