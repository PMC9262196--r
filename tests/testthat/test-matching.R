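t0 <- as.POSIXct("2020-07-01 00:00:00", tz = "UTC")

# small frame pair with one textured blob each
matching_frames <- function(seed = 5) {
  set.seed(seed)
  f1 <- matrix(0.85 + rnorm(120 * 100, 0, 0.01), 120, 100)
  f2 <- matrix(0.85 + rnorm(120 * 100, 0, 0.01), 120, 100)
  tex <- matrix(0.3 + runif(40 * 40, -0.1, 0.1), 40, 40)
  f1[30:60, 30:60] <- tex[1:31, 1:31]
  f2[33:63, 32:62] <- tex[1:31, 1:31] # same insect, shifted (+3, +2)
  list(f1 = f1, f2 = f2)
}

inst_at <- function(x0, y0, side = 31, frame_id = 1L, time = t0) {
  inst_square(x0, y0, side, frame_id = frame_id, time = time)
}

test_that("backend satisfies the descriptor contract", {
  fr <- matching_frames()
  b <- ncc_backend()
  m <- inst_at(29, 29)
  cm <- chronotrap:::masked_crop(fr$f1, m)
  expect_equal(b$similarity(cm, cm), 1, tolerance = 1e-6)
  n <- inst_at(32, 31, frame_id = 2L, time = t0 + 1200)
  cn <- chronotrap:::masked_crop(fr$f2, n)
  expect_equal(b$similarity(cm, cn), b$similarity(cn, cm),
               tolerance = 1e-6)
  expect_length(b$embed(cm), b$dim)
  expect_equal(sqrt(sum(b$embed(cm)^2)), 1, tolerance = 1e-9)
})

test_that("naive similarity separates same-insect from noise crops", {
  fr <- matching_frames()
  b <- ncc_backend()
  m <- inst_at(29, 29)
  n <- inst_at(32, 31, frame_id = 2L, time = t0 + 1200)
  S_same <- naive_similarity(m, n, fr$f1, fr$f2, b)
  expect_gt(S_same, 0.8)
  expect_equal(naive_similarity(m, n, fr$f1, fr$f2, b),
               naive_similarity(n, m, fr$f2, fr$f1, b), tolerance = 1e-6)
  # crop of pure background noise elsewhere
  noise <- inst_at(80, 60, frame_id = 2L, time = t0 + 1200)
  expect_lt(naive_similarity(m, noise, fr$f1, fr$f2, b), 0.5)
})

test_that("delayed self-similarity flags non-movers and ignores n's mask", {
  fr <- matching_frames()
  b <- ncc_backend()
  m <- inst_at(29, 29)
  # same frame twice: Q = 1
  expect_equal(self_similarity(m, fr$f1, fr$f1, b), 1, tolerance = 1e-6)
  # insect moved away: footprint in frame 2 is background there, Q low
  set.seed(9)
  f2_gone <- matrix(0.85 + rnorm(120 * 100, 0, 0.01), 120, 100)
  expect_lt(self_similarity(m, fr$f1, f2_gone, b), 0.5)
  # Q never looks at n: identical for any n by construction of the API
  expect_error(self_similarity(inst_at(110, 90, side = 31), fr$f1,
                               matrix(0.8, 50, 50)), "outside")
})

test_that("feature assembly matches the definitions", {
  m <- inst_at(0, 0, side = 10)
  n0 <- inst_at(3, 4, side = 10, frame_id = 2L, time = t0) # dt = 0
  f <- assemble_features(m, n0, S = 0.9, Q = 0.2)
  expect_equal(unname(f["log_dt"]), 0)
  expect_equal(unname(f["abs_log_area_ratio"]), 0)
  expect_equal(unname(f["centroid_dist"]), 5) # 3-4-5 triangle
  n1 <- inst_at(3, 4, side = 10, frame_id = 2L, time = t0 + 3 * 3600)
  f1 <- assemble_features(m, n1, S = 0.9, Q = 0.2)
  expect_equal(unname(f1["log_dt"]), log(4))
  # translation invariance
  m2 <- inst_at(50, 60, side = 10)
  n2 <- inst_at(53, 64, side = 10, frame_id = 2L, time = t0 + 3 * 3600)
  f2 <- assemble_features(m2, n2, S = 0.9, Q = 0.2)
  expect_equal(unclass(f1), unclass(f2))
  # time order enforced
  nm1 <- inst_at(0, 0, side = 10, time = t0 - 60)
  expect_error(assemble_features(m, nm1, S = 1, Q = 1), "precede")
})

test_that("match head has the stated architecture semantics", {
  f <- c(S = 0.5, Q = 0.5, centroid_dist = 10, abs_log_area_ratio = 0.1,
         log_dt = 0.3)
  zero <- match_head()
  expect_equal(match_score(f, zero), 0.5) # sigmoid(0)
  set.seed(1)
  w <- chronotrap:::new_head_weights()
  h <- match_head(weights = w)
  s <- match_score(f, h)
  expect_gt(s, 0); expect_lt(s, 1)
  expect_equal(match_score(f, h), s) # deterministic
  expect_error(match_score(c(f[-5], log_dt = NaN), h), "finite")
})

test_that("training on separable pairs reaches high held-out accuracy", {
  train <- synthetic_pairs(400, seed = 7)
  test <- synthetic_pairs(200, seed = 8)
  head <- trained_test_head()
  expect_lt(tail(head$loss_trace, 1), head$loss_trace[1])
  preds <- as.numeric(match_score(test$features, head) >= 0.5)
  expect_gte(mean(preds == test$labels), 0.9)
  # logistic fallback performs comparably on linear structure
  lg <- fit_matcher_logistic(train$features, train$labels)
  predl <- as.numeric(match_score(test$features, lg) >= 0.5)
  expect_gte(mean(predl == test$labels), 0.9)
})

test_that("training is deterministic under a fixed seed and rejects one class", {
  p <- synthetic_pairs(120, seed = 3)
  h1 <- fit_matcher(p$features, p$labels, schedule = list(pretrain = 0,
                                                          head = 60,
                                                          finetune = 0),
                    seed = 5)
  h2 <- fit_matcher(p$features, p$labels, schedule = list(pretrain = 0,
                                                          head = 60,
                                                          finetune = 0),
                    seed = 5)
  expect_identical(h1$weights, h2$weights)
  expect_error(fit_matcher(p$features[p$labels == 1, ],
                           p$labels[p$labels == 1]), "classes")
})

test_that("heavily imbalanced input still trains a usable head", {
  set.seed(11)
  p <- synthetic_pairs(840, seed = 13)
  # 20:1 imbalance: drop most positives
  keep <- c(which(p$labels == 1)[1:20], which(p$labels == 0))
  h <- fit_matcher(p$features[keep, ], p$labels[keep], seed = 2)
  test <- synthetic_pairs(200, seed = 14)
  acc <- mean((match_score(test$features, h) >= 0.5) == test$labels)
  expect_gte(acc, 0.9) # balanced batches rescue the minority class
})

test_that("increasing centroid distance never increases the score", {
  head <- trained_test_head()
  p <- synthetic_pairs(400, seed = 7)
  base <- colMeans(p$features)
  dists <- seq(0, 200, by = 10)
  scores <- vapply(dists, function(d) {
    f <- base; f["centroid_dist"] <- d
    match_score(f, head)
  }, numeric(1))
  expect_true(all(diff(scores) <= 0.02))
})

test_that("series scorer reproduces the manual computation and gates far pairs", {
  fr <- matching_frames()
  head <- trained_test_head()
  b <- ncc_backend()
  m <- inst_at(29, 29); m$id <- 1L
  n <- inst_at(32, 31, frame_id = 2L, time = t0 + 1200); n$id <- 1L
  scorer <- make_series_scorer(list(fr$f1, fr$f2), head, b, gate_px = 50)
  S <- naive_similarity(m, n, fr$f1, fr$f2, b)
  Q <- self_similarity(m, fr$f1, fr$f2, b)
  manual <- match_score(assemble_features(m, n, S = S, Q = Q), head)
  expect_equal(scorer(m, n), manual)
  far <- inst_at(100, 80, frame_id = 2L, time = t0 + 1200); far$id <- 2L
  expect_equal(scorer(m, far), 0)
})
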