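# Pairwise matching: appearance similarity (naive similarity S and delayed
# self-similarity Q) from a pluggable descriptor backend, combined with
# geometric/temporal statistics through a small fully connected decision
# head into the matching score M(m, n) in [0, 1] that drives tracking.

# ---- masked crops ----------------------------------------------------------

# X intersect A: image values over the instance bbox with pixels outside the
# mask zeroed. `mask_of` reuses the exact segmentation pixel set when
# available, else rasterizes the polygon.
masked_crop <- function(image, inst) {
  b <- round(inst$bbox)
  x0 <- max(0, b[1]); y0 <- max(0, b[2])
  x1 <- min(nrow(image), b[3]); y1 <- min(ncol(image), b[4])
  if (x1 <= x0 || y1 <= y0)
    stop("instance footprint outside frame bounds", call. = FALSE)
  crop <- image[(x0 + 1):x1, (y0 + 1):y1, drop = FALSE]
  pix <- instance_pixels(inst)
  if (nrow(pix) == 0L) stop("empty mask", call. = FALSE)
  keep <- matrix(FALSE, nrow(crop), ncol(crop))
  px <- pix[, 1] - x0 + 1L; py <- pix[, 2] - y0 + 1L
  ok <- px >= 1 & px <= nrow(crop) & py >= 1 & py <= ncol(crop)
  keep[cbind(px[ok], py[ok])] <- TRUE
  crop[!keep] <- 0
  crop
}

resize_square <- function(m, side) {
  if (nrow(m) == side && ncol(m) == side) return(m)
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = side, h = side))
}

# ---- descriptor backend contract ------------------------------------------

#' Normalized cross-correlation descriptor backend
#'
#' Default desk-scale appearance descriptor: crops are rescaled to a
#' 105 x 105 px grayscale patch; the embedding is the flattened patch and
#' the similarity D is the Pearson correlation of two embeddings clipped to
#' \[0, 1\] (`max(r, 0)`). Clipping, rather than the affine map (r+1)/2,
#' keeps unrelated pairs (r around 0) near similarity 0 instead of exactly at
#' the 0.5 matching threshold. D is symmetric and D(x, x) = 1. Learned
#' descriptors plug into the same contract: a list with `name`, `dim`,
#' `embed(crop) -> numeric vector` and `similarity(crop_a, crop_b) -> [0,1]`.
#'
#' @param side input side length in px (default 105).
#' @return Backend object of class `"descriptor_backend"`.
#' @export
ncc_backend <- function(side = 105) {
  embed <- function(crop) {
    v <- as.numeric(resize_square(crop, side))
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else v
  }
  similarity <- function(crop_a, crop_b) {
    a <- as.numeric(resize_square(crop_a, side))
    b <- as.numeric(resize_square(crop_b, side))
    if (sd(a) < 1e-12 || sd(b) < 1e-12) {
      return(if (max(abs(a - b)) < 1e-9) 1 else 0)
    }
    max(cor(a, b), 0)
  }
  structure(list(name = "ncc", dim = side * side, side = side,
                 embed = embed, similarity = similarity),
            class = "descriptor_backend")
}

#' Naive similarity S between two instances
#'
#' S(m, n) = D(X_i with m's mask, X_j with n's mask): each instance's masked
#' crop taken from its own frame, compared by the backend.
#'
#' @param m,n detection instances.
#' @param frame_i,frame_j the image matrices the instances were detected in.
#' @param backend a descriptor backend (default [ncc_backend()]).
#' @return S in \[0, 1\].
#' @export
naive_similarity <- function(m, n, frame_i, frame_j,
                             backend = ncc_backend()) {
  backend$similarity(masked_crop(frame_i, m), masked_crop(frame_j, n))
}

#' Delayed self-similarity Q of an instance
#'
#' Q(m, n) = D(X_i with m's mask, X_j with m's mask): m's masked crop versus
#' the same pixel footprint (same mask A_m) in the later frame j. High Q
#' means the first insect has, in fact, not moved; Q depends only on m and
#' the two frames, never on n's mask.
#'
#' @param m detection instance from frame i.
#' @param frame_i,frame_j image matrices; m's footprint must lie within
#'   `frame_j` bounds.
#' @inheritParams naive_similarity
#' @return Q in \[0, 1\].
#' @export
self_similarity <- function(m, frame_i, frame_j, backend = ncc_backend()) {
  if (m$bbox[3] > nrow(frame_j) + 0.5 || m$bbox[4] > ncol(frame_j) + 0.5 ||
      m$bbox[1] < -0.5 || m$bbox[2] < -0.5)
    stop("instance footprint outside frame_j bounds", call. = FALSE)
  backend$similarity(masked_crop(frame_i, m), masked_crop(frame_j, m))
}

# ---- feature assembly ------------------------------------------------------

#' Assemble the 5 matching features
#'
#' The input vector of the decision head:
#' `I = (S, Q, d(C(m), C(n)), |log(A_m / A_n)|, log(dt + 1))` with the
#' centroid distance in px and dt = t_n - t_m in hours.
#'
#' @param m,n detection instances with `time` set; `n` must not precede `m`.
#' @param S,Q appearance similarities; either supply them precomputed or
#'   pass `frame_i`, `frame_j` (and optionally `backend`) to compute them.
#' @inheritParams naive_similarity
#' @return Named numeric vector of class `"match_features"`:
#'   `S`, `Q`, `centroid_dist`, `abs_log_area_ratio`, `log_dt`.
#' @export
assemble_features <- function(m, n, S = NULL, Q = NULL, frame_i = NULL,
                              frame_j = NULL, backend = ncc_backend()) {
  if (m$area <= 0 || n$area <= 0) stop("zero area instance", call. = FALSE)
  dt_h <- as.numeric(difftime(n$time, m$time, units = "hours"))
  if (is.na(dt_h) || dt_h < 0)
    stop("n must not precede m in time", call. = FALSE)
  if (is.null(S)) S <- naive_similarity(m, n, frame_i, frame_j, backend)
  if (is.null(Q)) Q <- self_similarity(m, frame_i, frame_j, backend)
  f <- c(S = S, Q = Q,
         centroid_dist = sqrt(sum((m$centroid - n$centroid)^2)),
         abs_log_area_ratio = abs(log(m$area / n$area)),
         log_dt = log(dt_h + 1))
  if (any(!is.finite(f))) stop("non-finite match feature", call. = FALSE)
  class(f) <- "match_features"
  f
}

# ---- decision head ---------------------------------------------------------

#' Matching decision head (5-4-3-1 fully connected network)
#'
#' Layer sizes 5, 4, 3, 1 with rectifier activations after the first two
#' weight layers and a sigmoid output; input features are z-scored with the
#' normalization constants stored in the head. All-zero weights give
#' M = sigmoid(0) = 0.5.
#'
#' @param weights optional list `W1` (4 x 5), `b1`, `W2` (3 x 4), `b2`, `W3`
#'   (1 x 3), `b3`; zeros by default.
#' @param norm optional list `mean`, `sd` (length 5) for input z-scoring;
#'   identity by default.
#' @return Object of class `"match_head"`.
#' @export
match_head <- function(weights = NULL, norm = NULL) {
  if (is.null(weights))
    weights <- list(W1 = matrix(0, 4, 5), b1 = numeric(4),
                    W2 = matrix(0, 3, 4), b2 = numeric(3),
                    W3 = matrix(0, 1, 3), b3 = numeric(1))
  stopifnot(identical(dim(weights$W1), c(4L, 5L)),
            identical(dim(weights$W2), c(3L, 4L)),
            identical(dim(weights$W3), c(1L, 3L)))
  if (is.null(norm)) norm <- list(mean = rep(0, 5), sd = rep(1, 5))
  structure(list(weights = weights, norm = norm), class = "match_head")
}

head_forward <- function(head, x) {
  # x: 5 x n matrix of raw features (columns = cases)
  z <- (x - head$norm$mean) / head$norm$sd
  w <- head$weights
  h1 <- pmax(w$W1 %*% z + w$b1, 0)
  h2 <- pmax(w$W2 %*% h1 + w$b2, 0)
  o <- w$W3 %*% h2 + w$b3
  1 / (1 + exp(-o))
}

#' Matching score M(m, n)
#'
#' @param f a [assemble_features()] vector (or 5-column matrix, one row per
#'   pair).
#' @param head a [match_head()] (default: trained or zero-initialised) or a
#'   logistic fallback from [fit_matcher_logistic()].
#' @return M in (0, 1), deterministic given weights and input.
#' @export
match_score <- function(f, head) {
  x <- if (is.matrix(f)) t(f) else matrix(as.numeric(f), ncol = 1)
  if (any(!is.finite(x))) stop("non-finite feature", call. = FALSE)
  if (inherits(head, "match_head")) {
    as.numeric(head_forward(head, x))
  } else if (inherits(head, "logistic_match_head")) {
    eta <- head$coef[1] + as.numeric(t(x) %*% head$coef[-1])
    1 / (1 + exp(-eta))
  } else stop("unknown head type", call. = FALSE)
}

# ---- training --------------------------------------------------------------

new_head_weights <- function(scale = 0.5) {
  list(W1 = matrix(rnorm(20, 0, scale), 4, 5), b1 = rnorm(4, 0, 0.1),
       W2 = matrix(rnorm(12, 0, scale), 3, 4), b2 = rnorm(3, 0, 0.1),
       W3 = matrix(rnorm(3, 0, scale), 1, 3), b3 = rnorm(1, 0, 0.1))
}

# One Adam step over a batch; returns updated state. Plain analytic backprop
# through the 5-4-3-1 network with binary cross-entropy loss.
head_grad <- function(w, z, y) {
  n <- ncol(z)
  a1 <- w$W1 %*% z + w$b1; h1 <- pmax(a1, 0)
  a2 <- w$W2 %*% h1 + w$b2; h2 <- pmax(a2, 0)
  o <- as.numeric(w$W3 %*% h2 + w$b3)
  p <- 1 / (1 + exp(-o))
  do <- matrix(p - y, 1) / n                 # dL/do for BCE + sigmoid
  gW3 <- do %*% t(h2); gb3 <- sum(do)
  dh2 <- (t(w$W3) %*% do) * (a2 > 0)
  gW2 <- dh2 %*% t(h1); gb2 <- rowSums(dh2)
  dh1 <- (t(w$W2) %*% dh2) * (a1 > 0)
  gW1 <- dh1 %*% t(z); gb1 <- rowSums(dh1)
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  list(g = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3),
       loss = loss)
}

#' Train the matching head on labelled pairs
#'
#' Three-phase schedule mirroring the staged training of the full system:
#' (1) pretrain the similarity backend, (2) train the decision head only,
#' (3) joint fine-tune. The default descriptor backend has no trainable
#' parameters, so phases 1 and 3 are recorded as no-ops unless the supplied
#' backend provides `fit` hooks; phase 2 optimises the head by Adam on
#' binary cross-entropy. Each batch re-samples the negative class to a 0.5
#' proportion regardless of the input imbalance.
#'
#' @param features n x 5 matrix of [assemble_features()] rows.
#' @param labels binary vector (1 = same insect); both classes required.
#' @param backend descriptor backend (for its optional `fit` hooks).
#' @param schedule list with phase lengths `pretrain`, `head`, `finetune`
#'   (rounds; one round = one batch).
#' @param batch batch size.
#' @param lr Adam learning rate for the head phase.
#' @param seed integer seed; fixed seed gives identical final weights.
#' @return A trained [match_head()] with `$loss_trace` and `$schedule`
#'   attached.
#' @export
fit_matcher <- function(features, labels, backend = ncc_backend(),
                        schedule = list(pretrain = 0, head = 400,
                                        finetune = 0),
                        batch = 64, lr = 0.05, seed = 1L) {
  stopifnot(is.matrix(features), ncol(features) == 5)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  set.seed(seed)
  norm <- list(mean = colMeans(features),
               sd = pmax(apply(features, 2, sd), 1e-8))
  z_all <- t((t(features) - norm$mean) / norm$sd)
  pos <- which(labels == 1); neg <- which(labels == 0)
  phases <- character(0)
  if (schedule$pretrain > 0 && is.function(backend$fit)) {
    backend <- backend$fit(features, labels, rounds = schedule$pretrain)
    phases <- c(phases, "pretrain")
  } else phases <- c(phases, "pretrain:noop")

  w <- new_head_weights()
  mstate <- rapply(w, function(x) x * 0, how = "list")
  vstate <- rapply(w, function(x) x * 0, how = "list")
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(schedule$head)
  for (it in seq_len(schedule$head)) {
    np <- min(length(pos), ceiling(batch / 2))
    ip <- sample(pos, np, replace = length(pos) < np)
    im <- sample(neg, batch - np, replace = length(neg) < batch - np)
    idx <- c(ip, im)
    gr <- head_grad(w, t(z_all[idx, , drop = FALSE]), labels[idx])
    trace[it] <- gr$loss
    for (nm in names(w)) {
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr$g[[nm]]
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr$g[[nm]]^2
      mh <- mstate[[nm]] / (1 - b1^it)
      vh <- vstate[[nm]] / (1 - b2^it)
      w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  phases <- c(phases, "head")
  phases <- c(phases, if (schedule$finetune > 0 && is.function(backend$fit))
    "finetune" else "finetune:noop")
  out <- match_head(weights = w, norm = norm)
  out$loss_trace <- trace
  out$schedule <- phases
  out
}

#' Logistic-regression fallback head
#'
#' A plain logistic regression on the 5 matching features; useful when no
#' training beyond a linear decision boundary is warranted.
#'
#' @inheritParams fit_matcher
#' @return Object of class `"logistic_match_head"`.
#' @export
fit_matcher_logistic <- function(features, labels) {
  df <- as.data.frame(features)
  names(df) <- paste0("f", 1:5)
  fit <- suppressWarnings(
    stats::glm(labels ~ ., data = cbind(df, labels = as.numeric(labels)),
               family = stats::binomial()))
  structure(list(coef = unname(coef(fit))), class = "logistic_match_head")
}

# ---- series scorer ---------------------------------------------------------

#' Build a matching scorer over an image series
#'
#' Returns `scorer(m, n)` computing M(m, n) from the stored frames: masked
#' crops are cached per instance, and pairs whose centroids are farther than
#' `gate_px` apart are scored 0 without touching the backend (trapped
#' insects jitter by a few px; the gate only skips hopeless pairs).
#'
#' @param frames list of image matrices, indexed by `frame_id`.
#' @param head a trained [match_head()] (or logistic fallback).
#' @param backend descriptor backend.
#' @param gate_px centroid-distance gate in px (Inf disables gating).
#' @return Function `(m, n) -> M in [0, 1]`.
#' @export
make_series_scorer <- function(frames, head, backend = ncc_backend(),
                               gate_px = 150) {
  crop_cache <- new.env(parent = emptyenv())
  get_masked <- function(inst, frame_id) {
    key <- paste0(inst$frame_id, "_", inst$id, "@", frame_id)
    if (!is.null(crop_cache[[key]])) return(crop_cache[[key]])
    val <- masked_crop(frames[[frame_id]], inst)
    crop_cache[[key]] <- val
    val
  }
  function(m, n) {
    if (sqrt(sum((m$centroid - n$centroid)^2)) > gate_px) return(0)
    S <- backend$similarity(get_masked(m, m$frame_id),
                            get_masked(n, n$frame_id))
    Q <- backend$similarity(get_masked(m, m$frame_id),
                            get_masked(m, n$frame_id))
    f <- assemble_features(m, n, S = S, Q = Q)
    match_score(f, head)
  }
}
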