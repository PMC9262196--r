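# Tuboid classification: one taxonomic label per tracked insect, predicted
# from several frames at once. Six frames from the tuboid's first day are
# embedded by a pluggable per-frame embedder, fused by the element-wise
# median, augmented with the object's physical scale, and classified by a
# flat label head.

#' Pixel/millimetre scale conversion
#'
#' The imaging geometry gives a fixed scale; at the default
#' 15.5 px per mm, a 2 mm scale bar spans 31 px. The constant is exposed
#' as a parameter everywhere it is used rather than hard-coded.
#'
#' @param mm,px lengths to convert.
#' @param px_per_mm scale constant (default 15.5).
#' @return Converted length.
#' @export
mm_to_px <- function(mm, px_per_mm = 15.5) mm * px_per_mm

#' @rdname mm_to_px
#' @export
px_to_mm <- function(px, px_per_mm = 15.5) px / px_per_mm

#' Label scheme for tuboid classification
#'
#' An ordered list of flat class labels plus optional merge rules mapping
#' several labels onto one (e.g. collapsing the two catch-all classes
#' "Background objects" and "Undefined insects"). The default scheme holds
#' 18 labels typical of a berry-field community; any scheme can be supplied.
#'
#' @param labels character vector of unique labels.
#' @param merges named list: new label -> character vector of labels to
#'   collapse.
#' @return Object of class `"label_scheme"`.
#' @export
label_scheme <- function(labels = default_labels(),
                         merges = list(
                           "Background or undefined" =
                             c("Background objects", "Undefined insects"))) {
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  for (m in merges)
    if (!all(m %in% labels))
      stop("merge rules must map onto existing labels", call. = FALSE)
  structure(list(labels = labels, merges = merges), class = "label_scheme")
}

#' @rdname label_scheme
#' @export
default_labels <- function() c(
  "Background objects", "Undefined insects", "Macropsis fuscula",
  "Drosophila suzukii males", "Other Drosophilidae", "Anthonomus rubi",
  "Psyllobora vigintimaculata", "Other Coleoptera",
  "Lasioglossum laevissimum", "Figitidae", "Sciaridae", "Typhlocybinae",
  "Psychodidae", "Culicidae", "Lepidoptera", "Calyptratae", "Syrphidae",
  "Other Hemiptera")

#' Sample the frames used for classification
#'
#' The first frame is always included; `n_random` more are drawn uniformly
#' without replacement from the remaining frames within `horizon_h` hours of
#' the tuboid's start. When fewer than `n_random` are available the draw is
#' with replacement, so the output always has `n_random + 1` entries.
#'
#' @param tuboid a tuboid from [extract_tuboids()].
#' @param horizon_h sampling horizon after the first frame (default 24 h).
#' @param n_random number of random frames (default 5).
#' @param seed integer seed; sampling is reproducible.
#' @return Integer vector of `n_random + 1` indices into
#'   `tuboid$instances`, time-ordered, first frame first.
#' @export
sample_frames <- function(tuboid, horizon_h = 24, n_random = 5, seed = 1L) {
  nf <- length(tuboid$instances)
  if (nf == 0L) stop("empty tuboid", call. = FALSE)
  t0 <- as.numeric(tuboid$times[1])
  eligible <- which(as.numeric(tuboid$times) - t0 <= horizon_h * 3600)
  eligible <- setdiff(eligible, 1L)
  set.seed(seed)
  picked <- if (length(eligible) == 0L) {
    rep(1L, n_random)
  } else if (length(eligible) >= n_random) {
    sample(eligible, n_random)
  } else {
    sample(eligible, n_random, replace = TRUE)
  }
  c(1L, sort(picked))
}

# Pad a crop to a square (card-background value), then rescale.
pad_square <- function(crop, side = 224, fill = NULL) {
  if (is.null(fill)) fill <- median(crop)
  s <- max(nrow(crop), ncol(crop))
  sq <- matrix(fill, s, s)
  x0 <- floor((s - nrow(crop)) / 2); y0 <- floor((s - ncol(crop)) / 2)
  sq[x0 + seq_len(nrow(crop)), y0 + seq_len(ncol(crop))] <- crop
  resize_square(sq, side)
}

# Hu's seven moment invariants of an intensity patch (translation, scale and
# rotation invariant texture/shape summary).
hu_moments <- function(m) {
  m <- m / max(sum(m), 1e-12)
  nx <- nrow(m); ny <- ncol(m)
  x <- row(m) - sum(row(m) * m)
  y <- col(m) - sum(col(m) * m)
  mu <- function(p, q) sum(x^p * y^q * m)
  mu00 <- mu(0, 0)
  eta <- function(p, q) mu(p, q) / mu00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

#' Radial-histogram frame embedder
#'
#' Default desk-scale per-frame embedder: the crop is padded to a square and
#' rescaled to `side` px; the embedding concatenates mean darkness per
#' concentric ring (`n_rings` values), the seven Hu moment invariants
#' (signed log-scaled), and the overall mean and sd. A deep backbone plugs
#' into the same contract: a function `crop -> fixed-dimension numeric
#' vector`.
#'
#' @param n_rings number of concentric rings.
#' @param side working resolution (default 224).
#' @return Embedder function with a `"dim"` attribute.
#' @export
radial_embedder <- function(n_rings = 12, side = 224) {
  ring_idx <- NULL
  build_rings <- function() {
    cx <- (side + 1) / 2
    r <- sqrt((row(matrix(0, side, side)) - cx)^2 +
                (col(matrix(0, side, side)) - cx)^2)
    pmin(floor(r / (side / 2) * n_rings) + 1, n_rings)
  }
  f <- function(crop) {
    if (is.null(ring_idx)) ring_idx <<- build_rings()
    sq <- pad_square(crop, side)
    v <- 1 - sq # darkness
    rings <- vapply(seq_len(n_rings),
                    function(k) mean(v[ring_idx == k]), numeric(1))
    hu <- hu_moments(v)
    hu <- sign(hu) * log1p(abs(hu) * 1e6)
    c(rings, hu, mean(v), sd(v))
  }
  attr(f, "embed_dim") <- n_rings + 9L
  f
}

#' Fuse per-frame embeddings into one feature vector
#'
#' Element-wise median over the sampled frames, then the object's scale
#' appended. The median makes the fused vector robust to a minority of
#' corrupted frames and invariant to frame order.
#'
#' @param crops list of image crops (one per sampled frame).
#' @param embedder per-frame embedder (default [radial_embedder()]).
#' @param scale_px object scale: longest bbox side in px.
#' @param px_per_mm scale constant used to express the appended feature in
#'   mm.
#' @return Numeric vector of length `dim(embedder) + 1`; the last element is
#'   named `scale_mm`.
#' @export
fuse_frames <- function(crops, embedder = radial_embedder(), scale_px,
                        px_per_mm = 15.5) {
  emb <- lapply(crops, embedder)
  d <- unique(vapply(emb, length, integer(1)))
  if (length(d) != 1)
    stop("embedding dimension mismatch across frames", call. = FALSE)
  fused <- apply(do.call(rbind, emb), 2, median)
  c(fused, scale_mm = px_to_mm(scale_px, px_per_mm))
}

#' Features of one tuboid for classification
#'
#' Samples 6 frames ([sample_frames()]), embeds their crops and fuses them
#' ([fuse_frames()]); the scale is the median longest bbox side over the
#' sampled frames.
#'
#' @inheritParams sample_frames
#' @inheritParams fuse_frames
#' @return Fused feature vector.
#' @export
tuboid_features <- function(tuboid, embedder = radial_embedder(),
                            horizon_h = 24, n_random = 5, seed = 1L,
                            px_per_mm = 15.5) {
  idx <- sample_frames(tuboid, horizon_h, n_random, seed)
  crops <- lapply(tuboid$instances[idx], function(inst) {
    if (is.null(inst$crop)) stop("instances carry no crops", call. = FALSE)
    inst$crop
  })
  scale_px <- median(vapply(tuboid$instances[idx], instance_max_side,
                            numeric(1)))
  fuse_frames(crops, embedder, scale_px, px_per_mm)
}

#' Train the flat label head
#'
#' Multinomial logistic regression on fused features (the last, fully
#' connected layer of the architecture; here fit directly by
#' `nnet::multinom`).
#'
#' @param features matrix, one row per tuboid ([tuboid_features()] rows).
#' @param labels character vector of true labels (must be in `scheme`).
#' @param scheme a [label_scheme()].
#' @return Object of class `"tuboid_classifier"`.
#' @export
train_tuboid_classifier <- function(features, labels, scheme = label_scheme()) {
  if (!all(labels %in% scheme$labels))
    stop("label outside scheme", call. = FALSE)
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.label <- factor(labels, levels = scheme$labels)
  fit <- nnet::multinom(.label ~ ., data = df, trace = FALSE,
                        maxit = 300, MaxNWts = 5000)
  structure(list(fit = fit, scheme = scheme,
                 feature_names = names(df)[seq_len(ncol(features))],
                 classes = levels(droplevels(df$.label))),
            class = "tuboid_classifier")
}

#' Classify a fused feature vector
#'
#' @param model a [train_tuboid_classifier()] fit.
#' @param f fused feature vector (or matrix, one row per tuboid).
#' @param merge apply the scheme's merge rules to the probabilities?
#' @return List: `probs` (matrix, rows sum to 1), `label` (argmax per row).
#' @export
classify_tuboid <- function(model, f, merge = FALSE) {
  x <- if (is.matrix(f)) f else matrix(f, nrow = 1)
  df <- as.data.frame(x)
  names(df) <- model$feature_names
  p <- predict(model$fit, newdata = df, type = "probs")
  if (is.null(dim(p))) {
    if (length(model$classes) == 2L) {
      p <- cbind(1 - p, p)
      colnames(p) <- model$classes
    } else p <- matrix(p, nrow = nrow(x), dimnames = list(NULL, model$classes))
  }
  if (merge) p <- merge_label_probs(p, model$scheme)
  list(probs = p, label = colnames(p)[max.col(p, ties.method = "first")])
}

#' Collapse label probabilities under a scheme's merge rules
#'
#' Probabilities of merged labels are summed, so rows still sum to 1 over
#' the reduced label set.
#'
#' @param probs matrix with labels as columns.
#' @param scheme a [label_scheme()].
#' @return Probability matrix over the merged labels.
#' @export
merge_label_probs <- function(probs, scheme) {
  out <- probs
  for (new in names(scheme$merges)) {
    olds <- intersect(scheme$merges[[new]], colnames(out))
    if (length(olds) == 0) next
    merged <- rowSums(out[, olds, drop = FALSE])
    out <- out[, setdiff(colnames(out), olds), drop = FALSE]
    out <- cbind(out, merged)
    colnames(out)[ncol(out)] <- new
  }
  out
}

#' Per-label precision, recall and F1 plus confusion matrix
#'
#' @param pred,truth character vectors of predicted and true labels.
#' @param scheme a [label_scheme()]; labels outside it are an error.
#' @return List: `confusion` (rows = truth, columns = predicted),
#'   `per_label` data.frame (label, n_truth, precision, recall, f1),
#'   `accuracy` (trace / total).
#' @export
evaluate_classifier <- function(pred, truth, scheme = label_scheme()) {
  if (!all(c(pred, truth) %in% scheme$labels))
    stop("label outside scheme", call. = FALSE)
  lv <- scheme$labels
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  per_label <- do.call(rbind, lapply(lv, function(l) {
    tp <- cm[l, l]; fp <- sum(cm[, l]) - tp; fn <- sum(cm[l, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(label = l, n_truth = sum(cm[l, ]), precision = prec,
               recall = rec, f1 = f1, stringsAsFactors = FALSE)
  }))
  list(confusion = cm, per_label = per_label,
       accuracy = sum(diag(cm)) / sum(cm))
}
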