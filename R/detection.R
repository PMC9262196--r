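# Per-frame instance detection: pluggable per-tile segmenter applied to a
# tiled layout of the (padded) image, cross-tile Jaccard deduplication, and
# the size filters applied to every annotation source.

#' Plan a tile layout over an image
#'
#' Tiles are evenly spaced with the first tile at (0, 0) and the last flush
#' with the far edge: `x_i = round(i (W - tile) / (cols - 1))`. The default
#' (1024 px tiles in a 4 x 3 grid) covers a 2592 x 1944 px image with >= 500
#' px of overlap, so any insect narrower than 500 px is complete in at least
#' one tile.
#'
#' @param image_width,image_height image size in px.
#' @param tile_size square tile side in px (default 1024).
#' @param cols,rows grid layout (default 4 x 3).
#' @return Object of class `"tile_layout"`: `tile_size`, `cols`, `rows` and
#'   `offsets`, a data.frame (tile, x, y) in row-major order.
#' @examples
#' plan_tiles(2592, 1944)$offsets  # x: 0 523 1045 1568; y: 0 460 920
#' @export
plan_tiles <- function(image_width, image_height, tile_size = 1024,
                       cols = 4, rows = 3) {
  if (tile_size > image_width || tile_size > image_height)
    stop("tile_size exceeds image dimensions", call. = FALSE)
  xo <- if (cols == 1) 0 else
    round((0:(cols - 1)) * (image_width - tile_size) / (cols - 1))
  yo <- if (rows == 1) 0 else
    round((0:(rows - 1)) * (image_height - tile_size) / (rows - 1))
  offsets <- expand.grid(x = xo, y = yo) # row-major: x fastest
  offsets <- data.frame(tile = seq_len(nrow(offsets)), x = offsets$x,
                        y = offsets$y)
  structure(list(tile_size = tile_size, cols = cols, rows = rows,
                 width = image_width, height = image_height,
                 offsets = offsets),
            class = "tile_layout")
}

tile_extent <- function(layout, tile) {
  o <- layout$offsets[layout$offsets$tile == tile, ]
  c(o$x, o$y, o$x + layout$tile_size, o$y + layout$tile_size)
}

boxes_intersect <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

#' Classical blob segmenter (per-tile contract)
#'
#' Default desk-scale segmenter for dark insects on a light card: Otsu
#' threshold on the inverted intensities, connected-component labelling, and
#' optionally a watershed split of touching blobs. Learned backends plug into
#' [detect_frame()] through the same contract: a function taking a tile
#' matrix (values in \[0, 1\], rows = x) and returning a list of
#' [new_instance()] records in tile coordinates with scores.
#'
#' @param min_pixels components smaller than this many px are dropped as
#'   noise before any size filtering.
#' @param max_fg_fraction reject the threshold (return no detections) when it
#'   marks more than this fraction of the tile as foreground — the signature
#'   of a blank tile where Otsu splits noise.
#' @param min_contrast minimum foreground/background mean separation.
#' @param split_touching split touching blobs by watershed on the distance
#'   map (off by default; the simulator keeps insects disjoint).
#' @return A segmenter function.
#' @export
blob_segmenter <- function(min_pixels = 20, max_fg_fraction = 0.3,
                           min_contrast = 0.1, split_touching = FALSE) {
  force(min_pixels); force(max_fg_fraction); force(min_contrast)
  function(tile) {
    v <- 1 - tile
    # Threshold statistics on a regular pixel subsample: the histogram and
    # order statistics are stable well below full resolution.
    vs <- if (length(v) > 65536)
      v[seq(1L, length(v), by = ceiling(length(v) / 65536))] else as.numeric(v)
    # Otsu, capped by a robust background offset: with several insect
    # darkness modes Otsu can land between them and shatter the darker
    # blobs; the card occupies most of the tile, so median + MAD bounds the
    # background reliably.
    th <- min(EBImage::otsu(EBImage::Image(matrix(vs)), range = c(0, 1)),
              median(vs) + max(min_contrast, 6 * stats::mad(vs)))
    fg <- v > th
    if (!any(fg) || mean(fg) > max_fg_fraction) return(list())
    if (mean(v[fg]) - mean(v[!fg]) < min_contrast) return(list())
    # close 1-2 px texture holes so one insect stays one component
    fg <- EBImage::imageData(EBImage::closing(
      EBImage::Image(fg * 1), EBImage::makeBrush(3, "box"))) > 0
    lab <- if (split_touching) {
      EBImage::watershed(EBImage::distmap(EBImage::Image(fg * 1)), tolerance = 3)
    } else EBImage::bwlabel(EBImage::Image(fg * 1))
    lab_m <- EBImage::imageData(lab)
    contours <- EBImage::ocontour(lab)
    # one pass over foreground pixels, then split by component label
    fgidx <- which(lab_m > 0)
    nr <- nrow(lab_m)
    rows0 <- (fgidx - 1L) %% nr           # 0-based x
    cols0 <- (fgidx - 1L) %/% nr          # 0-based y
    by_comp <- split(seq_along(fgidx), lab_m[fgidx])
    out <- list()
    for (k in names(by_comp)) {
      s <- by_comp[[k]]
      if (length(s) < min_pixels) next
      ctr <- contours[[as.integer(k)]]
      if (is.null(ctr) || nrow(ctr) < 3) next
      poly <- cbind(ctr[, 1] + 0.5, ctr[, 2] + 0.5) # pixel centres
      score <- min(1, max(0, 0.5 + mean(v[fgidx[s]]) - th))
      out[[length(out) + 1L]] <-
        new_instance(poly, score = score,
                     pixels = cbind(rows0[s], cols0[s]))
    }
    out
  }
}

shift_instance <- function(inst, dx, dy) {
  inst$polygon <- translate_polygon(inst$polygon, dx, dy)
  inst$centroid <- inst$centroid + c(dx, dy)
  inst$bbox <- inst$bbox + c(dx, dy, dx, dy)
  if (!is.null(inst$pixels))
    inst$pixels <- cbind(inst$pixels[, 1] + dx, inst$pixels[, 2] + dy)
  inst
}

#' Detect insect instances in one frame
#'
#' Pads the image by a 32 px margin (so partial insects on the edge keep
#' their full context), runs the segmenter on every tile of the layout,
#' translates masks back to image coordinates, deduplicates across tiles via
#' the Jaccard rule and applies the size filter.
#'
#' @param image numeric matrix in \[0, 1\] (rows = x, cols = y).
#' @param segmenter per-tile segmenter (default [blob_segmenter()]).
#' @param layout a [plan_tiles()] layout for the padded image; when NULL a
#'   layout is chosen automatically (single tile if the padded image is
#'   <= `tile_size`, else an overlapping grid).
#' @param pad margin width in px (default 32).
#' @param pad_value padding intensity; NULL (default) uses the image median,
#'   i.e. the card background, so the classical segmenter sees no artificial
#'   edges. A learned backend trained with zero padding can pass 0.
#' @param tile_size used when `layout` is NULL.
#' @param min_len,max_len size-filter bounds in px, see [filter_by_size()].
#' @param crops attach image crops to instances (needed downstream by
#'   appearance matching)?
#' @return List of [new_instance()] records in original image coordinates,
#'   deduplicated and size-filtered.
#' @export
detect_frame <- function(image, segmenter = blob_segmenter(), layout = NULL,
                         pad = 32, pad_value = NULL, tile_size = 1024,
                         min_len = 30, max_len = 600, crops = TRUE) {
  w <- nrow(image); h <- ncol(image)
  if (is.null(pad_value))
    pad_value <- median(image[seq(1L, length(image),
                                  by = max(1L, length(image) %/% 65536))])
  padded <- matrix(pad_value, w + 2 * pad, h + 2 * pad)
  padded[pad + seq_len(w), pad + seq_len(h)] <- image
  pw <- nrow(padded); ph <- ncol(padded)
  if (is.null(layout)) {
    ts <- min(tile_size, pw, ph)
    cols <- max(1, ceiling(pw / ts * 1.3 - 0.3))
    rows <- max(1, ceiling(ph / ts * 1.3 - 0.3))
    layout <- plan_tiles(pw, ph, ts, cols, rows)
  }
  candidates <- list()
  for (t in layout$offsets$tile) {
    ext <- tile_extent(layout, t)
    tile <- padded[(ext[1] + 1):ext[3], (ext[2] + 1):ext[4], drop = FALSE]
    dets <- tryCatch(segmenter(tile), error = function(e)
      stop(sprintf("segmenter failed on tile %d: %s", t, conditionMessage(e)),
           call. = FALSE))
    for (d in dets) {
      # A mask cut by an interior tile edge is a fragment of an insect that
      # is complete in a neighbouring tile (the layout overlaps by more
      # than the largest insect), so drop it rather than hope the Jaccard
      # rule catches a sub-half fragment.
      pix <- instance_pixels(d)
      cut_edge <-
        (min(pix[, 1]) == 0 && ext[1] > 0) ||
        (max(pix[, 1]) == layout$tile_size - 1 && ext[3] < pw) ||
        (min(pix[, 2]) == 0 && ext[2] > 0) ||
        (max(pix[, 2]) == layout$tile_size - 1 && ext[4] < ph)
      if (cut_edge) next
      d <- shift_instance(d, ext[1] - pad, ext[2] - pad) # back to image coords
      d$tile <- t
      candidates[[length(candidates) + 1L]] <- d
    }
  }
  kept <- dedup_across_tiles(candidates, layout)
  kept <- filter_by_size(kept, min_len, max_len)
  kept <- lapply(seq_along(kept), function(i) {
    inst <- kept[[i]]; inst$id <- i
    if (crops) inst$crop <- crop_instance(image, inst)
    inst
  })
  kept
}

# Image region over the instance bbox, clipped to image bounds.
crop_instance <- function(image, inst) {
  b <- round(inst$bbox)
  x0 <- max(0, b[1]); y0 <- max(0, b[2])
  x1 <- min(nrow(image), b[3]); y1 <- min(ncol(image), b[4])
  if (x1 <= x0 || y1 <= y0) return(matrix(0, 1, 1))
  image[(x0 + 1):x1, (y0 + 1):y1, drop = FALSE]
}

#' Deduplicate candidate instances across overlapping tiles
#'
#' Tiles are processed in fixed row-major order; a candidate B is kept if
#' and only if its Jaccard index with every already-valid instance from
#' neighbouring tiles (tiles whose extents intersect B's tile) is < 0.5.
#' Idempotent: a second application changes nothing.
#'
#' @param candidates instances carrying a `$tile` field, all in common image
#'   coordinates.
#' @param layout the [plan_tiles()] layout that produced them.
#' @return The kept instances.
#' @export
dedup_across_tiles <- function(candidates, layout) {
  if (length(candidates) == 0L) return(list())
  tiles <- vapply(candidates, function(d) d$tile, numeric(1))
  ord <- order(tiles,
               -vapply(candidates, function(d) d$score, numeric(1)),
               vapply(candidates, function(d) d$centroid[1], numeric(1)),
               vapply(candidates, function(d) d$centroid[2], numeric(1)))
  valid <- list()
  for (i in ord) {
    b <- candidates[[i]]
    b_ext <- tile_extent(layout, b$tile)
    dup <- FALSE
    for (a in valid) {
      if (a$tile == b$tile) next
      if (!boxes_intersect(tile_extent(layout, a$tile), b_ext)) next
      if (!boxes_intersect(a$bbox, b$bbox)) next
      if (jaccard_index(a, b) >= 0.5) { dup <- TRUE; break }
    }
    if (!dup) valid[[length(valid) + 1L]] <- b
  }
  valid
}

#' Filter instances by object length
#'
#' Keeps an instance iff its longest bounding-box side lies in
#' \[`min_len`, `max_len`\] px (both bounds inclusive: the defaults discard
#' objects smaller than 30 px or wider than 600 px). The numbers of
#' discarded small/large objects are attached as the `"discarded"`
#' attribute.
#'
#' @param instances list of instances.
#' @param min_len,max_len inclusive bounds in px.
#' @return Filtered list with attribute `discarded = c(small =, large =)`.
#' @export
filter_by_size <- function(instances, min_len = 30, max_len = 600) {
  if (length(instances) == 0L)
    return(structure(list(), discarded = c(small = 0L, large = 0L)))
  sides <- vapply(instances, instance_max_side, numeric(1))
  keep <- sides >= min_len & sides <= max_len
  structure(instances[keep],
            discarded = c(small = sum(sides < min_len),
                          large = sum(sides > max_len)))
}

# IoU on masks; same as Jaccard but exposed under the evaluation name.
instance_iou <- function(a, b) {
  if (!boxes_intersect(a$bbox, b$bbox)) return(0)
  jaccard_index(a, b)
}

#' Evaluate detections against ground truth
#'
#' One-to-one greedy matching by descending IoU (>= `match_iou`);
#' precision = matched / predicted, recall = matched / truth, plus recall
#' binned by truth mask area.
#'
#' @param predicted,truth lists of instances in the same frame coordinates.
#' @param match_iou IoU threshold counting a prediction as correct.
#' @param size_breaks area bin edges (px^2) for the recall-by-size table.
#' @return List: `precision`, `recall`, `n_matched`, `n_predicted`,
#'   `n_truth`, `by_size` (data.frame bin, n_truth, n_matched, recall),
#'   `matches` (data.frame pred, truth, iou).
#' @export
evaluate_detection <- function(predicted, truth, match_iou = 0.5,
                               size_breaks = c(0, 1000, 4000, Inf)) {
  np <- length(predicted); nt <- length(truth)
  if (np == 0L && nt == 0L) {
    message("empty truth and prediction sets: precision = recall = 1 by convention")
    return(list(precision = 1, recall = 1, n_matched = 0L, n_predicted = 0L,
                n_truth = 0L, by_size = NULL,
                matches = data.frame(pred = integer(), truth = integer(),
                                     iou = numeric())))
  }
  pairs <- list()
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    iou <- instance_iou(predicted[[i]], truth[[j]])
    if (iou >= match_iou) pairs[[length(pairs) + 1L]] <- c(i, j, iou)
  }
  matches <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, 3], pm[, 1], pm[, 2]), , drop = FALSE]
    used_p <- logical(np); used_t <- logical(nt)
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1]; j <- pm[r, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
        matches <- rbind(matches, data.frame(pred = i, truth = j,
                                             iou = pm[r, 3]))
      }
    }
  }
  m <- nrow(matches)
  areas <- vapply(truth, function(x) x$area, numeric(1))
  bin <- cut(areas, size_breaks, include.lowest = TRUE)
  matched_t <- seq_len(nt) %in% matches$truth
  by_size <- do.call(rbind, lapply(levels(bin), function(lv) {
    sel <- !is.na(bin) & bin == lv
    data.frame(bin = lv, n_truth = sum(sel), n_matched = sum(matched_t[sel]),
               recall = if (sum(sel)) sum(matched_t[sel]) / sum(sel) else NA_real_)
  }))
  list(precision = if (np) m / np else 1,
       recall = if (nt) m / nt else 1,
       n_matched = m, n_predicted = np, n_truth = nt,
       by_size = by_size, matches = matches)
}

#' Detect all frames of a synthetic or loaded series
#'
#' @param series a `synthetic_series` (or any list with `frames` and
#'   `times`).
#' @param ... passed to [detect_frame()].
#' @return List (one element per frame) of instance lists; instances carry
#'   `frame_id` and `time`.
#' @export
detect_series <- function(series, ...) {
  lapply(seq_along(series$frames), function(f) {
    dets <- detect_frame(series$frames[[f]], ...)
    lapply(dets, function(d) {
      d$frame_id <- as.integer(f)
      d$time <- series$times[f]
      d
    })
  })
}
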