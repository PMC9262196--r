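# Three-pass tracking: build a directed graph over detections (edges run
# earlier -> later, every vertex has in/out degree <= 1), then read tuboids
# off the weakly connected components.
#   pass 1  link instances in contiguous frames (greedy by score, k >= 0.5)
#   pass 2  bridge gaps: tuboid tails to heads starting > 1 frame and
#           < 12 h later, always connecting the highest-scoring pair first
#   pass 3  merge conjoint tuboids (time-interleaved, no coincident frames)
#           when their neighbour-pair mean score clears k = 0.25
# followed by pruning of components with fewer than 4 vertices.

#' Tracker configuration
#'
#' @param k_link score threshold for pass-1 linking and pass-2 bridging.
#' @param k_merge threshold on the average neighbour score for pass-3
#'   merging; must satisfy 0 < k_merge <= k_link < 1.
#' @param max_gap_h maximum bridgeable time gap in hours.
#' @param min_vertices minimum component size kept by [extract_tuboids()].
#' @return List of class `"tracker_config"`.
#' @export
tracker_config <- function(k_link = 0.5, k_merge = 0.25, max_gap_h = 12,
                           min_vertices = 4) {
  if (!(k_merge > 0 && k_merge <= k_link && k_link < 1))
    stop("need 0 < k_merge <= k_link < 1", call. = FALSE)
  if (max_gap_h <= 0) stop("max_gap_h must be > 0", call. = FALSE)
  structure(list(k_link = k_link, k_merge = k_merge, max_gap_h = max_gap_h,
                 min_vertices = min_vertices), class = "tracker_config")
}

# Internal graph representation: flat vertex list (vid = position) + edge
# data.frame. Vertices are detection instances carrying frame_id and time.
new_tracking_graph <- function(vertices, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(from = integer(), to = integer(), score = numeric())
  structure(list(vertices = vertices, edges = edges),
            class = "tracking_graph")
}

#' @export
print.tracking_graph <- function(x, ...) {
  cat(sprintf("<tracking_graph> %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

graph_out_deg <- function(g) tabulate(g$edges$from, length(g$vertices))
graph_in_deg <- function(g) tabulate(g$edges$to, length(g$vertices))

# Degree and temporal invariants; called after every pass.
assert_graph_invariants <- function(g) {
  stopifnot(all(graph_out_deg(g) <= 1), all(graph_in_deg(g) <= 1))
  if (nrow(g$edges)) {
    tf <- vapply(g$vertices[g$edges$from], function(v) as.numeric(v$time),
                 numeric(1))
    tt <- vapply(g$vertices[g$edges$to], function(v) as.numeric(v$time),
                 numeric(1))
    stopifnot(all(tt > tf))
  }
  invisible(g)
}

# Deterministic pair ordering: descending score, then smaller centroid
# distance, then smaller (from, to) vertex ids.
order_pairs <- function(df) {
  order(-df$score, df$dist, df$from, df$to)
}

#' Pass 1: link instances in contiguous frames
#'
#' For every frame transition, each instance connects to its best match in
#' the next frame when that score clears `k_link`. Two instances may prefer
#' the same target; candidate pairs of a transition are therefore processed
#' in descending score order and accepted only while both endpoints are
#' unused, which honours the argmax rule under the degree constraints.
#'
#' @param frames list of per-frame instance lists, time-ordered; instances
#'   must carry `frame_id` and `time`.
#' @param scorer function `(m, n) -> M in [0, 1]`, e.g. from
#'   [make_series_scorer()].
#' @param cfg a [tracker_config()].
#' @return A `tracking_graph`; vertex ids (`vid`) are attached to the
#'   instances.
#' @export
link_contiguous <- function(frames, scorer, cfg = tracker_config()) {
  times <- vapply(frames, function(fr)
    if (length(fr)) as.numeric(fr[[1]]$time) else NA_real_, numeric(1))
  if (is.unsorted(times, na.rm = TRUE))
    stop("frames must be time-ordered", call. = FALSE)
  vertices <- list(); vid_of <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    vids <- integer(length(frames[[f]]))
    for (k in seq_along(frames[[f]])) {
      inst <- frames[[f]][[k]]
      inst$vid <- length(vertices) + 1L
      vertices[[inst$vid]] <- inst
      vids[k] <- inst$vid
    }
    vid_of[[f]] <- vids
  }
  g <- new_tracking_graph(vertices)
  for (f in seq_len(length(frames) - 1)) {
    ms <- vid_of[[f]]; ns <- vid_of[[f + 1]]
    if (!length(ms) || !length(ns)) next
    cand <- expand.grid(from = ms, to = ns)
    cand$score <- mapply(function(a, b) scorer(vertices[[a]], vertices[[b]]),
                         cand$from, cand$to)
    cand$dist <- mapply(function(a, b)
      sqrt(sum((vertices[[a]]$centroid - vertices[[b]]$centroid)^2)),
      cand$from, cand$to)
    cand <- cand[cand$score >= cfg$k_link, , drop = FALSE]
    used_from <- integer(0); used_to <- integer(0)
    for (r in order_pairs(cand)) {
      if (cand$from[r] %in% used_from || cand$to[r] %in% used_to) next
      g$edges <- rbind(g$edges, data.frame(from = cand$from[r],
                                           to = cand$to[r],
                                           score = cand$score[r]))
      used_from <- c(used_from, cand$from[r])
      used_to <- c(used_to, cand$to[r])
    }
  }
  assert_graph_invariants(g)
}

#' Pass 2: bridge gaps between tuboids
#'
#' Considers pairs (m, n) where m has no outgoing edge (a tuboid tail), n
#' has no incoming edge (a head), the frame gap exceeds 1 and the time gap
#' is below `max_gap_h`. The single highest-scoring admissible pair with
#' score >= `k_link` is connected, admissibility is recomputed, and the
#' procedure restarts until no pair qualifies.
#'
#' @param g a pass-1 `tracking_graph`.
#' @inheritParams link_contiguous
#' @return The augmented graph.
#' @export
bridge_gaps <- function(g, scorer, cfg = tracker_config()) {
  v <- g$vertices
  tv <- vapply(v, function(x) as.numeric(x$time), numeric(1))
  fv <- vapply(v, function(x) x$frame_id, integer(1))
  score_cache <- new.env(parent = emptyenv())
  cached_score <- function(a, b) {
    key <- paste0(a, "_", b)
    s <- score_cache[[key]]
    if (is.null(s)) {
      s <- scorer(v[[a]], v[[b]])
      score_cache[[key]] <- s
    }
    s
  }
  repeat {
    tails <- which(graph_out_deg(g) == 0L)
    heads <- which(graph_in_deg(g) == 0L)
    if (!length(tails) || !length(heads)) break
    cand <- expand.grid(from = tails, to = heads)
    cand <- cand[fv[cand$to] - fv[cand$from] > 1L &
                   (tv[cand$to] - tv[cand$from]) / 3600 < cfg$max_gap_h &
                   tv[cand$to] > tv[cand$from], , drop = FALSE]
    if (!nrow(cand)) break
    cand$score <- mapply(cached_score, cand$from, cand$to)
    cand <- cand[cand$score >= cfg$k_link, , drop = FALSE]
    if (!nrow(cand)) break
    cand$dist <- mapply(function(a, b)
      sqrt(sum((v[[a]]$centroid - v[[b]]$centroid)^2)), cand$from, cand$to)
    best <- cand[order_pairs(cand)[1], ]
    g$edges <- rbind(g$edges, data.frame(from = best$from, to = best$to,
                                         score = best$score))
  }
  assert_graph_invariants(g)
}

# Component membership as a vector over vertices (igraph weak components).
graph_components <- function(g) {
  n <- length(g$vertices)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(ig, mode = "weak")$membership
  as.integer(comp[as.character(seq_len(n))])
}

#' Are two tuboids conjoint?
#'
#' Conjoint tuboids overlap in time but share no coincident frame time: the
#' start of one lies within the other's \[start, end\] interval, and no two
#' vertices have equal times. Such pairs are the pass-3 merge candidates.
#'
#' @param p,q tuboids (or any lists with a `times` field of POSIXct).
#' @return TRUE or FALSE.
#' @export
conjoint <- function(p, q) {
  tp <- as.numeric(p$times); tq <- as.numeric(q$times)
  if (!length(tp) || !length(tq)) stop("empty tuboid", call. = FALSE)
  if (length(intersect(tp, tq)) > 0) return(FALSE)
  (min(tp) >= min(tq) && min(tp) <= max(tq)) ||
    (min(tq) >= min(tp) && min(tq) <= max(tp))
}

# Average matching score between conjoint tuboids over the neighbour-pair
# set K: every vertex paired with its immediate predecessor and successor in
# time from the other tuboid (deduplicated).
conjoint_mean_score <- function(p_vids, q_vids, tv, pair_score) {
  pairs <- matrix(integer(0), ncol = 2)
  add_neighbours <- function(a_vids, b_vids) {
    tb <- tv[b_vids]
    for (a in a_vids) {
      before <- b_vids[tb < tv[a]]
      after <- b_vids[tb > tv[a]]
      if (length(before)) {
        w <- before[which.max(tv[before])]
        pairs <<- rbind(pairs, if (tv[w] < tv[a]) c(w, a) else c(a, w))
      }
      if (length(after)) {
        w <- after[which.min(tv[after])]
        pairs <<- rbind(pairs, if (tv[w] < tv[a]) c(w, a) else c(a, w))
      }
    }
  }
  add_neighbours(p_vids, q_vids)
  add_neighbours(q_vids, p_vids)
  pairs <- unique(pairs)
  scores <- apply(pairs, 1, function(pr) pair_score(pr[1], pr[2]))
  mean(scores)
}

#' Pass 3: merge conjoint tuboids
#'
#' Computes the average score over neighbouring vertex pairs for every
#' conjoint pair of tuboids and iteratively merges the highest-scoring pair
#' with mean score >= `k_merge`, interleaving the vertices by time and
#' re-chaining the edges; newly merged tuboids re-enter the candidate pool
#' until a fixpoint.
#'
#' @inheritParams bridge_gaps
#' @return The merged graph.
#' @export
merge_conjoint <- function(g, scorer, cfg = tracker_config()) {
  v <- g$vertices
  tv <- vapply(v, function(x) as.numeric(x$time), numeric(1))
  score_cache <- new.env(parent = emptyenv())
  pair_score <- function(a, b) {
    key <- paste0(a, "_", b)
    s <- score_cache[[key]]
    if (is.null(s)) {
      s <- scorer(v[[a]], v[[b]])
      score_cache[[key]] <- s
    }
    s
  }
  repeat {
    comp <- graph_components(g)
    comps <- split(seq_along(comp), comp)
    if (length(comps) < 2) break
    info <- lapply(comps, function(vids) list(vids = vids, times = tv[vids]))
    best <- NULL
    ids <- names(comps)
    for (i in seq_along(comps)) for (j in seq_along(comps)) {
      if (j <= i) next
      p <- info[[i]]; q <- info[[j]]
      if (!conjoint(list(times = p$times), list(times = q$times))) next
      mbar <- conjoint_mean_score(p$vids, q$vids, tv, pair_score)
      if (mbar >= cfg$k_merge &&
          (is.null(best) || mbar > best$mbar)) best <- list(
            i = ids[i], j = ids[j], mbar = mbar)
    }
    if (is.null(best)) break
    vids <- sort(c(comps[[best$i]], comps[[best$j]]))
    ord <- vids[order(tv[vids])]
    if (any(duplicated(tv[ord])))
      stop("merge would duplicate a frame time", call. = FALSE)
    # re-chain: drop internal edges of both components, connect consecutively
    keep <- !(g$edges$from %in% vids | g$edges$to %in% vids)
    new_edges <- data.frame(from = ord[-length(ord)], to = ord[-1],
                            score = vapply(seq_len(length(ord) - 1),
                                           function(k) pair_score(ord[k], ord[k + 1]),
                                           numeric(1)))
    g$edges <- rbind(g$edges[keep, , drop = FALSE], new_edges)
  }
  assert_graph_invariants(g)
}

#' Extract tuboids from a tracking graph
#'
#' Weakly connected components become tuboids; components with fewer than
#' `cfg$min_vertices` instances are dropped. Tuboids are ordered by first
#' timestamp, then smallest vertex id, and instances within a tuboid by
#' time.
#'
#' @inheritParams bridge_gaps
#' @param g a `tracking_graph` after the passes you want applied.
#' @return List of `"tuboid"` objects: `id`, `instances`, `times`, `frames`,
#'   `start`, `end`.
#' @export
extract_tuboids <- function(g, cfg = tracker_config()) {
  if (length(g$vertices) == 0L) return(list())
  comp <- graph_components(g)
  tv <- vapply(g$vertices, function(x) as.numeric(x$time), numeric(1))
  comps <- split(seq_along(comp), comp)
  comps <- Filter(function(vids) length(vids) >= cfg$min_vertices, comps)
  if (!length(comps)) return(list())
  first_t <- vapply(comps, function(vids) min(tv[vids]), numeric(1))
  first_v <- vapply(comps, function(vids) min(vids), numeric(1))
  comps <- comps[order(first_t, first_v)]
  out <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    vids <- comps[[i]][order(tv[comps[[i]]])]
    if (any(duplicated(tv[vids])))
      stop("tuboid has coincident frame times", call. = FALSE)
    insts <- g$vertices[vids]
    out[[i]] <- structure(
      list(id = i, instances = insts,
           times = as.POSIXct(tv[vids], origin = "1970-01-01", tz = "UTC"),
           frames = vapply(insts, function(x) x$frame_id, integer(1)),
           start = min(tv[vids]), end = max(tv[vids])),
      class = "tuboid")
  }
  out
}

#' @export
print.tuboid <- function(x, ...) {
  cat(sprintf("<tuboid %d> %d instances, frames %d-%d\n", x$id,
              length(x$instances), min(x$frames), max(x$frames)))
  invisible(x)
}

#' Run all three tracking passes
#'
#' Convenience wrapper: [link_contiguous()], [bridge_gaps()],
#' [merge_conjoint()], [extract_tuboids()].
#'
#' @inheritParams link_contiguous
#' @return List of tuboids.
#' @export
track_series <- function(frames, scorer, cfg = tracker_config()) {
  g <- link_contiguous(frames, scorer, cfg)
  g <- bridge_gaps(g, scorer, cfg)
  g <- merge_conjoint(g, scorer, cfg)
  extract_tuboids(g, cfg)
}

#' Identity-preservation metrics against ground truth
#'
#' Requires instances to carry `truth_id` (synthetic data). Purity is the
#' per-tuboid majority-truth fraction (weighted mean over tuboids by size);
#' completeness is, per truth track, the fraction of its detected instances
#' contained in the largest single tuboid (mean over tracks). An ID switch
#' is a change of truth id between consecutive instances of a tuboid.
#'
#' @param tuboids list from [extract_tuboids()].
#' @return List: `purity`, `completeness`, `id_switches`, `n_splits`
#'   (truth tracks spread over > 1 tuboid), `n_merges` (tuboids containing
#'   > 1 truth id), `per_tuboid`, `per_truth` data.frames.
#' @export
evaluate_tracking <- function(tuboids) {
  if (!length(tuboids))
    return(list(purity = NA_real_, completeness = NA_real_,
                id_switches = 0L, n_splits = 0L, n_merges = 0L,
                per_tuboid = NULL, per_truth = NULL))
  truth_ids <- function(tb) {
    ids <- vapply(tb$instances, function(x) as.character(x$truth_id),
                  character(1))
    ids[is.na(ids)] <- "<unmatched>"
    ids
  }
  per_tuboid <- do.call(rbind, lapply(tuboids, function(tb) {
    ids <- truth_ids(tb)
    tab <- table(ids)
    data.frame(tuboid = tb$id, n = length(ids),
               majority = names(tab)[which.max(tab)],
               purity = max(tab) / length(ids),
               n_truth_ids = length(tab),
               switches = sum(ids[-1] != ids[-length(ids)]),
               stringsAsFactors = FALSE)
  }))
  counts <- list()
  for (tb in tuboids) {
    ids <- truth_ids(tb)
    for (tid in unique(ids))
      counts[[tid]] <- c(counts[[tid]], sum(ids == tid))
  }
  counts <- counts[names(counts) != "<unmatched>"]
  per_truth <- do.call(rbind, lapply(names(counts), function(tid) {
    n <- sum(counts[[tid]])
    data.frame(truth_id = tid, n_instances = n,
               n_tuboids = length(counts[[tid]]),
               completeness = max(counts[[tid]]) / n,
               stringsAsFactors = FALSE)
  }))
  list(purity = sum(per_tuboid$purity * per_tuboid$n) / sum(per_tuboid$n),
       completeness = if (is.null(per_truth)) NA_real_ else
         mean(per_truth$completeness),
       id_switches = sum(per_tuboid$switches),
       n_splits = sum(per_truth$n_tuboids > 1),
       n_merges = sum(per_tuboid$n_truth_ids > 1),
       per_tuboid = per_tuboid, per_truth = per_truth)
}
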