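# Independent reference for the pass-1 assignment: instead of the package's
# single descending-score sweep, recursively extract the global argmax pair
# from an explicit enumeration of degree-feasible candidate pairs, remove
# the two endpoints, and recurse. Ties broken as documented (smaller
# centroid distance, then smaller ids).

oracle_link_transition <- function(ms, ns, scorer, k) {
  cand <- list()
  for (m in ms) for (n in ns) {
    s <- scorer(m, n)
    if (s >= k)
      cand[[length(cand) + 1L]] <- list(
        from = m$id, to = n$id, score = s,
        dist = sqrt(sum((m$centroid - n$centroid)^2)))
  }
  edges <- data.frame(from = integer(), to = integer(), score = numeric())
  repeat {
    if (length(cand) == 0) break
    sc <- vapply(cand, `[[`, numeric(1), "score")
    dd <- vapply(cand, `[[`, numeric(1), "dist")
    ff <- vapply(cand, `[[`, numeric(1), "from")
    tt <- vapply(cand, `[[`, numeric(1), "to")
    best <- order(-sc, dd, ff, tt)[1]
    b <- cand[[best]]
    edges <- rbind(edges, data.frame(from = b$from, to = b$to,
                                     score = b$score))
    cand <- Filter(function(p) p$from != b$from && p$to != b$to, cand)
  }
  edges[order(edges$from), , drop = FALSE]
}

# Enumerate every degree-feasible matching between two vertex sets (used to
# confirm the reference itself returns a feasible matching).
all_feasible_matchings <- function(from_ids, to_ids) {
  if (length(from_ids) == 0) return(list(data.frame(from = integer(),
                                                    to = integer())))
  rest <- all_feasible_matchings(from_ids[-1], to_ids)
  out <- rest # first vertex unmatched
  for (n in to_ids) {
    sub <- all_feasible_matchings(from_ids[-1], setdiff(to_ids, n))
    out <- c(out, lapply(sub, function(m)
      rbind(data.frame(from = from_ids[1], to = n), m)))
  }
  out
}
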