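# Temporal-niche ordination: dissimilarity between diel activity profiles,
# classical MDS, bootstrap point clouds aligned by Procrustes, and
# bivariate-t confidence ellipses.

#' Dissimilarity between diel profiles
#'
#' Pairwise Pearson correlation r of the hourly profiles, mapped to a
#' distance. The default map `d = sqrt((1 - r) / 2)` sends r = 1 to 0 and
#' r = -1 (perfect anti-phase) to 1 and is a proper metric on profile
#' space; `method = "linear"` uses d = (1 - r) / 2 instead.
#'
#' @param profiles matrix, one row per taxon, columns = hourly bins.
#' @param method `"sqrt"` (default) or `"linear"`.
#' @return A symmetric `dist`-convertible matrix with zero diagonal, values
#'   in \[0, 1\]. Zero-variance rows are an error (flag and drop them
#'   first).
#' @export
profile_distance <- function(profiles, method = c("sqrt", "linear")) {
  method <- match.arg(method)
  sds <- apply(profiles, 1, sd)
  if (any(sds == 0))
    stop("constant profile(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "), call. = FALSE)
  r <- cor(t(profiles))
  d <- if (method == "sqrt") sqrt(pmax(1 - r, 0) / 2) else (1 - r) / 2
  diag(d) <- 0
  d
}

# Hourly count profile per taxon from WZT event hours.
hourly_profiles <- function(wzt_h, taxon) {
  taxa <- sort(unique(as.character(taxon)))
  m <- t(vapply(taxa, function(tx)
    tabulate(floor(wzt_h[taxon == tx] %% 24) + 1, 24), numeric(24)))
  rownames(m) <- taxa
  m
}

# 2-D classical MDS with padding when the solution collapses.
mds_2d <- function(d) {
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = 2))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  xy
}

#' Bootstrap MDS of temporal niches
#'
#' Computes the taxon-by-taxon profile dissimilarity and a 2-D metric MDS
#' embedding; uncertainty comes from resampling the capture instances with
#' replacement independently for each taxon, recomputing one distance
#' matrix and one MDS per replicate, and aligning every replicate solution
#' to the point estimate by orthogonal Procrustes
#' (rotation/reflection/translation) before pooling. Per taxon, a 95%
#' confidence ellipse is fit to the pooled replicate cloud assuming a
#' bivariate t-distribution.
#'
#' @param wzt_h event times as WZT hours in \[0, 24).
#' @param taxon taxon label per event; at least 3 taxa with non-constant
#'   profiles are required. Constant-profile taxa are dropped with a
#'   warning.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param method distance map, see [profile_distance()].
#' @param level ellipse confidence level.
#' @return Object of class `"niche_mds"`: `points` (data.frame taxon, x,
#'   y), `boot` (data.frame rep, taxon, x, y), `ellipses` (named list:
#'   `center`, `cov`, `radius`, `polygon`), `distance` (point-estimate
#'   matrix), `dropped` (taxa excluded).
#' @export
niche_mds <- function(wzt_h, taxon, n_boot = 500, seed = 1L,
                      method = c("sqrt", "linear"), level = 0.95) {
  method <- match.arg(method)
  taxon <- as.character(taxon)
  prof <- hourly_profiles(wzt_h, taxon)
  sds <- apply(prof, 1, sd)
  dropped <- rownames(prof)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant-profile taxa: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep_ev <- !(taxon %in% dropped)
    wzt_h <- wzt_h[keep_ev]; taxon <- taxon[keep_ev]
    prof <- prof[sds > 0, , drop = FALSE]
  }
  taxa <- rownames(prof)
  if (length(taxa) < 3) stop("need >= 3 taxa", call. = FALSE)
  d0 <- profile_distance(prof, method)
  xy0 <- mds_2d(d0)
  rownames(xy0) <- taxa
  set.seed(seed)
  idx_by_taxon <- split(seq_along(wzt_h), taxon)
  boot <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    res_h <- unlist(lapply(idx_by_taxon, function(ix)
      wzt_h[sample(ix, length(ix), replace = TRUE)]), use.names = FALSE)
    res_tx <- rep(names(idx_by_taxon),
                  vapply(idx_by_taxon, length, integer(1)))
    pb <- hourly_profiles(res_h, res_tx)
    sdb <- apply(pb, 1, sd)
    if (any(sdb == 0)) next # degenerate resample; skip
    xyb <- mds_2d(profile_distance(pb, method))
    al <- vegan::procrustes(xy0[rownames(pb), , drop = FALSE], xyb,
                            symmetric = FALSE)
    boot[[b]] <- data.frame(rep = b, taxon = rownames(pb),
                            x = al$Yrot[, 1], y = al$Yrot[, 2],
                            stringsAsFactors = FALSE)
  }
  boot <- do.call(rbind, boot)
  ellipses <- lapply(taxa, function(tx) {
    pts <- as.matrix(boot[boot$taxon == tx, c("x", "y")])
    n <- nrow(pts)
    if (n < 8) return(NULL)
    fit <- MASS::cov.trob(pts)
    radius <- sqrt(2 * qf(level, 2, n - 2))
    ang <- seq(0, 2 * pi, length.out = 101)
    circ <- cbind(cos(ang), sin(ang))
    ch <- chol(fit$cov)
    poly <- t(fit$center + t(circ %*% ch) * radius)
    list(center = fit$center, cov = fit$cov, radius = radius,
         polygon = poly)
  })
  names(ellipses) <- taxa
  structure(list(
    points = data.frame(taxon = taxa, x = xy0[, 1], y = xy0[, 2],
                        stringsAsFactors = FALSE, row.names = NULL),
    boot = boot, ellipses = ellipses, distance = d0, dropped = dropped),
    class = "niche_mds")
}

# Mahalanobis membership of points in a fitted ellipse.
in_ellipse <- function(pts, ell) {
  z <- sweep(pts, 2, ell$center)
  q <- rowSums((z %*% solve(ell$cov)) * z)
  q <= ell$radius^2
}

#' Do two confidence ellipses overlap?
#'
#' Approximate test: any boundary vertex or the centre of one ellipse lying
#' inside the other counts as overlap.
#'
#' @param e1,e2 elements of `niche_mds()$ellipses`.
#' @return TRUE/FALSE (NA when either ellipse is missing).
#' @export
ellipses_overlap <- function(e1, e2) {
  if (is.null(e1) || is.null(e2)) return(NA)
  any(in_ellipse(rbind(e1$polygon, e1$center), e2)) ||
    any(in_ellipse(rbind(e2$polygon, e2$center), e1))
}

#' Mean silhouette of a grouping on an MDS embedding
#'
#' Small helper for separation checks: silhouette width of each taxon point
#' under a given group labelling, computed on Euclidean distances in the
#' embedding. Positive mean silhouette means the groups separate.
#'
#' @param points `niche_mds()$points`.
#' @param groups named vector mapping taxon -> group.
#' @return Mean silhouette width.
#' @export
mds_silhouette <- function(points, groups) {
  g <- groups[points$taxon]
  xy <- as.matrix(points[, c("x", "y")])
  dmat <- as.matrix(stats::dist(xy))
  s <- vapply(seq_len(nrow(xy)), function(i) {
    own <- which(g == g[i] & seq_along(g) != i)
    oth <- split(which(g != g[i]), g[g != g[i]])
    if (!length(own) || !length(oth)) return(0)
    a <- mean(dmat[i, own])
    b <- min(vapply(oth, function(ix) mean(dmat[i, ix]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
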