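# Base-graphics views of the two headline outputs.

#' Plot a diel activity profile
#'
#' Mean capture rate per WZT hour with standard-error bars; sunrise (WZT 0)
#' and sunset (WZT 12) delimit the shaded night.
#'
#' @param profile a [diel_profile()].
#' @param main plot title.
#' @export
plot_diel_profile <- function(profile, main = "Diel activity") {
  up <- profile$mean + profile$se
  plot(profile$bin + 0.5, profile$mean, type = "n", xlim = c(0, 24),
       ylim = c(0, max(up) * 1.05 + 1e-9), xaxt = "n",
       xlab = "Warped Zeitgeber time (h)", ylab = "capture rate (h^-1)",
       main = main)
  graphics::rect(12, -1, 24, max(up) * 2 + 1, col = gray(0.92),
                 border = NA)
  axis(1, at = seq(0, 24, 6))
  graphics::segments(profile$bin + 0.5, profile$mean - profile$se,
                     profile$bin + 0.5, up)
  lines(profile$bin + 0.5, profile$mean, type = "b", pch = 16)
  invisible(profile)
}

#' Plot a temporal-niche MDS map
#'
#' Bootstrap clouds, 95% ellipses and taxon labels on the 2-D embedding.
#'
#' @param x a [niche_mds()] result.
#' @param main plot title.
#' @export
plot_niche_mds <- function(x, main = "Temporal niches (MDS)") {
  rng <- range(c(x$boot$x, x$boot$y, x$points$x, x$points$y))
  plot(NA, xlim = rng, ylim = rng, xlab = "dimension 1",
       ylab = "dimension 2", main = main, asp = 1)
  cols <- seq_along(unique(x$boot$taxon))
  names(cols) <- unique(x$boot$taxon)
  points(x$boot$x, x$boot$y, pch = ".", col = cols[x$boot$taxon])
  for (tx in names(x$ellipses)) {
    e <- x$ellipses[[tx]]
    if (!is.null(e)) polygon(e$polygon, border = cols[tx])
  }
  graphics::text(x$points$x, x$points$y, x$points$taxon, cex = 0.8)
  invisible(x)
}
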