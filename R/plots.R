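# Base-graphics figures following the study's display conventions:
# solid = entropy, dashed = mutual information; STM heatmaps with a
# marginal histogram on top (log colour scale for large state spaces);
# rasters with time horizontal and neuron index vertical.

#' Plot entropy / mutual information noise-scan curves
#'
#' @param scan a `scan_result`.
#' @param observables which observables to draw (default every entropy as a
#'   solid line, every MI as a dashed line).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted means.
#' @export
plot_scan <- function(scan, observables = NULL, ...) {
  s <- scan$summary
  observables <- observables %||% unique(s$observable)
  m <- sapply(observables, function(o) s$mean[s$observable == o])
  r <- sort(unique(s$r))
  lty <- ifelse(grepl("^H", observables), 1, 2)
  graphics::matplot(r, m, type = "b", pch = 20, lty = lty,
                    xlab = "noise strength r", ylab = "bits",
                    main = sprintf("%s, W=%g", scan$condition, scan$W), ...)
  graphics::legend("topleft", legend = observables, lty = lty,
                   col = seq_along(observables), bty = "n", cex = 0.8)
  invisible(m)
}

#' Heatmap of a state transition matrix with marginal histogram
#'
#' Current state on the horizontal axis, subsequent state on the vertical
#' axis (descending, so the main diagonal runs from top-left). With
#' `log = TRUE` the colour scale is logarithmic with a pseudo-probability
#' floor applied for colour mapping only, never to the statistics.
#'
#' @param model a `transition_model`.
#' @param log logarithmic colour scale (recommended for m = 10).
#' @param floor colour floor used under `log`.
#' @return invisibly, `NULL`.
#' @export
plot_stm <- function(model, log = FALSE, floor = 1e-6) {
  K <- length(model$marginal)
  z <- model$stm
  if (log) z <- log10(pmax(z, floor))
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::layout(matrix(1:2, 2, 1), heights = c(1, 3))
  graphics::par(mar = c(0.5, 4, 2, 1))
  graphics::barplot(model$marginal, border = NA, space = 0,
                    ylab = "P(x)", main = sprintf("STM, m = %d", model$m))
  graphics::par(mar = c(4, 4, 0.5, 1))
  graphics::image(x = 0:(K - 1), y = 0:(K - 1), z = z[, K:1],
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  xlab = "state at t", ylab = "state at t+1", yaxt = "n")
  at <- pretty(c(0, K - 1))
  at <- at[at >= 0 & at <= K - 1]
  graphics::axis(2, at = at, labels = K - 1 - at)
  invisible(NULL)
}

#' Spatiotemporal raster of binary activity
#'
#' Time on the horizontal axis, neuron index on the vertical axis; active
#' (1) cells drawn dark.
#'
#' @param traj a `trajectory` or binary matrix.
#' @param interval subsampling interval passed to [raster()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot_raster <- function(traj, interval = 1, ...) {
  b <- raster(traj, interval)
  graphics::image(x = seq_len(nrow(b)), y = seq_len(ncol(b)), z = b,
                  col = c("white", "black"), xlab = "time step",
                  ylab = "neuron", ...)
  invisible(b)
}

#' Attractor classification scatter
#'
#' Diagonal stability against visitation gain (log scale), coloured by
#' class, with the theoretical noise floor (G = 1) and the empirical
#' baseline stability drawn as guide lines.
#'
#' @param classification output of [classify_attractors()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_classification <- function(classification, ...) {
  th <- attr(classification, "thresholds")
  cols <- c(strong = "red3", weak = "blue3", transient = "green4")
  g <- pmax(classification$G, 1e-3)
  graphics::plot(g, classification$Txx, log = "x",
                 col = cols[classification$label], pch = 20,
                 xlab = "gain G(x)", ylab = "stability Txx", ...)
  graphics::abline(v = th[["g_transient"]], lty = 3, col = "grey40")
  graphics::abline(h = th[["baseline"]], lty = 2, col = "grey40")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 20,
                   bty = "n", cex = 0.8)
  invisible(NULL)
}

#' Render a named figure from a protocol bundle
#'
#' Thin orchestration over the plot functions: `"scan_curves"` (one panel
#' per scan), `"stm_panel"` (transition matrix of the representative
#' trial), `"raster_panels"` (fine and coarse rasters), `"te_comparison"`
#' (mean +/- SD transfer-entropy curves per condition),
#' `"classification_map"` (attractor scatter). Writes a PNG when `file` is
#' given, otherwise draws on the current device.
#'
#' @param name figure name.
#' @param bundle a `protocol_bundle` from [run_protocol()].
#' @param file optional PNG path.
#' @return invisibly, `file` (or `NULL`).
#' @export
replicate_figure <- function(name = c("scan_curves", "stm_panel",
                                      "raster_panels", "te_comparison",
                                      "classification_map"),
                             bundle, file = NULL) {
  name <- match.arg(name)
  if (!length(bundle$scans)) stop("bundle has no scan results")
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900, res = 120)
    on.exit(grDevices::dev.off())
  }
  switch(name,
    scan_curves = {
      k <- length(bundle$scans)
      op <- graphics::par(mfrow = grDevices::n2mfrow(k))
      on.exit(graphics::par(op), add = TRUE)
      for (s in bundle$scans) plot_scan(s, c("H_global", "MI_global"))
    },
    stm_panel = {
      if (is.null(bundle$stm)) stop("bundle has no transition model")
      plot_stm(bundle$stm, log = bundle$stm$m >= 10)
    },
    raster_panels = {
      if (is.null(bundle$raster_fine)) stop("bundle has no rasters")
      op <- graphics::par(mfrow = c(2, 1))
      on.exit(graphics::par(op), add = TRUE)
      plot_raster(bundle$raster_fine, main = "fine (interval 1)")
      plot_raster(bundle$raster_coarse, main = "coarse (interval 200)")
    },
    te_comparison = {
      obs <- grep("^TE_", unique(bundle$scans[[1]]$summary$observable),
                  value = TRUE)[1]
      if (is.na(obs)) stop("bundle has no transfer-entropy observable")
      r <- bundle$scans[[1]]$grid
      means <- sapply(bundle$scans, function(s) {
        s$summary$mean[s$summary$observable == obs]
      })
      sds <- sapply(bundle$scans, function(s) {
        s$summary$sd[s$summary$observable == obs]
      })
      graphics::matplot(r, means, type = "b", pch = 20, lty = 1,
                        xlab = "noise strength r", ylab = paste(obs, "(bits)"))
      for (k in seq_len(ncol(means))) {
        graphics::polygon(c(r, rev(r)),
                          c(means[, k] + sds[, k], rev(means[, k] - sds[, k])),
                          border = NA,
                          col = grDevices::adjustcolor(k, alpha.f = 0.15))
      }
      graphics::legend("topright", legend = colnames(means),
                       col = seq_len(ncol(means)), lty = 1, bty = "n",
                       cex = 0.8)
    },
    classification_map = {
      if (is.null(bundle$classification)) stop("bundle has no classification")
      plot_classification(bundle$classification)
    }
  )
  invisible(file)
}
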