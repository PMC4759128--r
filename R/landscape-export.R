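#' @include synthetic.R
NULL

.deltaPalette <- function(n = 101) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n)
}

#' Plot an interaction landscape
#'
#' `plotLandscape()` draws the delta surface of a combination block as a
#' 2-D heatmap (red = synergy, blue = antagonism, symmetric around 0);
#' `plotLandscape3D()` draws the same surface in perspective. Delta is
#' shown as percent inhibition beyond the zero-interaction expectation.
#'
#' @param landscape an [InteractionLandscape-class].
#' @param main plot title; defaults to the block and summary delta.
#' @param theta,phi viewing angles of the 3-D perspective plot.
#' @return invisibly, the plotted percent-delta matrix.
#' @export
plotLandscape <- function(landscape, main = NULL) {
  stopifnot(is(landscape, "InteractionLandscape"))
  d <- 100 * landscape@delta
  lim <- max(abs(d), 5)
  if (is.null(main))
    main <- sprintf("%s x %s  (mean delta = %.1f%%)", landscape@drugRow,
                    landscape@drugCol, 100 * landscape@summaryDelta)
  nR <- nrow(d); nC <- ncol(d)
  graphics::image(seq_len(nR), seq_len(nC), d, zlim = c(-lim, lim),
                  col = .deltaPalette(), axes = FALSE, main = main,
                  xlab = landscape@drugRow, ylab = landscape@drugCol)
  graphics::axis(1, at = seq_len(nR),
                 labels = format(landscape@concRow, digits = 3))
  graphics::axis(2, at = seq_len(nC),
                 labels = format(landscape@concCol, digits = 3))
  graphics::box()
  invisible(d)
}

#' @rdname plotLandscape
#' @export
plotLandscape3D <- function(landscape, main = NULL, theta = 35, phi = 25) {
  stopifnot(is(landscape, "InteractionLandscape"))
  d <- 100 * landscape@delta
  lim <- max(abs(d), 5)
  if (is.null(main))
    main <- sprintf("%s x %s", landscape@drugRow, landscape@drugCol)
  pal <- .deltaPalette()
  facet <- (d[-1, -1] + d[-1, -ncol(d)] + d[-nrow(d), -1] +
              d[-nrow(d), -ncol(d)]) / 4
  col <- pal[pmin(pmax(round((facet + lim) / (2 * lim) * 100) + 1, 1), 101)]
  graphics::persp(seq_len(nrow(d)), seq_len(ncol(d)), d,
                  zlim = c(-lim, lim), col = col, theta = theta, phi = phi,
                  ticktype = "detailed", xlab = landscape@drugRow,
                  ylab = landscape@drugCol, zlab = "delta (% inhibition)",
                  main = main)
  invisible(d)
}

#' Export an interaction landscape to files
#'
#' Writes the canonical artifacts of a delta landscape into a directory:
#'
#' * `delta_<block>.csv` — the delta grid in percent inhibition beyond
#'   expectation, with concentration headers and `#` metadata lines
#'   (block, drugs, summary delta);
#' * `landscape2d_<block>.png` — the 2-D heatmap;
#' * `landscape3d_<block>.png` — the 3-D perspective surface.
#'
#' The CSV is the canonical artifact; re-reading it reproduces the delta
#' values exactly. Images are convenience outputs and can be switched off.
#'
#' @param landscape an [InteractionLandscape-class].
#' @param outDir output directory (created if missing).
#' @param images write the PNG images as well as the CSV.
#' @return character vector of the files written, invisibly.
#' @export
exportLandscape <- function(landscape, outDir, images = TRUE) {
  stopifnot(is(landscape, "InteractionLandscape"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outDir))
  safe <- gsub("[^A-Za-z0-9._-]", "_", landscape@blockId)
  csv <- file.path(outDir, sprintf("delta_%s.csv", safe))
  con <- file(csv, "w")
  writeLines(c(sprintf("# block_id: %s", landscape@blockId),
               sprintf("# drug_row: %s", landscape@drugRow),
               sprintf("# drug_col: %s", landscape@drugCol),
               "# units: percent inhibition beyond expectation",
               sprintf("# summary_delta_percent: %.6f",
                       100 * landscape@summaryDelta)), con)
  writeLines(paste(c("conc", format(landscape@concCol, digits = 15,
                                    trim = TRUE)), collapse = ","), con)
  d <- 100 * landscape@delta
  for (i in seq_along(landscape@concRow))
    writeLines(paste(c(format(landscape@concRow[i], digits = 15, trim = TRUE),
                       format(d[i, ], digits = 15, trim = TRUE)),
                     collapse = ","), con)
  close(con)
  files <- csv
  if (images) {
    png2 <- file.path(outDir, sprintf("landscape2d_%s.png", safe))
    grDevices::png(png2, width = 720, height = 640)
    plotLandscape(landscape)
    grDevices::dev.off()
    png3 <- file.path(outDir, sprintf("landscape3d_%s.png", safe))
    grDevices::png(png3, width = 720, height = 640)
    plotLandscape3D(landscape)
    grDevices::dev.off()
    files <- c(files, png2, png3)
  }
  invisible(files)
}
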