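#' Bivariate angle-by-velocity occurrence grid
#'
#' Builds the 2D histogram used to examine at which angular position a given
#' angular velocity mainly occurs. Default edges cover 30-180 deg in 2.5 deg
#' bins and -200 to +200 deg/s in 5 deg/s bins (the bin widths are tunable;
#' they echo the visual granularity of typical density panels). Out-of-range
#' samples are clipped into the edge bins and counted in a clip report, so
#' total counts always equal the number of input samples.
#'
#' @param angle,velocity paired samples (deg, deg/s), equal length.
#' @param angle_edges,velocity_edges ascending bin-edge vectors.
#' @param leg,discipline optional labels stored on the grid.
#' @return List of class `ski_density`: `angle_edges`, `velocity_edges`,
#'   `counts` (angle bins x velocity bins), `clipped` (named count),
#'   `normalized` flag, `leg`, `discipline`.
#' @export
density_grid <- function(angle, velocity,
                         angle_edges = seq(30, 180, by = 2.5),
                         velocity_edges = seq(-200, 200, by = 5),
                         leg = NA_character_, discipline = NA_character_) {
  angle <- ts_values(angle); velocity <- ts_values(velocity)
  stopifnot(length(angle) == length(velocity))
  keep <- !is.na(angle) & !is.na(velocity)
  angle <- angle[keep]; velocity <- velocity[keep]
  if (!length(angle)) stop("no samples to histogram")
  if (is.unsorted(angle_edges, strictly = TRUE) ||
      is.unsorted(velocity_edges, strictly = TRUE))
    stop("bin edges must be strictly ascending")
  na <- length(angle_edges) - 1
  nv <- length(velocity_edges) - 1
  clipped <- c(angle = sum(angle < angle_edges[1] | angle > angle_edges[na + 1]),
               velocity = sum(velocity < velocity_edges[1] |
                                velocity > velocity_edges[nv + 1]))
  ia <- pmin(pmax(findInterval(angle, angle_edges, rightmost.closed = TRUE), 1), na)
  iv <- pmin(pmax(findInterval(velocity, velocity_edges, rightmost.closed = TRUE), 1), nv)
  counts <- matrix(0, na, nv)
  tab <- table(factor(ia, levels = seq_len(na)), factor(iv, levels = seq_len(nv)))
  counts[] <- as.numeric(tab)
  structure(list(angle_edges = angle_edges, velocity_edges = velocity_edges,
                 counts = counts, clipped = clipped, normalized = FALSE,
                 leg = leg, discipline = discipline),
            class = "ski_density")
}

#' Normalize a density grid to its maximum occurrence
#'
#' Linear division by the maximum count within the (leg, discipline) grid,
#' so the most visited angle-velocity bin is 1 and an all-zero grid stays
#' zero. Idempotent.
#'
#' @param grid a `ski_density`.
#' @return The grid with `counts` in [0, 1] and `normalized = TRUE`.
#' @export
normalize_grid <- function(grid) {
  stopifnot(inherits(grid, "ski_density"))
  m <- max(grid$counts)
  if (m > 0) grid$counts <- grid$counts / m
  grid$normalized <- TRUE
  grid
}

#' @export
print.ski_density <- function(x, ...) {
  cat(sprintf("<ski_density> %s/%s: %d x %d bins, %s, %d clipped\n",
              x$discipline, x$leg, nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else sprintf("%d counts", sum(x$counts)),
              sum(x$clipped)))
  invisible(x)
}

#' Render a panel matrix of density grids
#'
#' One panel per grid (typically disciplines x legs), shared axes, linear
#' blue-to-red colormap: deep blue = no occurrence, dark red = maximum
#' occurrence within the panel. Grids are normalized before drawing if they
#' are not already.
#'
#' @param grids list of `ski_density` objects.
#' @param file output image path (`.png`); `NULL` draws on the active
#'   device.
#' @param ncol panels per row; default = number of distinct legs, else 2.
#' @param width,height image size in pixels.
#' @return `file` (or `NULL`), invisibly.
#' @export
render_density <- function(grids, file = NULL, ncol = NULL,
                           width = 1200, height = 1600) {
  if (inherits(grids, "ski_density")) grids <- list(grids)
  stopifnot(length(grids) >= 1)
  if (is.null(ncol)) {
    legs <- unique(vapply(grids, function(g) as.character(g$leg), character(1)))
    ncol <- if (all(!is.na(legs)) && length(legs) > 1) length(legs) else
      min(2L, length(grids))
  }
  pal <- grDevices::colorRampPalette(c("#00008B", "#2166AC", "#67A9CF",
                                       "#F7F7F7", "#EF8A62", "#B2182B",
                                       "#67001F"))(256)
  if (!is.null(file)) grDevices::png(file, width = width, height = height)
  op <- graphics::par(mfrow = c(ceiling(length(grids) / ncol), ncol),
                      mar = c(4, 4, 2, 1))
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  for (g in grids) {
    if (!g$normalized) g <- normalize_grid(g)
    va <- (g$angle_edges[-1] + g$angle_edges[-length(g$angle_edges)]) / 2
    vv <- (g$velocity_edges[-1] + g$velocity_edges[-length(g$velocity_edges)]) / 2
    graphics::image(vv, va, t(g$counts), col = pal, zlim = c(0, 1),
                    xlab = "angular velocity (deg/s)", ylab = "knee angle (deg)",
                    main = paste(g$discipline, g$leg), useRaster = TRUE)
  }
  invisible(file)
}

#' Pool metric samples into per-(leg, discipline) density grids
#'
#' Convenience wrapper: pools filtered angle/velocity samples of the
#' retained segments of several runs and builds one grid per (discipline,
#' leg) present.
#'
#' @param samples data frame with columns `angle`, `velocity`, `leg`,
#'   `discipline`.
#' @param ... passed to [density_grid()].
#' @return Named list of `ski_density` grids (`"GS.OL"`, ...).
#' @export
density_grids_by_group <- function(samples, ...) {
  stopifnot(all(c("angle", "velocity", "leg", "discipline") %in% names(samples)))
  out <- list()
  for (d in unique(samples$discipline)) {
    for (l in unique(samples$leg)) {
      sel <- samples$discipline == d & samples$leg == l
      if (!any(sel)) next
      out[[paste(d, l, sep = ".")]] <-
        density_grid(samples$angle[sel], samples$velocity[sel],
                     leg = l, discipline = d, ...)
    }
  }
  out
}
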