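# Coerce projection input (matrix, data.frame or list with $points) to a
# plain n x 2 matrix, keeping a times_ps attribute when present.
as_projection <- function(points) {
  times <- attr(points, "times_ps")
  if (is.list(points) && !is.data.frame(points) && !is.null(points$points)) {
    times <- times %||% points$times_ps
    points <- points$points
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop_format("projection must have 2 columns")
  if (!all(is.finite(pts))) stop_format("non-finite projection points")
  attr(pts, "times_ps") <- times
  pts
}

#' Bin a 2D projection on a regular grid
#'
#' Bins are half-open `[lo, hi)` except the last bin along each axis, which
#' is closed, so every in-range point lands in exactly one bin. With
#' `clip = TRUE`, points outside the extent are assigned to the nearest edge
#' bin and counted in the `n_clipped` attribute (projected points of one
#' ensemble can fall slightly outside another's bounding box).
#'
#' @param points `n x 2` matrix (or object coercible to one).
#' @param n_bins_x,n_bins_y Grid resolution (default 50 x 50).
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)`; default the bounding
#'   box of `points`.
#' @param clip Clip out-of-extent points to edge bins instead of erroring.
#' @return Object of class `bmbs_hist2d`: list with `counts`
#'   (`n_bins_x x n_bins_y`), `xedges`, `yedges`, `total`, `n_clipped`, and
#'   `bin_of_point` (`n x 2` bin subscripts per input point).
#' @export
bin_projection <- function(points, n_bins_x = 50L, n_bins_y = 50L,
                           extent = NULL, clip = FALSE) {
  pts <- as_projection(points)
  if (nrow(pts) == 0L) stop_config("empty projection")
  if (n_bins_x < 1L || n_bins_y < 1L) stop_config("need at least 1 bin per axis")
  if (is.null(extent))
    extent <- c(range(pts[, 1L]), range(pts[, 2L]))
  if (extent[2L] <= extent[1L]) extent[1:2] <- extent[1L] + c(-0.5, 0.5)
  if (extent[4L] <= extent[3L]) extent[3:4] <- extent[3L] + c(-0.5, 0.5)
  xedges <- seq(extent[1L], extent[2L], length.out = n_bins_x + 1L)
  yedges <- seq(extent[3L], extent[4L], length.out = n_bins_y + 1L)
  ix <- findInterval(pts[, 1L], xedges, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2L], yedges, rightmost.closed = TRUE)
  out_of_range <- ix < 1L | ix > n_bins_x | iy < 1L | iy > n_bins_y
  n_clipped <- sum(out_of_range)
  if (n_clipped > 0L && !clip)
    stop_config(sprintf("%d points outside the binning extent (use clip = TRUE)",
                        n_clipped))
  ix <- pmin(pmax(ix, 1L), n_bins_x)
  iy <- pmin(pmax(iy, 1L), n_bins_y)
  counts <- matrix(0, n_bins_x, n_bins_y)
  tab <- table(factor(ix, levels = seq_len(n_bins_x)),
               factor(iy, levels = seq_len(n_bins_y)))
  counts[] <- as.numeric(tab)
  structure(
    list(counts = counts, xedges = xedges, yedges = yedges,
         total = nrow(pts), n_clipped = n_clipped,
         bin_of_point = cbind(ix, iy)),
    class = "bmbs_hist2d"
  )
}

#' @export
print.bmbs_hist2d <- function(x, ...) {
  cat(sprintf("2D histogram: %d x %d bins, %d points (%d occupied bins%s)\n",
              nrow(x$counts), ncol(x$counts), x$total, sum(x$counts > 0),
              if (x$n_clipped) paste0(", ", x$n_clipped, " clipped") else ""))
  invisible(x)
}

#' Bin centres of a 2D histogram
#' @param hist A `bmbs_hist2d`.
#' @return List with `x` and `y` centre vectors.
#' @export
bin_centers <- function(hist) {
  list(x = (head(hist$xedges, -1L) + tail(hist$xedges, -1L)) / 2,
       y = (head(hist$yedges, -1L) + tail(hist$yedges, -1L)) / 2)
}

same_grid <- function(h1, h2, tol = 1e-9) {
  length(h1$xedges) == length(h2$xedges) &&
    length(h1$yedges) == length(h2$yedges) &&
    max(abs(h1$xedges - h2$xedges)) <= tol &&
    max(abs(h1$yedges - h2$yedges)) <= tol
}

#' Plot a 2D histogram
#'
#' Density shading on the histogram grid. Axes are unlabelled: the two
#' projection coordinates of a non-linear map carry no physical meaning.
#'
#' @param x A `bmbs_hist2d`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `x`.
#' @export
plot.bmbs_hist2d <- function(x, ...) {
  graphics::image(x$xedges, x$yedges, x$counts, xlab = "", ylab = "",
                  xaxt = "n", yaxt = "n", ...)
  invisible(x)
}
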