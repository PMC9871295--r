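#' Raw earth mover's distance between two 2D histograms
#'
#' Exact optimal-transport (Wasserstein-1) distance between the two binned
#' distributions, with Euclidean distance between bin centres as the ground
#' metric. Both histograms are normalised to unit mass first, so ensembles
#' of different sizes compare directly. Because the ground distance is a
#' metric, shared mass can stay in place in an optimal plan; the solver
#' therefore transports only the signed difference between the two
#' distributions, which is exact and much faster for similar histograms.
#'
#' @param hist_P,hist_Q `bmbs_hist2d` objects on the same grid.
#' @return Non-negative scalar; 0 iff the mass distributions are identical.
#' @export
raw_emd <- function(hist_P, hist_Q) {
  stopifnot(inherits(hist_P, "bmbs_hist2d"), inherits(hist_Q, "bmbs_hist2d"))
  if (!same_grid(hist_P, hist_Q))
    stop_config("histograms are on different grids")
  if (sum(hist_P$counts) <= 0 || sum(hist_Q$counts) <= 0)
    stop_config("empty histogram")
  p <- hist_P$counts / sum(hist_P$counts)
  q <- hist_Q$counts / sum(hist_Q$counts)
  diffm <- p - q
  sup <- which(diffm > 1e-15)
  dem <- which(diffm < -1e-15)
  if (length(sup) == 0L || length(dem) == 0L) return(0)
  ctr <- bin_centers(hist_P)
  nx <- nrow(p)
  xy <- function(idx) {
    i <- (idx - 1L) %% nx + 1L
    j <- (idx - 1L) %/% nx + 1L
    cbind(ctr$x[i], ctr$y[j])
  }
  a <- diffm[sup]
  b <- -diffm[dem]
  # re-balance exactly (normalisation rounding)
  b <- b * sum(a) / sum(b)
  cost <- cross_dist(xy(sup), xy(dem))
  .cpp_transport_cost(a, b, cost)
}

#' Build a unity normalisation for earth mover's distances
#'
#' The normalisation constant `max_emd` is defined as the raw EMD between
#' the reference projection's histogram and a uniform rectangular sample of
#' the same point count over the reference's bounding box, binned on the
#' same grid. Normalised EMD values of 1 then mean "as dissimilar from the
#' reference as a structureless uniform distribution"; `min_emd` is 0.
#'
#' @param reference_projection `n x 2` matrix of reference points (e.g. the
#'   coarse-grained map).
#' @param n_bins_x,n_bins_y Grid resolution (default 50 x 50).
#' @param rng_seed Seed for the uniform sample; the normalisation is
#'   deterministic given it.
#' @param reference_tag Free-text tag recorded in the result.
#' @return Object of class `bmbs_emd_norm`: list with `min_emd` (0),
#'   `max_emd`, `reference_hist`, `uniform_hist`, `rng_seed`,
#'   `reference_tag`.
#' @export
make_normalization <- function(reference_projection, n_bins_x = 50L,
                               n_bins_y = 50L, rng_seed = 0L,
                               reference_tag = "reference") {
  pts <- as_projection(reference_projection)
  if (nrow(pts) == 0L) stop_config("empty reference projection")
  ext <- c(range(pts[, 1L]), range(pts[, 2L]))
  if (ext[2L] <= ext[1L] || ext[4L] <= ext[3L])
    stop_config("degenerate reference bounding box (zero area)")
  ref_hist <- bin_projection(pts, n_bins_x, n_bins_y, extent = ext)
  uni <- with_seed(rng_seed, cbind(runif(nrow(pts), ext[1L], ext[2L]),
                                   runif(nrow(pts), ext[3L], ext[4L])))
  uni_hist <- bin_projection(uni, n_bins_x, n_bins_y, extent = ext, clip = TRUE)
  max_emd <- raw_emd(ref_hist, uni_hist)
  bin_diag <- sqrt(diff(ext[1:2])^2 / n_bins_x^2 + diff(ext[3:4])^2 / n_bins_y^2)
  if (max_emd <= 0.5 * bin_diag)
    stop_config(paste("degenerate normalisation: the reference is itself",
                      "(nearly) uniform over its bounding box"))
  structure(
    list(min_emd = 0, max_emd = max_emd, reference_hist = ref_hist,
         uniform_hist = uni_hist, rng_seed = as.integer(rng_seed),
         reference_tag = reference_tag),
    class = "bmbs_emd_norm"
  )
}

#' Unity-normalised earth mover's distance
#'
#' `EMD' = (EMD - min_emd) / (max_emd - min_emd)` with `min_emd = 0` and
#' `max_emd` from [make_normalization()]. Identical distributions give 0;
#' a pair as dissimilar as the reference-vs-uniform comparison gives 1;
#' values above 1 are possible for still more dissimilar pairs.
#'
#' @param hist_P,hist_Q `bmbs_hist2d` objects on the same grid.
#' @param norm A `bmbs_emd_norm`.
#' @return Non-negative scalar.
#' @export
normalized_emd <- function(hist_P, hist_Q, norm) {
  stopifnot(inherits(norm, "bmbs_emd_norm"))
  (raw_emd(hist_P, hist_Q) - norm$min_emd) / (norm$max_emd - norm$min_emd)
}

# Common duration (ps) of a list of timed projections; error on mismatch
# unless truncation is allowed.
common_duration <- function(trajs, truncate) {
  durs <- vapply(trajs, function(p) {
    t <- attr(as_projection(p), "times_ps")
    if (is.null(t)) stop_config("every trajectory projection needs times_ps")
    max(t) - min(t)
  }, 1)
  if (max(durs) - min(durs) > 1e-6) {
    if (!truncate)
      stop_config("trajectories have unequal durations (set truncate = TRUE)")
    return(min(durs))
  }
  durs[1L]
}

#' Cumulative 2D histograms of trajectory projections over time
#'
#' Pools the projected frames of every trajectory up to (forward) or from
#' (reversed) a growing time window and bins them on a fixed grid. With a
#' window step of `interval_ps` and common duration `T`, the result has
#' `T / interval_ps` histograms; e.g. 50 ns trajectories at 250 ps steps
#' give 200 histograms. In reversed mode the window grows backwards from
#' each trajectory's final frame, which removes the seeding bias from the
#' early histograms.
#'
#' @param trajectory_projections List of `n x 2` matrices, each with a
#'   `times_ps` attribute (ps, relative times are taken per trajectory).
#' @param interval_ps Window step in ps.
#' @param direction `"forward"` or `"reversed"`.
#' @param grid A `bmbs_hist2d` or `bmbs_emd_norm` defining the common grid.
#' @param truncate Allow unequal trajectory durations (truncates to the
#'   shortest).
#' @return List of `bmbs_hist2d` with attribute `times_ns` (window end
#'   times, ns).
#' @export
cumulative_histograms <- function(trajectory_projections, interval_ps,
                                  direction = c("forward", "reversed"),
                                  grid, truncate = FALSE) {
  direction <- match.arg(direction)
  if (inherits(grid, "bmbs_emd_norm")) grid <- grid$reference_hist
  stopifnot(inherits(grid, "bmbs_hist2d"))
  if (interval_ps <= 0) stop_config("interval_ps must be positive")
  trajs <- lapply(trajectory_projections, as_projection)
  dur <- common_duration(trajs, truncate)
  n_win <- floor(dur / interval_ps + 1e-9)
  if (n_win < 1L) stop_config("interval longer than the trajectories")
  nx <- nrow(grid$counts); ny <- ncol(grid$counts)
  ext <- c(grid$xedges[1L], tail(grid$xedges, 1L),
           grid$yedges[1L], tail(grid$yedges, 1L))
  rel <- lapply(trajs, function(p) attr(p, "times_ps") - min(attr(p, "times_ps")))
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    tau <- k * interval_ps
    pooled <- do.call(rbind, lapply(seq_along(trajs), function(i) {
      t <- rel[[i]]
      keep <- if (direction == "forward") t <= tau + 1e-9
              else t >= dur - tau - 1e-9
      trajs[[i]][keep, , drop = FALSE]
    }))
    out[[k]] <- bin_projection(pooled, nx, ny, extent = ext, clip = TRUE)
  }
  attr(out, "times_ns") <- seq_len(n_win) * interval_ps / 1000
  attr(out, "direction") <- direction
  out
}

#' Time-resolved normalised EMD curve
#'
#' Tracks how the pooled 2D distribution of a set of trajectories
#' approaches (or departs from) a reference histogram as individual
#' simulation time grows. One normalised EMD value is computed per
#' cumulative window (see [cumulative_histograms()]).
#'
#' @inheritParams cumulative_histograms
#' @param reference_hist Reference `bmbs_hist2d` (same grid as `norm`).
#' @param norm A [make_normalization()] result.
#' @param tag Free-text comparison tag stored on the curve.
#' @return Data frame of class `bmbs_emd_curve` with columns `time_ns`,
#'   `emd_normalized`, `direction`, `tag`.
#' @export
time_resolved_emd <- function(trajectory_projections, reference_hist,
                              interval_ps, norm,
                              direction = c("forward", "reversed"),
                              truncate = FALSE, tag = "") {
  direction <- match.arg(direction)
  hists <- cumulative_histograms(trajectory_projections, interval_ps,
                                 direction, grid = reference_hist,
                                 truncate = truncate)
  vals <- vapply(hists, normalized_emd, 1, hist_Q = reference_hist, norm = norm)
  structure(
    data.frame(time_ns = attr(hists, "times_ns"), emd_normalized = vals,
               direction = direction, tag = tag),
    class = c("bmbs_emd_curve", "data.frame")
  )
}

#' Cross-seeding EMD curve
#'
#' Compares the growing cumulative histograms of one seeding strategy's
#' trajectories against the fixed histogram of the final `tail_ns` of
#' another strategy's trajectories. Decreasing curves mean the two
#' ensembles converge toward a shared region of the map.
#'
#' @param source_projections List of timed projections (strategy X).
#' @param target_projections List of timed projections (strategy Y) whose
#'   last `tail_ns` of each trajectory define the fixed target histogram.
#' @param tail_ns Target tail length in ns (default 10).
#' @inheritParams time_resolved_emd
#' @return A `bmbs_emd_curve`.
#' @export
cross_seeding_emd <- function(source_projections, target_projections,
                              interval_ps, norm, tail_ns = 10,
                              truncate = FALSE, tag = "") {
  grid <- norm$reference_hist
  trajs <- lapply(target_projections, as_projection)
  dur <- common_duration(trajs, truncate)
  tail_ps <- tail_ns * 1000
  if (tail_ps > dur + 1e-9) stop_config("tail_ns exceeds trajectory duration")
  pooled <- do.call(rbind, lapply(trajs, function(p) {
    t <- attr(p, "times_ps") - min(attr(p, "times_ps"))
    p[t >= dur - tail_ps - 1e-9, , drop = FALSE]
  }))
  nx <- nrow(grid$counts); ny <- ncol(grid$counts)
  ext <- c(grid$xedges[1L], tail(grid$xedges, 1L),
           grid$yedges[1L], tail(grid$yedges, 1L))
  target_hist <- bin_projection(pooled, nx, ny, extent = ext, clip = TRUE)
  time_resolved_emd(source_projections, target_hist, interval_ps, norm,
                    direction = "forward", truncate = truncate, tag = tag)
}

#' Write an EMD curve as TSV
#' @param curve A `bmbs_emd_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emd_curve <- function(curve, path) {
  write.table(curve, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot an EMD curve
#' @param x A `bmbs_emd_curve`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.bmbs_emd_curve <- function(x, ...) {
  graphics::plot(x$time_ns, x$emd_normalized, type = "l",
                 xlab = "individual simulation time (ns)",
                 ylab = "normalised EMD", ...)
  invisible(x)
}
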