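# Occupied bins of a histogram ordered by decreasing population, ties
# broken by (row, col) lexicographic order for determinism.
occupied_bins_ordered <- function(hist) {
  occ <- which(hist$counts > 0, arr.ind = TRUE)
  cnt <- hist$counts[occ]
  occ[order(-cnt, occ[, 1L], occ[, 2L]), , drop = FALSE]
}

# Point indices (rows of the binned projection) falling in bin (i, j).
bin_members <- function(hist, i, j) {
  which(hist$bin_of_point[, 1L] == i & hist$bin_of_point[, 2L] == j)
}

new_seedset <- function(frames, bins, strategy, rng_seed) {
  structure(
    list(frames = as.integer(frames), bins = bins, strategy = strategy,
         rng_seed = as.integer(rng_seed), n = length(frames)),
    class = "bmbs_seedset"
  )
}

#' @export
print.bmbs_seedset <- function(x, ...) {
  cat(sprintf("Seed set: %d seeds, %s strategy (rng %d), %d distinct bins\n",
              x$n, x$strategy, x$rng_seed, nrow(unique(x$bins))))
  invisible(x)
}

check_seed_args <- function(hist, n, replacement = TRUE) {
  stopifnot(inherits(hist, "bmbs_hist2d"))
  if (is.null(hist$bin_of_point))
    stop_config("histogram lacks per-point bin assignments")
  if (n < 1L) stop_config("n must be >= 1")
  if (!replacement && n > hist$total)
    stop_config("cannot select more seeds than projected points")
}

#' Minima-focused seeding
#'
#' Replicates the deepest free-energy minima of the 2D map and their
#' weighting: bins are visited in decreasing population order and each
#' visited bin contributes `round(n * bin_share)` seeds (at least one),
#' drawn uniformly without replacement from its member points, until `n`
#' seeds are selected.
#'
#' @param hist A [bin_projection()] result (must carry point assignments).
#' @param n Number of seeds.
#' @param rng_seed Integer seed; selection is deterministic given it.
#' @return A `bmbs_seedset`: frame indices into the binned projection, one
#'   bin record per seed.
#' @export
seed_minima_focused <- function(hist, n, rng_seed = 0L) {
  check_seed_args(hist, n, replacement = FALSE)
  ord <- occupied_bins_ordered(hist)
  total <- sum(hist$counts)
  frames <- integer(0)
  bins <- matrix(integer(0), 0L, 2L)
  with_seed(rng_seed, {
    repeat {
      for (r in seq_len(nrow(ord))) {
        if (length(frames) >= n) break
        i <- ord[r, 1L]; j <- ord[r, 2L]
        members <- setdiff(bin_members(hist, i, j), frames)
        if (length(members) == 0L) next
        quota <- max(1L, round(n * hist$counts[i, j] / total))
        take <- min(quota, length(members), n - length(frames))
        pick <- members[sample.int(length(members), take)]
        frames <- c(frames, pick)
        bins <- rbind(bins, matrix(c(rep(i, take), rep(j, take)), take, 2L))
      }
      if (length(frames) >= n) break
    }
  })
  new_seedset(frames, bins, "minima_focused", rng_seed)
}

#' Boltzmann-weighted seeding
#'
#' Monte Carlo selection that retains the population weighting of the map
#' while still admitting rare conformations: repeatedly pick an occupied
#' bin uniformly at random and accept it with probability proportional to
#' its population (normalised by the most populated bin); on acceptance one
#' member point is drawn uniformly. Sampling is with replacement across
#' iterations, so seed shares converge to bin population shares for large
#' `n`.
#'
#' @inheritParams seed_minima_focused
#' @return A `bmbs_seedset`.
#' @export
seed_boltzmann <- function(hist, n, rng_seed = 0L) {
  check_seed_args(hist, n)
  occ <- which(hist$counts > 0, arr.ind = TRUE)
  maxc <- max(hist$counts)
  frames <- integer(n)
  bins <- matrix(0L, n, 2L)
  with_seed(rng_seed, {
    k <- 0L
    while (k < n) {
      r <- sample.int(nrow(occ), 1L)
      i <- occ[r, 1L]; j <- occ[r, 2L]
      if (runif(1L) <= hist$counts[i, j] / maxc) {
        members <- bin_members(hist, i, j)
        k <- k + 1L
        frames[k] <- members[sample.int(length(members), 1L)]
        bins[k, ] <- c(i, j)
      }
    }
  })
  new_seedset(frames, bins, "boltzmann", rng_seed)
}

#' Uniform seeding over occupied bins
#'
#' Targets a uniform distribution in the 2D space: occupied bins are chosen
#' uniformly at random without replacement, one seed point per chosen bin.
#' If the pool of occupied bins empties before `n` seeds are selected, the
#' pool is replenished and selection continues, so every occupied bin is
#' covered once before any bin contributes a second seed.
#'
#' @inheritParams seed_minima_focused
#' @return A `bmbs_seedset`.
#' @export
seed_uniform <- function(hist, n, rng_seed = 0L) {
  check_seed_args(hist, n)
  occ <- which(hist$counts > 0, arr.ind = TRUE)
  frames <- integer(n)
  bins <- matrix(0L, n, 2L)
  with_seed(rng_seed, {
    pool <- seq_len(nrow(occ))
    for (k in seq_len(n)) {
      if (length(pool) == 0L) pool <- seq_len(nrow(occ))
      pick <- pool[sample.int(length(pool), 1L)]
      pool <- setdiff(pool, pick)
      i <- occ[pick, 1L]; j <- occ[pick, 2L]
      members <- bin_members(hist, i, j)
      frames[k] <- members[sample.int(length(members), 1L)]
      bins[k, ] <- c(i, j)
    }
  })
  new_seedset(frames, bins, "uniform", rng_seed)
}

#' Write a seed set as TSV
#'
#' Columns: frame index (1-based into the binned projection), bin row, bin
#' column, strategy, rng seed.
#'
#' @param seeds A `bmbs_seedset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seed_set <- function(seeds, path) {
  df <- data.frame(frame = seeds$frames, bin_i = seeds$bins[, 1L],
                   bin_j = seeds$bins[, 2L], strategy = seeds$strategy,
                   rng_seed = seeds$rng_seed)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export seed structures for back-mapping
#'
#' Writes the selected frames as a multi-model C-alpha PDB, the hand-off
#' format for an external resolution-transformation tool (e.g. the MARTINI
#' "backward" script). The back-mapping itself is outside this package:
#' coarse-grained structures go out, back-mapped atomistic structures come
#' back in via [load_ensemble()].
#'
#' @param ens The source `bmbs_ensemble` the seeds index into.
#' @param seeds A `bmbs_seedset`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
export_seed_structures <- function(ens, seeds, path) {
  if (any(seeds$frames < 1L) || any(seeds$frames > n_frames(ens)))
    stop_config("seed frame indices outside the ensemble")
  write_ensemble_pdb(ens, path, frames = seeds$frames)
}
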