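# Approximate top-k eigenfactor V_k * sqrt(L_k) of a symmetric matrix,
# used to initialise the embedding. Full eigen() for small problems;
# deterministic subspace iteration (cosine-basis start) for large ones,
# where only the leading subspace is needed.
top_k_factor <- function(S, k) {
  n <- nrow(S)
  if (n <= 600L) {
    eg <- eigen(S, symmetric = TRUE)
    return(eg$vectors[, seq_len(k), drop = FALSE] %*%
             diag(sqrt(pmax(eg$values[seq_len(k)], 1e-12)), k))
  }
  p <- min(n, k + 8L)
  i <- seq_len(n)
  Q <- qr.Q(qr(vapply(seq_len(p), function(j) cos(pi * (i - 0.5) * j / n),
                      numeric(n))))
  for (it in 1:30) Q <- qr.Q(qr(S %*% Q))
  B <- crossprod(Q, S %*% Q)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- (Q %*% eg$vectors)[, seq_len(k), drop = FALSE]
  V %*% diag(sqrt(pmax(eg$values[seq_len(k)], 1e-12)), k)
}

#' Correlation-preserving intermediate embedding (cc_analysis style)
#'
#' Multidimensional-scaling-like embedding that minimises
#' `sum_{i<j} (r_ij - <x_i, x_j>)^2`, where `r_ij` is the Pearson
#' correlation between the feature vectors of frames i and j and `x_i` are
#' k-dimensional embedding vectors. Initialised from the top-k
#' eigenvectors of the correlation matrix and refined by L-BFGS-B with the
#' analytic gradient; the result is deterministic.
#'
#' @param features Numeric matrix `frames x d`; no frame may have constant
#'   features (Pearson correlation undefined).
#' @param k Embedding dimensionality (>= 2; typical values 10-40).
#' @param rng_seed Seed, used only when `jitter_sd > 0` perturbs the
#'   spectral initialisation; recorded in the result either way.
#' @param corr Optional precomputed frame-frame correlation matrix
#'   (overrides `features`).
#' @param max_iter Optimiser iteration cap.
#' @param jitter_sd Optional Gaussian perturbation of the initialisation.
#' @return Object of class `bmbs_cc_embedding`: list with `coordinates`
#'   (`frames x k`), `residual` (RMS of the off-diagonal fit errors), `k`,
#'   `rng_seed`.
#' @export
cc_embed <- function(features, k = 10L, rng_seed = 0L, corr = NULL,
                     max_iter = 500L, jitter_sd = 0) {
  k <- as.integer(k)
  if (k < 2L) stop_config("k must be >= 2")
  if (is.null(corr)) {
    X <- as.matrix(features)
    sds <- apply(X, 1L, sd)
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad))
      stop_config(paste0("constant feature row(s): frame ",
                         paste(head(bad, 5L), collapse = ", ")))
    corr <- cor(t(X))
  }
  n <- nrow(corr)
  if (n < k + 1L) stop_config("need at least k + 1 frames")
  x0 <- top_k_factor(corr, k)
  if (jitter_sd > 0)
    x0 <- x0 + with_seed(rng_seed, matrix(rnorm(n * k, sd = jitter_sd), n, k))
  off <- n * (n - 1)  # ordered off-diagonal pair count
  # fn and gr share the residual matrix; L-BFGS-B evaluates both at the
  # same point, so cache on the parameter vector
  cache <- new.env(parent = emptyenv())
  residual_at <- function(par) {
    if (!identical(cache$par, par)) {
      Xk <- matrix(par, n, k)
      E <- corr - tcrossprod(Xk)
      diag(E) <- 0
      cache$par <- par
      cache$Xk <- Xk
      cache$E <- E
    }
    cache
  }
  fn <- function(par) {
    cc <- residual_at(par)
    0.5 * sum(cc$E * cc$E)
  }
  gr <- function(par) {
    cc <- residual_at(par)
    as.vector(-2 * cc$E %*% cc$Xk)
  }
  opt <- optim(as.vector(x0), fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 10))
  Xk <- matrix(opt$par, n, k)
  E <- corr - tcrossprod(Xk)
  diag(E) <- 0
  residual <- sqrt(sum(E^2) / off)
  structure(
    list(coordinates = Xk, residual = residual, k = k,
         rng_seed = as.integer(rng_seed), converged = opt$convergence == 0L),
    class = "bmbs_cc_embedding"
  )
}

#' Density-based clustering of an embedding (HDBSCAN)
#'
#' Hierarchical density-based clustering with noise: builds the
#' mutual-reachability single-linkage hierarchy of the embedding, condenses
#' it at `min_cluster_size` and selects clusters by excess-of-mass
#' stability. Low-density points are labelled -1.
#'
#' @param embedding A [cc_embed()] result or a plain coordinate matrix.
#' @param min_cluster_size Smallest cluster size retained (default 80).
#' @param min_samples Neighbourhood size for core distances (default equal
#'   to `min_cluster_size`).
#' @param allow_single_cluster Permit the hierarchy root itself to be
#'   selected (off by default; see the iterative workflow for when this is
#'   useful).
#' @return Object of class `bmbs_clusters`: `labels` (0-based cluster ids,
#'   -1 noise), `representatives` (frame index of each cluster's embedding
#'   medoid), `iteration` (per assigned frame), `params`.
#' @export
density_cluster <- function(embedding, min_cluster_size = 80L,
                            min_samples = min_cluster_size,
                            allow_single_cluster = FALSE) {
  X <- if (inherits(embedding, "bmbs_cc_embedding")) embedding$coordinates
       else as.matrix(embedding)
  labels <- hdbscan_labels(X, min_cluster_size, min_samples,
                           allow_single_cluster)
  n_cl <- if (any(labels >= 0L)) max(labels) + 1L else 0L
  reps <- integer(n_cl)
  if (n_cl > 0L) {
    for (c in seq_len(n_cl) - 1L) {
      mem <- which(labels == c)
      dm <- as.matrix(dist(X[mem, , drop = FALSE]))
      reps[c + 1L] <- mem[which.min(rowSums(dm))]
    }
  }
  structure(
    list(labels = labels,
         representatives = reps,
         iteration = ifelse(labels >= 0L, 1L, NA_integer_),
         params = list(min_cluster_size = as.integer(min_cluster_size),
                       min_samples = as.integer(min_samples),
                       allow_single_cluster = allow_single_cluster)),
    class = "bmbs_clusters"
  )
}

#' @export
print.bmbs_clusters <- function(x, ...) {
  nc <- sum(unique(x$labels) >= 0L)
  cat(sprintf("Cluster assignment: %d clusters, %d/%d frames assigned (%.1f%%)\n",
              nc, sum(x$labels >= 0L), length(x$labels),
              100 * mean(x$labels >= 0L)))
  invisible(x)
}

#' Minimum RMSD under optimal rigid superposition
#'
#' Kabsch superposition: both frames are centred, the optimal rotation is
#' taken from the SVD of the cross-covariance (with the reflection branch
#' excluded), and the RMSD of the superposed coordinates is returned. Zero
#' for congruent frames; invariant to rigid motion of either frame.
#'
#' @param frame_a,frame_b Numeric `sites x 3` matrices (nm).
#' @param site_selection Optional row indices used for the superposition
#'   and the RMSD (default all sites).
#' @return Scalar RMSD in nm.
#' @export
kabsch_rmsd <- function(frame_a, frame_b, site_selection = NULL) {
  if (!is.null(site_selection)) {
    frame_a <- frame_a[site_selection, , drop = FALSE]
    frame_b <- frame_b[site_selection, , drop = FALSE]
  }
  if (nrow(frame_a) != nrow(frame_b))
    stop_domain("frames must have equal site counts")
  if (nrow(frame_a) < 3L) stop_domain("need at least 3 sites")
  A <- sweep(frame_a, 2L, colMeans(frame_a))
  B <- sweep(frame_b, 2L, colMeans(frame_b))
  sv <- svd(crossprod(A, B))
  s <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

# 2D footprint of each cluster: centroid and the 95th percentile of member
# distances to it.
cluster_footprints <- function(labels, projection) {
  ids <- sort(unique(labels[labels >= 0L]))
  lapply(ids, function(c) {
    mem <- which(labels == c)
    ctr <- colMeans(projection[mem, , drop = FALSE])
    rr <- sqrt(rowSums(sweep(projection[mem, , drop = FALSE], 2L, ctr)^2))
    list(id = c, centroid = ctr,
         r95 = as.numeric(stats::quantile(rr, 0.95)))
  })
}

#' Expand clusters to unassigned frames via the 2D map
#'
#' Cheap 2D pre-screening followed by an exact RMSD gate: an unassigned
#' frame is a candidate for a cluster when its 2D point lies within the
#' cluster's footprint radius (95th percentile of member radii around the
#' cluster's 2D centroid, or a fixed `neighborhood_radius`); candidates are
#' then compared by [kabsch_rmsd()] to the cluster representative over the
#' unmasked sites and assigned iff the RMSD is at most `rmsd_cutoff`,
#' ties going to the lowest-RMSD cluster. Already-assigned frames are never
#' touched.
#'
#' @param assignment A `bmbs_clusters` (labels over all frames of `ens`).
#' @param ens The `bmbs_ensemble` holding the frame coordinates.
#' @param projection `n x 2` matrix of per-frame map positions.
#' @param rmsd_cutoff RMSD gate in nm (default 0.3 nm = 3 Angstrom).
#' @param neighborhood_radius Fixed 2D screening radius; default `NULL`
#'   uses each cluster's own 95th-percentile footprint radius.
#' @param iteration Iteration index recorded for newly assigned frames.
#' @return Updated `bmbs_clusters`.
#' @export
expand_clusters <- function(assignment, ens, projection, rmsd_cutoff = 0.3,
                            neighborhood_radius = NULL, iteration = 1L) {
  stopifnot(inherits(assignment, "bmbs_clusters"))
  if (rmsd_cutoff <= 0) stop_config("rmsd_cutoff must be positive")
  labels <- assignment$labels
  if (!any(labels >= 0L)) return(assignment)
  projection <- as_projection(projection)
  sites <- unlist(lapply(seq_len(n_domains(ens$partition)),
                         function(i) domain_sites(ens, i)))
  fp <- cluster_footprints(labels, projection)
  reps <- assignment$representatives
  rep_coords <- lapply(reps, function(f) ens$coords[f, , , drop = TRUE])
  un <- which(labels < 0L)
  for (f in un) {
    best_c <- -1L
    best_r <- Inf
    p <- projection[f, ]
    for (fpc in fp) {
      rad <- neighborhood_radius %||% fpc$r95
      if (sqrt(sum((p - fpc$centroid)^2)) > rad) next
      r <- kabsch_rmsd(ens$coords[f, , , drop = TRUE],
                       rep_coords[[fpc$id + 1L]], sites)
      if (r <= rmsd_cutoff && r < best_r) {
        best_r <- r
        best_c <- fpc$id
      }
    }
    if (best_c >= 0L) {
      labels[f] <- best_c
      assignment$iteration[f] <- iteration
    }
  }
  assignment$labels <- labels
  assignment
}

#' Iterative conformational clustering workflow
#'
#' Repeats up to `max_iter` times on the still-unassigned frames:
#' correlation embedding ([cc_embed()]) -> density clustering
#' ([density_cluster()]) -> RMSD-gated expansion over the 2D map
#' ([expand_clusters()]). Labels from later iterations are offset so every
#' cluster id is unique; iteration provenance is recorded per frame. Stops
#' early once the assigned fraction reaches `stop_fraction`. If the first
#' pass finds no cluster structure at all, it is retried allowing the
#' hierarchy root as a cluster, so a single-basin data set resolves to one
#' cluster rather than none.
#'
#' @param features RMD feature matrix (`frames x d`).
#' @param ens The `bmbs_ensemble` with the frame coordinates.
#' @param projection `n x 2` map positions per frame.
#' @param k Embedding dimensionality (default 10).
#' @param min_cluster_size,min_samples HDBSCAN parameters (default 80).
#' @param rmsd_cutoff Expansion gate in nm (default 0.3).
#' @param max_iter Maximum iterations (default 3, must be >= 1).
#' @param stop_fraction Assigned-fraction stopping threshold (default 0.9).
#' @param rng_seed Base seed (per-iteration seeds derive from it).
#' @param cc_max_iter Optimiser cap for the per-iteration embedding
#'   (default 100; the spectral initialisation is already close, and the
#'   density clustering that follows does not need a fully converged fit).
#' @return A `bmbs_clusters` with global labels, per-frame iteration
#'   indices, representatives and a per-iteration `log`.
#' @export
iterative_workflow <- function(features, ens, projection, k = 10L,
                               min_cluster_size = 80L,
                               min_samples = min_cluster_size,
                               rmsd_cutoff = 0.3, max_iter = 3L,
                               stop_fraction = 0.9, rng_seed = 0L,
                               cc_max_iter = 100L) {
  if (max_iter < 1L) stop_config("max_iter must be >= 1")
  features <- as.matrix(features)
  n <- nrow(features)
  projection <- as_projection(projection)
  if (nrow(projection) != n || n_frames(ens) != n)
    stop_config("features, ensemble and projection must cover the same frames")
  labels <- rep(-1L, n)
  iteration <- rep(NA_integer_, n)
  reps <- integer(0)
  log <- list()
  for (it in seq_len(max_iter)) {
    un <- which(labels < 0L)
    if (length(un) < max(k + 2L, min_cluster_size)) break
    emb <- cc_embed(features[un, , drop = FALSE], k = k,
                    rng_seed = rng_seed + it, max_iter = cc_max_iter)
    ca <- density_cluster(emb, min_cluster_size, min_samples)
    if (!any(ca$labels >= 0L) && it == 1L && length(un) == n) {
      ca <- density_cluster(emb, min_cluster_size, min_samples,
                            allow_single_cluster = TRUE)
    }
    if (!any(ca$labels >= 0L)) {
      log[[it]] <- list(iteration = it, n_input = length(un), n_new_clusters = 0L)
      break
    }
    offset <- length(reps)
    new_mask <- ca$labels >= 0L
    labels[un[new_mask]] <- ca$labels[new_mask] + offset
    iteration[un[new_mask]] <- it
    reps <- c(reps, un[ca$representatives])
    glob <- structure(
      list(labels = labels, representatives = reps, iteration = iteration,
           params = ca$params),
      class = "bmbs_clusters")
    glob <- expand_clusters(glob, ens, projection, rmsd_cutoff,
                            iteration = it)
    labels <- glob$labels
    iteration <- glob$iteration
    log[[it]] <- list(iteration = it, n_input = length(un),
                      n_new_clusters = max(ca$labels) + 1L,
                      assigned_fraction = mean(labels >= 0L))
    if (mean(labels >= 0L) >= stop_fraction) break
  }
  structure(
    list(labels = labels, representatives = reps, iteration = iteration,
         params = list(k = k, min_cluster_size = min_cluster_size,
                       min_samples = min_samples, rmsd_cutoff = rmsd_cutoff,
                       max_iter = max_iter, stop_fraction = stop_fraction,
                       rng_seed = rng_seed),
         log = log),
    class = "bmbs_clusters"
  )
}

#' Cumulative growth of one cluster over individual simulation time
#'
#' Pools all trajectories and counts, at multiples of `interval_ps`, how
#' many frames assigned to the cluster have individual simulation time up
#' to that point. A cluster whose trajectories visit it early and then
#' leave shows growth followed by a plateau; the first time after which the
#' count stops growing is reported.
#'
#' @param assignment A `bmbs_clusters`.
#' @param frame_times Per-frame individual simulation times (ps).
#' @param cluster_id Cluster label (0-based).
#' @param interval_ps Sampling interval of the curve (ps).
#' @return Data frame with `time_ns` and `cumulative_count`, attribute
#'   `plateau_ns` (NA if the cluster is still growing at the end).
#' @export
cluster_growth_curve <- function(assignment, frame_times, cluster_id,
                                 interval_ps = 250) {
  stopifnot(inherits(assignment, "bmbs_clusters"))
  if (!cluster_id %in% assignment$labels)
    stop_config(paste("unknown cluster id:", cluster_id))
  if (length(frame_times) != length(assignment$labels))
    stop_config("frame_times length must match labels")
  tmem <- frame_times[assignment$labels == cluster_id]
  tmax <- max(frame_times)
  grid <- seq(0, tmax + interval_ps - 1e-9, by = interval_ps)
  cum <- vapply(grid, function(tau) sum(tmem <= tau + 1e-9), 1L)
  plateau <- NA_real_
  final <- cum[length(cum)]
  if (any(cum == final)) {
    first_flat <- grid[which(cum == final)[1L]]
    if (first_flat < tmax) plateau <- first_flat / 1000
  }
  structure(
    data.frame(time_ns = grid / 1000, cumulative_count = cum),
    plateau_ns = plateau
  )
}

#' Write a cluster assignment as TSV
#'
#' Columns: frame (1-based), label (0-based, -1 noise), iteration.
#'
#' @param assignment A `bmbs_clusters`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(assignment, path) {
  df <- data.frame(frame = seq_along(assignment$labels),
                   label = assignment$labels,
                   iteration = assignment$iteration)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
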