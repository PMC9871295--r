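test_that("correlation embedding reproduces planted structure", {
  # duplicated frames have identical correlation profiles, hence identical
  # embedding rows
  set.seed(40)
  F <- matrix(rnorm(60L), 10L, 6L)
  F[2L, ] <- F[1L, ]
  e <- cc_embed(F, k = 2L)
  expect_equal(e$coordinates[1L, ], e$coordinates[2L, ], tolerance = 1e-8)

  # exact rank-2 correlation structure: residual vanishes
  xs <- matrix(rnorm(40L, sd = 0.5), 20L, 2L)
  nrm <- pmax(sqrt(rowSums(xs^2)), 1)
  xs <- xs / nrm * 0.9
  C <- tcrossprod(xs)
  diag(C) <- 1
  e2 <- cc_embed(features = NULL, k = 2L, corr = C, max_iter = 2000L)
  expect_lt(e2$residual, 1e-6)

  # planted 3-state features: inter-state embedding distance dominates
  spec <- synthetic_spec(300L, domain_sizes = c(6L, 6L, 6L), tail_mask = 0L,
                         state_weights = c(open = 1 / 3, collapsed = 1 / 3,
                                           AB_contact = 1 / 3),
                         rng_seed = 41L)
  ens <- generate_synthetic_ensemble(spec)
  f <- featurize_ensemble(ens)
  lab <- attr(ens, "state_labels")
  e3 <- cc_embed(f, k = 10L)
  X <- e3$coordinates
  states <- unique(lab)
  ctrs <- t(vapply(states, function(s) colMeans(X[lab == s, , drop = FALSE]),
                   numeric(10L)))
  intra <- mean(vapply(seq_along(states), function(i) {
    mean(sqrt(rowSums(sweep(X[lab == states[i], , drop = FALSE], 2L,
                            ctrs[i, ])^2)))
  }, 1))
  expect_gt(mean(dist(ctrs)), intra)

  # constant feature rows are rejected by name
  Fc <- matrix(rnorm(30L), 5L, 6L)
  Fc[3L, ] <- 2
  expect_error(cc_embed(Fc, k = 2L), "frame 3", class = "bmbs_config_error")
})

test_that("density clustering finds planted states and rejects noise", {
  set.seed(42)
  B <- rbind(matrix(rnorm(500L * 5L), 500L, 5L),
             matrix(rnorm(500L * 5L, mean = 8), 500L, 5L),
             sweep(matrix(rnorm(500L * 5L), 500L, 5L), 2L,
                   c(-8, 8, 0, 0, 0), "+"))
  lab <- rep(0:2, each = 500L)
  dc <- density_cluster(B, min_cluster_size = 80L, min_samples = 80L)
  expect_equal(length(dc$representatives), 3L)
  expect_gte(mclust::adjustedRandIndex(dc$labels, lab), 0.95)
  # representatives are members of their clusters
  for (c in 0:2) expect_equal(dc$labels[dc$representatives[c + 1L]], c)

  # pure uniform noise: at least 90% labelled -1
  U <- matrix(runif(1000L * 5L), 1000L, 5L)
  du <- density_cluster(U, 80L, 80L)
  expect_gte(mean(du$labels == -1L), 0.9)

  # fewer frames than min_cluster_size: all noise, with a warning
  expect_warning(ds <- density_cluster(matrix(rnorm(60L), 20L, 3L), 80L, 80L))
  expect_true(all(ds$labels == -1L))
})

test_that("Kabsch RMSD matches closed forms and an orientation-search oracle", {
  set.seed(43)
  A <- matrix(rnorm(30L), 10L, 3L)
  expect_equal(kabsch_rmsd(A, A), 0)
  # rigid transforms of either argument are invisible
  for (r in 1:5) {
    R <- rand_rotation()
    B <- A %*% R + matrix(runif(3L, -3, 3), 10L, 3L, byrow = TRUE)
    expect_lt(kabsch_rmsd(A, B), 1e-9)
    expect_equal(kabsch_rmsd(A, B), kabsch_rmsd(B, A), tolerance = 1e-9)
  }
  # two hand-built 4-point frames vs direct minimisation over rotations
  A2 <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1.5, 0, 0.3, 0.2, 1.1), 4L, 3L,
               byrow = TRUE)
  B2 <- matrix(c(0, 0, 0, 1.1, 0.1, 0, -0.2, 1.4, 0.2, 0.5, 0, 1), 4L, 3L,
               byrow = TRUE)
  expect_equal(kabsch_rmsd(A2, B2), rmsd_orientation_oracle(A2, B2),
               tolerance = 1e-4)
  expect_error(kabsch_rmsd(A2[1:2, ], B2[1:2, ]), class = "bmbs_domain_error")
})

make_state_fixture <- function(n = 1500L, seed = 44L) {
  spec <- synthetic_spec(
    n, domain_sizes = c(10L, 10L, 10L), tail_mask = 0L,
    state_weights = c(open = 0.4, collapsed = 0.35, AB_contact = 0.25),
    rng_seed = seed)
  ens <- generate_synthetic_ensemble(spec)
  f <- featurize_ensemble(ens)
  list(ens = ens, f = f, lab = attr(ens, "state_labels"),
       proj = stats::prcomp(f, rank. = 2L)$x)
}

test_that("cluster expansion honours the RMSD gate and recovers held-out frames", {
  fx <- make_state_fixture()
  emb <- cc_embed(fx$f, k = 8L, max_iter = 100L)
  set.seed(45)
  half <- sort(sample.int(nrow(fx$f), nrow(fx$f) %/% 2L))
  dc <- density_cluster(emb$coordinates[half, , drop = FALSE], 40L, 40L)
  full <- structure(
    list(labels = rep(-1L, nrow(fx$f)),
         representatives = half[dc$representatives],
         iteration = rep(NA_integer_, nrow(fx$f)), params = dc$params),
    class = "bmbs_clusters")
  full$labels[half] <- dc$labels
  before <- full$labels
  ex <- expand_clusters(full, fx$ens, fx$proj, rmsd_cutoff = 0.3)
  # already-assigned frames are never touched
  expect_identical(ex$labels[before >= 0L], before[before >= 0L])
  held <- setdiff(seq_len(nrow(fx$f)), half)
  expect_gte(mean(ex$labels[held] >= 0L), 0.9)
  # every expansion assignment is within the cutoff of its representative
  sites <- seq_len(dim(fx$ens$coords)[2L])
  newly <- which(ex$labels >= 0L & before < 0L)
  for (f in head(newly, 25L)) {
    rep_f <- ex$representatives[ex$labels[f] + 1L]
    expect_lte(kabsch_rmsd(fx$ens$coords[f, , ], fx$ens$coords[rep_f, , ],
                           sites), 0.3)
  }

  # an exact copy of a representative is always recaptured: plant one on an
  # unassigned frame
  rep1 <- full$representatives[1L]
  copy_ens <- fx$ens
  copy_ens$coords[held[2L], , ] <- copy_ens$coords[rep1, , ]
  copy_assign <- full
  copy_proj <- fx$proj
  copy_proj[held[2L], ] <- colMeans(fx$proj[full$labels == 0L, , drop = FALSE])
  ex_copy <- expand_clusters(copy_assign, copy_ens, copy_proj,
                             rmsd_cutoff = 0.3)
  expect_equal(ex_copy$labels[held[2L]], 0L)

  # a frame far from every representative stays unassigned
  far <- fx$ens
  far$coords[held[1L], , ] <- far$coords[held[1L], , ] * 3
  ex2 <- expand_clusters(full, far, fx$proj, rmsd_cutoff = 0.05)
  expect_equal(ex2$labels[held[1L]], -1L)
})

test_that("the iterative workflow recovers planted states end to end", {
  fx <- make_state_fixture()
  wf <- iterative_workflow(fx$f, fx$ens, fx$proj, k = 8L,
                           min_cluster_size = 40L, min_samples = 40L,
                           rng_seed = 46L)
  expect_lte(length(wf$log), 3L)
  expect_gte(mclust::adjustedRandIndex(wf$labels, fx$lab), 0.9)
  # provenance is a partition: every frame has exactly one final label
  expect_length(wf$labels, nrow(fx$f))
  expect_true(all(wf$labels >= -1L))
  expect_true(all(!is.na(wf$iteration[wf$labels >= 0L])))
  # clusters occupy compact regions of the 2D map
  ids <- sort(unique(wf$labels[wf$labels >= 0L]))
  ctrs <- t(vapply(ids, function(c) colMeans(fx$proj[wf$labels == c, ,
                                                     drop = FALSE]),
                   numeric(2L)))
  intra <- mean(vapply(seq_along(ids), function(i) {
    mean(sqrt(rowSums(sweep(fx$proj[wf$labels == ids[i], , drop = FALSE], 2L,
                            ctrs[i, ])^2)))
  }, 1))
  if (length(ids) > 1L) expect_gt(mean(dist(ctrs)), intra)

  expect_error(iterative_workflow(fx$f, fx$ens, fx$proj, max_iter = 0L),
               class = "bmbs_config_error")
})

test_that("a single-basin ensemble resolves to one cluster", {
  spec <- synthetic_spec(400L, domain_sizes = c(8L, 8L, 8L), tail_mask = 0L,
                         state_weights = c(collapsed = 1), noise_sd = 0.02,
                         rng_seed = 47L)
  ens <- generate_synthetic_ensemble(spec)
  f <- featurize_ensemble(ens)
  proj <- stats::prcomp(f, rank. = 2L)$x
  wf <- iterative_workflow(f, ens, proj, k = 5L, min_cluster_size = 40L,
                           min_samples = 40L, rng_seed = 48L)
  expect_equal(length(wf$representatives), 1L)
  expect_equal(length(wf$log), 1L)
  expect_gte(mean(wf$labels == 0L), 0.99)
})

test_that("cluster growth curves report plateaus", {
  labels <- c(rep(0L, 40L), rep(-1L, 60L))
  assignment <- structure(
    list(labels = labels, representatives = 1L,
         iteration = ifelse(labels >= 0L, 1L, NA_integer_), params = list()),
    class = "bmbs_clusters")
  # cluster populated only in the first half of each trajectory
  times <- c(seq(0, 250 * 39, by = 250),              # members: first 10 ns
             seq(250 * 40, 250 * 99, by = 250))       # non-members afterwards
  gc <- cluster_growth_curve(assignment, times, 0L, interval_ps = 250)
  expect_true(all(diff(gc$cumulative_count) >= 0))
  expect_equal(max(gc$cumulative_count), 40L)
  expect_equal(attr(gc, "plateau_ns"), 250 * 39 / 1000)

  # unknown id errors; an unpopulated id cannot be queried
  expect_error(cluster_growth_curve(assignment, times, 7L),
               class = "bmbs_config_error")
})
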