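two_bin_hist <- function(n1 = 90L, n2 = 10L) {
  pts <- rbind(matrix(rep(c(0.25, 0.5), n1), ncol = 2L, byrow = TRUE),
               matrix(rep(c(0.75, 0.5), n2), ncol = 2L, byrow = TRUE))
  bin_projection(pts, 2L, 1L, extent = c(0, 1, 0, 1))
}

test_that("binning assigns every point to exactly one bin", {
  pts <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  h <- bin_projection(pts, 2L, 2L, extent = c(-2, 2, -2, 2))
  expect_equal(h$counts, matrix(1, 2L, 2L))
  expect_equal(h$total, 4L)

  h1 <- bin_projection(matrix(rnorm(40L, sd = 0.01), 20L, 2L), 5L, 5L,
                       extent = c(-1, 1, -1, 1))
  expect_equal(sum(h1$counts > 0), 1L)
  expect_equal(max(h1$counts), 20)

  # random points vs a double-loop oracle
  set.seed(10)
  pts2 <- matrix(runif(200L, 0, 4), 100L, 2L)
  h2 <- bin_projection(pts2, 4L, 5L, extent = c(0, 4, 0, 4))
  oracle <- matrix(0, 4L, 5L)
  xe <- seq(0, 4, length.out = 5L)
  ye <- seq(0, 4, length.out = 6L)
  for (p in 1:100) {
    i <- min(max(findInterval(pts2[p, 1L], xe, rightmost.closed = TRUE), 1L), 4L)
    j <- min(max(findInterval(pts2[p, 2L], ye, rightmost.closed = TRUE), 1L), 5L)
    oracle[i, j] <- oracle[i, j] + 1
  }
  expect_equal(h2$counts, oracle)
  expect_error(bin_projection(matrix(0, 0L, 2L)), class = "bmbs_config_error")
})

test_that("minima-focused seeding follows the population quota rule", {
  h <- two_bin_hist()
  s <- seed_minima_focused(h, 10L, rng_seed = 1L)
  expect_equal(sum(s$bins[, 1L] == 1L), 9L)  # 90% bin
  expect_equal(sum(s$bins[, 1L] == 2L), 1L)  # 10% bin
  expect_equal(s$n, 10L)

  # single occupied bin: all seeds come from it
  pts <- matrix(rnorm(120L, sd = 0.01), 60L, 2L)
  h1 <- bin_projection(pts, 3L, 3L, extent = c(-1, 1, -1, 1))
  s1 <- seed_minima_focused(h1, 50L, rng_seed = 2L)
  expect_equal(nrow(unique(s1$bins)), 1L)
  expect_equal(s1$n, 50L)
  # without-replacement within a bin: all indices distinct
  expect_equal(anyDuplicated(s1$frames), 0L)
})

test_that("Boltzmann seeding reproduces bin population shares", {
  h <- two_bin_hist()
  s <- seed_boltzmann(h, 10000L, rng_seed = 3L)
  share <- mean(s$bins[, 1L] == 1L)
  # 3 sigma binomial band around 0.9
  expect_lt(abs(share - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))

  # chi-square goodness of fit of seed bins vs bin populations
  obs <- c(sum(s$bins[, 1L] == 1L), sum(s$bins[, 1L] == 2L))
  expect_gt(stats::chisq.test(obs, p = c(0.9, 0.1))$p.value, 1e-4)

  # uniform histogram: acceptance probability 1 for every bin
  ptsu <- cbind(rep(c(0.25, 0.75), each = 10L), rep(c(0.25, 0.75), 10L))
  hu <- bin_projection(ptsu, 2L, 2L, extent = c(0, 1, 0, 1))
  su <- seed_boltzmann(hu, 400L, rng_seed = 4L)
  expect_true(all(table(paste(su$bins[, 1L], su$bins[, 2L])) > 50))

  # single occupied bin
  h1 <- bin_projection(matrix(0.5, 30L, 2L), 2L, 2L, extent = c(0, 1, 0, 1))
  s1 <- seed_boltzmann(h1, 20L, rng_seed = 5L)
  expect_equal(nrow(unique(s1$bins)), 1L)
})

test_that("uniform seeding covers bins without replacement, then replenishes", {
  # 3 occupied bins, n = 3: exactly one seed per bin
  pts <- rbind(c(0.1, 0.1), c(0.5, 0.5), c(0.9, 0.9))
  h <- bin_projection(pts, 3L, 3L, extent = c(0, 1, 0, 1))
  s <- seed_uniform(h, 3L, rng_seed = 6L)
  expect_equal(nrow(unique(s$bins)), 3L)

  # 2 occupied bins, n = 5: bin multiset {3, 2}
  h2 <- two_bin_hist()
  s2 <- seed_uniform(h2, 5L, rng_seed = 7L)
  expect_setequal(as.integer(table(s2$bins[, 1L])), c(2L, 3L))
})

test_that("seed records are internally consistent and reproducible", {
  set.seed(12)
  pts <- synthetic_projection_cloud(400L, rng_seed = 30L)
  h <- bin_projection(pts, 10L, 10L)
  for (fn in list(seed_minima_focused, seed_boltzmann, seed_uniform)) {
    s1 <- fn(h, 25L, rng_seed = 9L)
    s2 <- fn(h, 25L, rng_seed = 9L)
    expect_identical(s1$frames, s2$frames)  # pure function of inputs
    # every returned index maps into its recorded bin
    expect_equal(h$bin_of_point[s1$frames, , drop = FALSE],
                 unname(s1$bins), ignore_attr = TRUE)
  }
  expect_error(seed_minima_focused(h, 0L), class = "bmbs_config_error")
  expect_error(seed_minima_focused(h, 401L), class = "bmbs_config_error")
})

test_that("seeding strategies rank as expected on a rugged landscape", {
  pts <- synthetic_projection_cloud(3000L, sd = c(0.3, 0.5, 0.8),
                                    weights = c(0.6, 0.3, 0.1), rng_seed = 14L)
  h <- bin_projection(pts, 15L, 15L)
  nrm <- make_normalization(pts, 15L, 15L, rng_seed = 15L)
  ext <- c(range(pts[, 1L]), range(pts[, 2L]))
  seed_emd <- function(s) {
    hs <- bin_projection(pts[s$frames, , drop = FALSE], 15L, 15L,
                         extent = ext, clip = TRUE)
    normalized_emd(hs, h, nrm)
  }
  sm <- seed_minima_focused(h, 50L, rng_seed = 16L)
  sb <- seed_boltzmann(h, 50L, rng_seed = 16L)
  su <- seed_uniform(h, 50L, rng_seed = 16L)
  e <- vapply(list(sm, sb, su), seed_emd, 1)
  # minima-focused tracks the source histogram best
  expect_equal(which.min(e), 1L)
  # uniform spreads over strictly more occupied bins than Boltzmann
  expect_gt(nrow(unique(su$bins)), nrow(unique(sb$bins)))

  # exported structures arrive as a multi-model PDB hand-off
  spec <- synthetic_spec(60L, domain_sizes = c(4L, 4L, 4L), tail_mask = 0L,
                         rng_seed = 17L)
  ens <- generate_synthetic_ensemble(spec)
  he <- bin_projection(matrix(rnorm(120L), 60L, 2L), 5L, 5L)
  se <- seed_uniform(he, 10L, rng_seed = 18L)
  pdb <- tempfile(fileext = ".pdb")
  export_seed_structures(ens, se, pdb)
  expect_equal(sum(grepl("^MODEL", readLines(pdb))), 10L)
})
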