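test_that("sketch sigmoid closed forms hold for both canonical parameter sets", {
  high <- sigmoid_params(20, 12, 10)
  low <- sigmoid_params(1, 2, 10)
  for (p in list(high, low, sigmoid_params(3, 5, 2))) {
    expect_equal(sketch_sigmoid(0, p), 0)
    expect_equal(sketch_sigmoid(p$sigma, p), 0.5)
  }
  # independent scalar arithmetic: sigma=1, a=2, b=10 at D=2
  # 1 - (1 + (2^0.2 - 1) * 4)^(-5) = 0.903066...
  expect_equal(sketch_sigmoid(2, low), 0.9031, tolerance = 1e-4)
  # monotone: non-decreasing everywhere, strictly increasing where the
  # steep high-D sigmoid is resolvable in double precision
  grid <- seq(0, 200, by = 0.5)
  vals <- sketch_sigmoid(grid, high)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(diff(sketch_sigmoid(seq(2, 100, by = 0.5), high)) > 0))
  expect_true(all(diff(sketch_sigmoid(seq(0, 10, by = 0.1), low)) > 0))
  expect_lte(max(vals), 1)
  expect_gt(sketch_sigmoid(1e6, high), 1 - 1e-6)
  expect_error(sketch_sigmoid(-1, low), class = "bmbs_domain_error")
  expect_error(sigmoid_params(0, 1, 1), class = "bmbs_domain_error")
})

test_that("auto loss is the mean Euclidean reconstruction distance", {
  X <- matrix(rnorm(40L), 8L, 5L)
  expect_equal(auto_loss(X, X), 0)
  expect_equal(auto_loss(rbind(c(0, 0, 0)), rbind(c(3, 0, 0))), 3)
  Y <- X + matrix(rnorm(40L, sd = 0.3), 8L, 5L)
  oracle <- mean(vapply(1:8, function(i) sqrt(sum((X[i, ] - Y[i, ])^2)), 1))
  expect_equal(auto_loss(X, Y), oracle, tolerance = 1e-12)
  expect_error(auto_loss(X, X[1:3, ]), class = "bmbs_domain_error")
})

test_that("sketch loss matches hand arithmetic and a double-loop oracle", {
  high <- sigmoid_params(20, 12, 10)
  low <- sigmoid_params(1, 2, 10)
  # every high-D distance at sigma_h and 2D distance at sigma_l -> both
  # sigmoids give 0.5 and the loss vanishes
  Xh <- rbind(c(0, 0), c(20, 0))
  xl <- rbind(c(0, 0), c(1, 0))
  expect_equal(sketch_loss(Xh, xl, high, low), 0)

  # N = 2 with hand-picked distances: 2 ordered pairs, divided by N
  Xh2 <- rbind(c(0, 0), c(10, 0))
  xl2 <- rbind(c(0, 0), c(2, 0))
  hand <- 2 * (sketch_sigmoid(10, high) - sketch_sigmoid(2, low))^2 / 2
  expect_equal(sketch_loss(Xh2, xl2, high, low), hand, tolerance = 1e-12)

  set.seed(8)
  Xb <- matrix(rnorm(60L, sd = 10), 10L, 6L)
  xb <- matrix(rnorm(20L), 10L, 2L)
  oracle <- 0
  for (i in 1:10) for (j in 1:10) if (i != j) {
    dh <- sqrt(sum((Xb[i, ] - Xb[j, ])^2))
    dl <- sqrt(sum((xb[i, ] - xb[j, ])^2))
    oracle <- oracle + (sketch_sigmoid(dh, high) - sketch_sigmoid(dl, low))^2
  }
  expect_equal(sketch_loss(Xb, xb, high, low), oracle / 10, tolerance = 1e-9)
  expect_error(sketch_loss(Xb[1, , drop = FALSE], xb[1, , drop = FALSE],
                           high, low),
               class = "bmbs_domain_error")
})

make_blobs <- function(n_per = 80L, d = 12L, sep = 14, seed = 21L) {
  set.seed(seed)
  centers <- matrix(0, 3L, d)
  centers[1L, 1L] <- sep; centers[2L, 2L] <- sep; centers[3L, 3L] <- -sep
  lab <- rep(1:3, each = n_per)
  list(X = centers[lab, ] + matrix(rnorm(3L * n_per * d), 3L * n_per, d),
       labels = lab)
}

test_that("training is deterministic and the loss decomposition is exact", {
  blobs <- make_blobs()
  hp <- encodermap_hyperparams(n_steps = 60L, n_neurons = 16L,
                               batch_size = 32L, rng_seed = 5L)
  m1 <- train_map(blobs$X, hp)
  m2 <- train_map(blobs$X, hp)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$encoder, m2$encoder)
  h <- m1$history
  expect_lt(max(abs(h[, "total"] -
                    (hp$k_a * h[, "auto"] + hp$k_s * h[, "sketch"] + h[, "reg"]))),
            1e-12)
  # recomputation at the stored parameters reproduces the identity
  ev <- evaluate_losses(m1, blobs$X)
  expect_equal(ev$total, hp$k_a * ev$auto + hp$k_s * ev$sketch + ev$reg,
               tolerance = 1e-12)
})

test_that("with k_s = 0 the model is a plain autoencoder whose error decreases", {
  blobs <- make_blobs(n_per = 60L)
  hp <- encodermap_hyperparams(n_steps = 400L, n_neurons = 24L, k_s = 0,
                               batch_size = 48L, rng_seed = 2L)
  m <- train_map(blobs$X, hp)
  win <- function(i) mean(m$history[((i - 1L) * 100L + 1L):(i * 100L), "auto"])
  wins <- vapply(1:4, win, 1)
  expect_lt(wins[4L], wins[1L])
  expect_true(all(diff(wins) < 0))
})

test_that("projection is a pure function and separates planted structure", {
  blobs <- make_blobs()
  hp <- encodermap_hyperparams(n_steps = 500L, n_neurons = 24L,
                               sig_high = sigmoid_params(14, 12, 10),
                               batch_size = 64L, rng_seed = 9L)
  m <- train_map(blobs$X, hp)
  p1 <- project_map(m, blobs$X)
  p2 <- project_map(m, blobs$X)
  expect_identical(p1, p2)
  # duplicated input row -> duplicated 2D point
  dup <- blobs$X[c(1L, 1L), ]
  pd <- project_map(m, dup)
  expect_identical(pd[1L, ], pd[2L, ])
  # planted states are better separated between than within
  lab <- blobs$labels
  ctrs <- rbind(colMeans(p1[lab == 1L, ]), colMeans(p1[lab == 2L, ]),
                colMeans(p1[lab == 3L, ]))
  intra <- mean(vapply(1:3, function(c) {
    mean(sqrt(rowSums(sweep(p1[lab == c, ], 2L, ctrs[c, ])^2)))
  }, 1))
  inter <- mean(dist(ctrs))
  expect_gt(inter, intra)
  expect_error(project_map(m, blobs$X[, 1:5]), class = "bmbs_domain_error")
})

test_that("trained maps survive serialisation", {
  blobs <- make_blobs(n_per = 30L)
  hp <- encodermap_hyperparams(n_steps = 20L, n_neurons = 8L,
                               batch_size = 16L, rng_seed = 3L)
  m <- train_map(blobs$X, hp)
  path <- tempfile(fileext = ".rds")
  write_map(m, path)
  back <- read_map(path)
  expect_identical(project_map(back, blobs$X), project_map(m, blobs$X))
})
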