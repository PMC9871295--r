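test_that("partition validation enforces disjointness, size and masking rules", {
  expect_s3_class(domain_partition(list(0:1, 2:3)), "bmbs_partition")
  expect_error(domain_partition(list(0:1)), class = "bmbs_config_error")
  expect_error(domain_partition(list(0:2, 2:4)), class = "bmbs_config_error")
  # masking a whole domain away is a configuration error
  expect_error(domain_partition(list(0:1, 2:3), masked = 0:1),
               class = "bmbs_config_error")
  p <- tri_ub_partition()
  expect_equal(n_domains(p), 3L)
  expect_equal(vapply(1:3, function(i) length(unmasked_residues(p, i)), 1L),
               rep(72L, 3L))
})

test_that("partition config files round-trip 1-based biology numbering", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c(
    "# tri-ub-like chain",
    "index_base = 1",
    "domain distal = 1-76",
    "domain middle = 77-152",
    "domain proximal = 153-228",
    "mask = 73-76, 149-152, 225-228"
  ), cfg)
  p <- read_partition_config(cfg)
  expect_identical(p$domains, tri_ub_partition()$domains)
  expect_identical(p$masked, tri_ub_partition()$masked)
  expect_error(read_partition_config(tempfile()), class = "bmbs_config_error")
  bad <- tempfile(fileext = ".cfg")
  writeLines("domain A = 1-x", bad)
  expect_error(read_partition_config(bad), class = "bmbs_config_error")
})

test_that("multi-model PDB and CSV tables load with the expected shapes", {
  # 3-model PDB of a 6-residue toy chain
  ens0 <- toy_ensemble(3L)
  pdb <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens0, pdb)
  ens <- load_ensemble(pdb, partition = toy_partition())
  expect_equal(n_frames(ens), 3L)
  expect_equal(dim(ens$coords)[2L], 6L)

  # CSV with 12 coordinate columns (4 sites), 10 rows
  csv <- tempfile(fileext = ".csv")
  m <- matrix(round(rnorm(120), 3), 10L, 12L)
  write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  ens2 <- load_ensemble(csv, partition = domain_partition(list(0:1, 2:3)))
  expect_equal(n_frames(ens2), 10L)
  expect_equal(dim(ens2$coords)[2L], 4L)

  # partition referencing an out-of-range residue
  expect_error(
    load_ensemble(csv, partition = domain_partition(list(0:1, c(2L, 99L)))),
    class = "bmbs_config_error")
  # unknown extension
  xtc <- tempfile(fileext = ".xtc")
  writeLines("x", xtc)
  expect_error(load_ensemble(xtc, partition = toy_partition()),
               class = "bmbs_format_error")
})

test_that("PDB round trip preserves coordinates to format precision", {
  spec <- synthetic_spec(4L, domain_sizes = c(5L, 5L, 5L), tail_mask = 0L,
                         rng_seed = 8L)
  ens <- generate_synthetic_ensemble(spec)
  pdb <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, pdb)
  back <- load_ensemble(pdb, partition = ens$partition)
  # PDB stores Angstrom at 3 decimals -> 1e-4 nm round-trip precision
  expect_lt(max(abs(back$coords - ens$coords)), 1e-4)
})

test_that("GRO topologies are read as nm with backbone-bead selection", {
  gro <- tempfile(fileext = ".gro")
  writeLines(c(
    "toy chain",
    "    4",
    "    1ALA     BB    1   0.000   0.000   0.000",
    "    2ALA     BB    2   1.000   0.000   0.000",
    "    3ALA     BB    3   2.000   0.000   0.000",
    "    4ALA     BB    4   3.000   0.500   0.000",
    "   5.00000   5.00000   5.00000"
  ), gro)
  ens <- load_ensemble(gro, partition = domain_partition(list(0:1, 2:3)))
  expect_equal(n_frames(ens), 1L)
  expect_equal(ens$coords[1L, 2L, 1L], 1.0)
})

test_that("CoG distances: hand value, rigid invariance, planted contact range", {
  # two single-site domains 1 nm apart (third domain far away)
  coords <- array(0, dim = c(1L, 3L, 3L))
  coords[1L, 2L, 1L] <- 1
  coords[1L, 3L, 1L] <- 10
  ens <- ensemble(coords, domain_partition(list(0L, 1L, 2L)))
  cd <- cog_distances(ens)
  expect_equal(cd[1L, 1L, 2L], 1.0)
  expect_equal(cd[1L, 2L, 1L], 1.0)
  expect_equal(diag(cd[1L, , ]), rep(0, 3L), ignore_attr = TRUE)

  # invariance under random rigid transforms
  spec <- synthetic_spec(5L, domain_sizes = c(6L, 6L, 6L), tail_mask = 0L,
                         rng_seed = 2L)
  ens2 <- generate_synthetic_ensemble(spec)
  cd2 <- cog_distances(ens2)
  set.seed(11)
  for (r in 1:5) {
    R <- rand_rotation()
    tr <- runif(3L, -5, 5)
    moved <- ens2
    for (f in seq_len(n_frames(ens2)))
      moved$coords[f, , ] <- ens2$coords[f, , ] %*% R +
        matrix(tr, dim(ens2$coords)[2L], 3L, byrow = TRUE)
    expect_lt(max(abs(cog_distances(moved) - cd2)), 1e-9)
  }

  # collapsed-state frames sit at the planted contact geometry
  spc <- synthetic_spec(30L, state_weights = c(collapsed = 1),
                        domain_sizes = c(8L, 8L, 8L), tail_mask = 0L,
                        noise_sd = 0.01, rng_seed = 3L)
  ens3 <- generate_synthetic_ensemble(spc)
  cd3 <- cog_distances(ens3)
  offdiag <- cbind(cd3[, 1L, 2L], cd3[, 1L, 3L], cd3[, 2L, 3L])
  expect_true(all(abs(offdiag - spc$contact_nm) < 0.2))
})

test_that("synthetic generator is deterministic and honours its spec", {
  spec <- synthetic_spec(50L, domain_sizes = c(6L, 6L, 6L), tail_mask = 0L,
                         rng_seed = 7L)
  e1 <- generate_synthetic_ensemble(spec)
  e2 <- generate_synthetic_ensemble(spec)
  expect_identical(e1$coords, e2$coords)
  expect_identical(attr(e1, "state_labels"), attr(e2, "state_labels"))

  # zero noise: every frame is an exact rigid copy of its state template
  spc0 <- synthetic_spec(10L, state_weights = c(collapsed = 1), noise_sd = 0,
                         domain_sizes = c(5L, 5L, 5L), tail_mask = 0L,
                         rng_seed = 1L)
  e0 <- generate_synthetic_ensemble(spc0)
  tmpl <- attr(e0, "templates")$collapsed
  for (f in seq_len(10L))
    expect_lt(kabsch_rmsd(e0$coords[f, , ], tmpl), 1e-9)

  # empirical state counts within 3 sigma of the multinomial expectation
  spc <- synthetic_spec(1000L, domain_sizes = c(5L, 5L, 5L), tail_mask = 0L,
                        rng_seed = 1L)
  eb <- generate_synthetic_ensemble(spc)
  counts <- table(factor(attr(eb, "state_labels"),
                         levels = names(spc$state_weights)))
  for (s in names(spc$state_weights)) {
    p <- spc$state_weights[[s]]
    expect_lt(abs(counts[[s]] - 1000 * p), 3 * sqrt(1000 * p * (1 - p)) + 1)
  }

  # invalid specs
  expect_error(synthetic_spec(10L, state_weights = c(open = 0.5)),
               class = "bmbs_config_error")
  expect_error(synthetic_spec(10L, noise_sd = -1), class = "bmbs_config_error")
})
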