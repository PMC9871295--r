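# Independent oracles and small fixture builders used across the suite.

# All permutations of 1..n as rows (n <= 7 in the tests).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# Exact transport cost between two integer-count histograms by grain
# enumeration: expand each histogram into unit grains and minimise the
# assignment cost over all permutations. With unit masses an optimal
# transport plan is an assignment, so this is exact and fully independent
# of the package's solver. Returns cost per unit mass (histograms are
# treated as probability distributions, mirroring raw_emd).
grain_emd_oracle <- function(counts_p, counts_q, centers) {
  sup <- rep(seq_along(counts_p), counts_p)
  dem <- rep(seq_along(counts_q), counts_q)
  G <- length(sup)
  stopifnot(G == length(dem), G <= 7L)
  Cg <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G))
    Cg[i, j] <- sqrt(sum((centers[sup[i], ] - centers[dem[j], ])^2))
  P <- all_perms(G)
  lin <- matrix(Cg[cbind(rep(seq_len(G), times = nrow(P)), as.vector(t(P)))],
                ncol = G, byrow = TRUE)
  min(rowSums(lin)) / G
}

# Histogram with prescribed integer counts: points are placed exactly at
# the bin centres of a fixed grid and passed through bin_projection, so the
# object is built through the public API.
hist_from_counts <- function(counts) {
  nx <- nrow(counts); ny <- ncol(counts)
  extent <- c(0, nx, 0, ny)
  cx <- (seq_len(nx) - 0.5)
  cy <- (seq_len(ny) - 0.5)
  pts <- do.call(rbind, lapply(seq_len(nx), function(i) {
    do.call(rbind, lapply(seq_len(ny), function(j) {
      k <- counts[i, j]
      if (k > 0) matrix(rep(c(cx[i], cy[j]), k), k, 2L, byrow = TRUE)
    }))
  }))
  bin_projection(pts, nx, ny, extent = extent)
}

# Random integer-count histogram on an nx x ny grid with a fixed total.
random_counts <- function(nx, ny, total) {
  counts <- matrix(0L, nx, ny)
  idx <- sample.int(nx * ny, total, replace = TRUE)
  for (i in idx) counts[i] <- counts[i] + 1L
  counts
}

# Uniform random rotation for invariance tests.
rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9L), 3L, 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Direct numerical minimisation of RMSD over rotations (axis-angle
# parameterisation, multi-start Nelder-Mead): an oracle for the closed-form
# superposition that shares no code with it.
rmsd_orientation_oracle <- function(A, B, n_starts = 12L) {
  A0 <- sweep(A, 2L, colMeans(A))
  B0 <- sweep(B, 2L, colMeans(B))
  f <- function(w) {
    th <- sqrt(sum(w^2))
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3L, 3L,
                byrow = TRUE)
    R <- diag(3L) + (if (th > 1e-12) sin(th) / th else 1) * K +
      (if (th > 1e-12) (1 - cos(th)) / th^2 else 0.5) * (K %*% K)
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  best <- Inf
  for (r in seq_len(n_starts)) best <- min(best, stats::optim(rnorm(3L), f)$value)
  best
}

# Small three-domain toy partition (2/2/2 residues, no masking).
toy_partition <- function() domain_partition(list(0:1, 2:3, 4:5))

# Tiny deterministic ensemble: n frames of a 6-site chain.
toy_ensemble <- function(n = 3L) {
  coords <- array(0, dim = c(n, 6L, 3L))
  base <- cbind(seq(0, 2.5, length.out = 6L), 0, 0)
  for (f in seq_len(n)) coords[f, , ] <- base + (f - 1L) * 0.1
  ensemble(coords, toy_partition(), source_tag = "toy")
}
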