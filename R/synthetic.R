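#' Specification for a synthetic three-domain ensemble
#'
#' Defines the study conditions for the planted-state generator: a chain of
#' three rigid template domains placed in one of five metastable arrangements
#' per frame. The states mirror the regions seen in 2D conformational maps
#' of tri-ubiquitin-like chains: fully `open` (extended) chains, a fully
#' `collapsed` arrangement with all three moieties in contact, and the three
#' pairwise-contact states `AB_contact`, `BC_contact`, `AC_contact`.
#'
#' State geometries are parameterised by two length scales: a contact
#' CoG-CoG distance (default 2.5 nm) and an open distance (default 6 nm).
#'
#' @param n_frames Number of frames to generate.
#' @param state_weights Named probabilities over the five states; must sum
#'   to 1. Default uniform.
#' @param domain_sizes Residues per domain (length 3, default `c(76,76,76)`).
#' @param noise_sd Isotropic Gaussian site jitter, nm (default 0.03).
#' @param rng_seed Integer seed; the generator is deterministic given it.
#' @param tail_mask Trailing residues masked per domain (default 4, set 0
#'   for small toy chains).
#' @param contact_nm,open_nm The two CoG length scales (nm).
#' @return An object of class `bmbs_synth_spec`.
#' @export
synthetic_spec <- function(n_frames,
                           state_weights = c(open = 0.2, collapsed = 0.2,
                                             AB_contact = 0.2, BC_contact = 0.2,
                                             AC_contact = 0.2),
                           domain_sizes = c(76L, 76L, 76L),
                           noise_sd = 0.03,
                           rng_seed = 1L,
                           tail_mask = 4L,
                           contact_nm = 2.5,
                           open_nm = 6) {
  states <- c("open", "collapsed", "AB_contact", "BC_contact", "AC_contact")
  w <- setNames(rep(0, 5L), states)
  if (is.null(names(state_weights)) || !all(names(state_weights) %in% states))
    stop_config(paste("state_weights names must be among:",
                      paste(states, collapse = ", ")))
  w[names(state_weights)] <- state_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop_config("state_weights must be non-negative and sum to 1")
  if (length(domain_sizes) != 3L || any(domain_sizes < 1L))
    stop_config("domain_sizes must be 3 positive integers")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (n_frames < 1L) stop_config("n_frames must be >= 1")
  if (tail_mask * 2L >= min(domain_sizes))
    tail_mask <- 0L
  structure(
    list(n_frames = as.integer(n_frames), state_weights = w,
         domain_sizes = as.integer(domain_sizes), noise_sd = noise_sd,
         rng_seed = as.integer(rng_seed), tail_mask = as.integer(tail_mask),
         contact_nm = contact_nm, open_nm = open_nm),
    class = "bmbs_synth_spec"
  )
}

# Deterministic compact template for one domain: points on a spherical
# spiral of ~1.2 nm radius with mild radial modulation. Purely geometric;
# no RNG so templates are identical across calls.
domain_template <- function(n) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  zfrac <- if (n > 1) 1 - 2 * (i - 1) / (n - 1) else 0
  r <- 1.2 * (0.75 + 0.25 * ((i * 0.37) %% 1))
  theta <- golden * i
  rho <- sqrt(pmax(1 - zfrac^2, 0))
  cbind(r * rho * cos(theta), r * rho * sin(theta), r * zfrac)
}

# CoG anchor positions of the three domains for each planted state.
state_anchor <- function(state, contact, open) {
  switch(state,
    open = rbind(c(-open, 0, 0), c(0, 0, 0), c(open, 0, 0)),
    collapsed = {
      h <- contact * sqrt(3) / 2
      rbind(c(-contact / 2, 0, 0), c(contact / 2, 0, 0), c(0, h, 0))
    },
    AB_contact = rbind(c(contact, 0, 0), c(0, 0, 0), c(-open, 0, 0)),
    BC_contact = rbind(c(open, 0, 0), c(0, 0, 0), c(-contact, 0, 0)),
    AC_contact = {
      d <- 0.75 * open
      rbind(c(d, contact / 2, 0), c(0, 0, 0), c(d, -contact / 2, 0))
    },
    stop_domain(paste("unknown state:", state))
  )
}

# Rigid assembly of the three templates for one state (pre-rotation).
state_template_coords <- function(spec, resolution = "cg") {
  templates <- lapply(spec$domain_sizes, domain_template)
  if (resolution == "atomistic") {
    # Back-mapped atomistic sites sit near, not exactly at, the bead
    # positions: apply a fixed deterministic deformation per domain.
    templates <- lapply(seq_along(templates), function(i) {
      tp <- templates[[i]]
      ph <- seq_len(nrow(tp)) * (1.7 + 0.31 * i)
      tp + 0.05 * cbind(sin(ph), cos(1.3 * ph), sin(0.7 * ph + i))
    })
  }
  states <- names(spec$state_weights)
  out <- lapply(states, function(s) {
    anch <- state_anchor(s, spec$contact_nm, spec$open_nm)
    do.call(rbind, lapply(1:3, function(d) {
      tp <- templates[[d]]
      sweep(tp, 2L, colMeans(tp)) + matrix(anch[d, ], nrow(tp), 3L, byrow = TRUE)
    }))
  })
  names(out) <- states
  out
}

#' Generate a synthetic multi-domain ensemble with planted states
#'
#' Each frame is drawn from one of five planted metastable states (see
#' [synthetic_spec()]): the state's rigid template assembly is given a
#' random global rotation and translation, then isotropic Gaussian jitter of
#' sd `noise_sd` is added per site. With `noise_sd = 0` every frame is an
#' exact rigid copy of its state template. The per-frame state labels and
#' the templates are attached as attributes `state_labels` and `templates`
#' for use as test oracles.
#'
#' @param spec A [synthetic_spec()].
#' @param resolution `"cg"` (one bead per residue at the template position)
#'   or `"atomistic"` (same site count with a fixed small deformation of the
#'   templates, emulating back-mapped C-alpha positions).
#' @param dt_ps Optional frame spacing in ps; sets `frame_times`.
#' @return A `bmbs_ensemble` with attributes `state_labels` (character per
#'   frame) and `templates` (named list of site-coordinate matrices).
#' @export
generate_synthetic_ensemble <- function(spec, resolution = c("cg", "atomistic"),
                                        dt_ps = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(spec, "bmbs_synth_spec"))
  tmpl <- state_template_coords(spec, resolution)
  states <- names(spec$state_weights)
  n <- spec$n_frames
  ns <- sum(spec$domain_sizes)
  coords <- array(NA_real_, dim = c(n, ns, 3L))
  labels <- character(n)
  with_seed(spec$rng_seed, {
    labels <- sample(states, n, replace = TRUE, prob = spec$state_weights)
    for (f in seq_len(n)) {
      xyz <- tmpl[[labels[f]]]
      R <- random_rotation()
      tr <- runif(3L, -2, 2)
      xyz <- xyz %*% R + matrix(tr, ns, 3L, byrow = TRUE)
      if (spec$noise_sd > 0)
        xyz <- xyz + matrix(rnorm(ns * 3L, sd = spec$noise_sd), ns, 3L)
      coords[f, , ] <- xyz
    }
  })
  offs <- cumsum(c(0L, spec$domain_sizes[-3L]))
  doms <- lapply(1:3, function(d) seq.int(offs[d], offs[d] + spec$domain_sizes[d] - 1L))
  masked <- if (spec$tail_mask > 0L)
    unlist(lapply(doms, function(d) tail(d, spec$tail_mask))) else integer()
  part <- domain_partition(doms, masked)
  ens <- ensemble(coords, part,
                  frame_times = if (!is.null(dt_ps)) (seq_len(n) - 1L) * dt_ps,
                  source_tag = paste0("synthetic-", resolution))
  attr(ens, "state_labels") <- labels
  attr(ens, "templates") <- tmpl
  attr(ens, "spec") <- spec
  ens
}

#' Synthetic 2D point cloud with planted modes
#'
#' A mixture of isotropic Gaussian modes in the plane, used as a stand-in
#' for a reference 2D projection (e.g. a coarse-grained conformational map)
#' when exercising binning, seeding and earth-mover's-distance analyses
#' without running the full featurise/train pipeline.
#'
#' @param n Number of points.
#' @param modes Matrix `m x 2` of mode centres. Default: three modes in a
#'   "T" arrangement.
#' @param weights Mode weights (default uniform).
#' @param sd Mode standard deviation(s), recycled over modes.
#' @param rng_seed Integer seed.
#' @return A `n x 2` matrix with attribute `mode_labels`.
#' @export
synthetic_projection_cloud <- function(n, modes = NULL, weights = NULL,
                                       sd = 0.5, rng_seed = 1L) {
  if (is.null(modes))
    modes <- rbind(c(-3, 2), c(3, 2), c(0, -2.5))
  m <- nrow(modes)
  weights <- weights %||% rep(1 / m, m)
  sd <- rep_len(sd, m)
  with_seed(rng_seed, {
    lab <- sample.int(m, n, replace = TRUE, prob = weights)
    pts <- modes[lab, , drop = FALSE] +
      cbind(rnorm(n, sd = sd[lab]), rnorm(n, sd = sd[lab]))
  })
  attr(pts, "mode_labels") <- lab
  pts
}

#' Synthetic drifting 2D trajectories
#'
#' Emulates sets of short simulations whose 2D projections relax from their
#' seed points toward (or away from) target attractors, for exercising
#' time-resolved convergence monitoring. Each trajectory starts at a seed
#' point and relaxes exponentially toward its target with rate
#' `rate_per_ns`, plus Gaussian wander.
#'
#' @param seeds Matrix `n_traj x 2` of starting points.
#' @param targets Matrix `n_traj x 2` of per-trajectory attractors.
#' @param n_frames Frames per trajectory.
#' @param dt_ps Frame spacing (ps).
#' @param rate_per_ns Relaxation rate (1/ns).
#' @param wander_sd Per-frame Gaussian wander sd.
#' @param rng_seed Integer seed.
#' @return List of `n_traj` matrices `n_frames x 2` with attribute
#'   `times_ps` on each.
#' @export
synthetic_drift_projections <- function(seeds, targets, n_frames, dt_ps = 250,
                                        rate_per_ns = 0.2, wander_sd = 0.05,
                                        rng_seed = 1L) {
  stopifnot(nrow(seeds) == nrow(targets))
  times <- (seq_len(n_frames) - 1L) * dt_ps
  frac <- 1 - exp(-rate_per_ns * times / 1000)
  with_seed(rng_seed, {
    lapply(seq_len(nrow(seeds)), function(i) {
      base <- outer(1 - frac, seeds[i, ]) + outer(frac, targets[i, ])
      pts <- base + matrix(rnorm(n_frames * 2L, sd = wander_sd), n_frames, 2L)
      attr(pts, "times_ps") <- times
      pts
    })
  })
}
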