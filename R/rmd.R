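#' Pairwise Euclidean distance matrix between two site sets
#'
#' Entry (i, j) is the distance between site i of P and site j of Q, in the
#' units of the inputs (nm throughout this package).
#'
#' @param sites_P,sites_Q Numeric matrices `n x 3` of site coordinates.
#' @return `nrow(sites_P) x nrow(sites_Q)` matrix.
#' @export
pairwise_distance_matrix <- function(sites_P, sites_Q) {
  sites_P <- rbind(sites_P); sites_Q <- rbind(sites_Q)
  if (nrow(sites_P) == 0L || nrow(sites_Q) == 0L)
    stop_config("empty site set")
  cross_dist(sites_P, sites_Q)
}

#' Row-wise and column-wise minima of a distance matrix
#'
#' For a domain-pair distance matrix D_(P,Q), the row minima are the
#' residue-wise minimal distances from each residue of P to domain Q, and
#' the column minima those from each residue of Q to domain P. Both vectors
#' share the same global minimum (the closest approach of the two domains).
#'
#' @param distance_matrix Numeric matrix.
#' @return List with components `row_min` and `col_min`.
#' @export
residue_wise_minima <- function(distance_matrix) {
  if (length(distance_matrix) == 0L) stop_config("empty distance matrix")
  distance_matrix <- rbind(distance_matrix)
  list(row_min = apply(distance_matrix, 1L, min),
       col_min = apply(distance_matrix, 2L, min))
}

# Ordered sequence of unordered domain pairs. Three domains follow the
# conventional (A,B), (B,C), (A,C) order used for ubiquitin trimers; for
# other domain counts pairs are lexicographic. Each unordered pair (P,Q)
# contributes blocks P_Q (row minima) then Q_P (column minima).
domain_pair_order <- function(D) {
  if (D == 3L) return(list(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
  prs <- list()
  for (i in seq_len(D - 1L)) for (j in (i + 1L):D)
    prs[[length(prs) + 1L]] <- c(i, j)
  prs
}

#' Residue-wise minimal-distance (RMD) vector of one frame
#'
#' The collective variable shared between coarse-grained and atomistic
#' resolutions: for every unordered domain pair (P, Q), the per-residue
#' minimal distances P_Q (each residue of P to any site of Q) followed by
#' Q_P, concatenated over all pairs. Masked residues contribute no entries.
#' For three domains of 72 unmasked residues each this gives the canonical
#' 432-dimensional vector, in block order A_B, B_A, B_C, C_B, A_C, C_A.
#'
#' @param frame_coords Numeric `sites x 3` matrix for one frame (nm).
#' @param partition A [domain_partition()].
#' @param site_residue Site-to-residue map (0-based); default one site per
#'   consecutive residue.
#' @return Numeric vector of length `(D-1) * sum(n_d)` with attribute
#'   `block_index` (named list of index ranges per block).
#' @export
rmd_vector <- function(frame_coords, partition, site_residue = NULL) {
  if (is.null(site_residue)) site_residue <- seq_len(nrow(frame_coords)) - 1L
  D <- n_domains(partition)
  sites <- lapply(seq_len(D), function(i) {
    idx <- match(unmasked_residues(partition, i), site_residue)
    if (anyNA(idx)) stop_config("domain residues missing from site map")
    idx
  })
  vals <- numeric(0)
  block_index <- list()
  for (pr in domain_pair_order(D)) {
    P <- pr[1L]; Q <- pr[2L]
    dm <- cross_dist(frame_coords[sites[[P]], , drop = FALSE],
                     frame_coords[sites[[Q]], , drop = FALSE])
    mins <- residue_wise_minima(dm)
    lp <- partition$labels[P]; lq <- partition$labels[Q]
    block_index[[paste0(lp, "_", lq)]] <-
      seq.int(length(vals) + 1L, length.out = length(mins$row_min))
    vals <- c(vals, mins$row_min)
    block_index[[paste0(lq, "_", lp)]] <-
      seq.int(length(vals) + 1L, length.out = length(mins$col_min))
    vals <- c(vals, mins$col_min)
  }
  attr(vals, "block_index") <- block_index
  vals
}

#' Featurise an ensemble into an RMD feature matrix
#'
#' One row per frame, columns are the concatenated RMD blocks (see
#' [rmd_vector()]). The block layout and source tag are carried as
#' attributes; concatenating ensembles that share a partition yields
#' identical widths, which is what makes the feature resolution-agnostic.
#'
#' @param ens A `bmbs_ensemble`.
#' @return Numeric matrix `frames x n_features` with attributes
#'   `block_index` and `source_tag`.
#' @export
featurize_ensemble <- function(ens) {
  nf <- n_frames(ens)
  first <- rmd_vector(ens$coords[1L, , , drop = TRUE], ens$partition,
                      ens$site_residue)
  out <- matrix(NA_real_, nf, length(first))
  out[1L, ] <- first
  if (nf > 1L) for (f in 2:nf) {
    out[f, ] <- rmd_vector(ens$coords[f, , , drop = TRUE], ens$partition,
                           ens$site_residue)
  }
  attr(out, "block_index") <- attr(first, "block_index")
  attr(out, "source_tag") <- ens$source_tag
  out
}

#' Write / read a feature matrix as TSV
#'
#' Columns are named by RMD block and within-block position so the block
#' index survives a round trip.
#'
#' @param features Matrix from [featurize_ensemble()].
#' @param path File path.
#' @return `write_features`: `path` invisibly. `read_features`: the matrix
#'   with its `block_index` attribute restored.
#' @export
write_features <- function(features, path) {
  bi <- attr(features, "block_index")
  cn <- if (!is.null(bi)) {
    nm <- character(ncol(features))
    for (b in names(bi)) nm[bi[[b]]] <- paste0(b, ".", seq_along(bi[[b]]))
    nm
  } else paste0("f", seq_len(ncol(features)))
  df <- as.data.frame(features)
  names(df) <- cn
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  blocks <- sub("\\.[0-9]+$", "", colnames(m))
  if (!anyNA(blocks) && all(nzchar(blocks))) {
    bi <- split(seq_len(ncol(m)), factor(blocks, levels = unique(blocks)))
    attr(m, "block_index") <- bi
  }
  dimnames(m) <- NULL
  m
}
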