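#' Construct a conformational ensemble
#'
#' The universal input container: per-frame coordinates of labelled backbone
#' sites (one C-alpha atom or backbone bead per residue), plus the domain
#' partition. Coordinates are stored in nm.
#'
#' @param coords Numeric array `frames x sites x 3` (nm), or a `frames x
#'   (3*sites)` matrix in site-major xyz column order.
#' @param partition A [domain_partition()].
#' @param site_residue Integer vector mapping each site (column of `coords`)
#'   to its 0-based residue index. Defaults to `0:(n_sites-1)` (one site per
#'   consecutive residue).
#' @param frame_times Optional numeric vector of frame times in ps, strictly
#'   increasing.
#' @param source_tag Free-text provenance tag.
#' @return An object of class `bmbs_ensemble`.
#' @export
ensemble <- function(coords, partition, site_residue = NULL,
                     frame_times = NULL, source_tag = "") {
  if (is.matrix(coords)) {
    if (ncol(coords) %% 3L != 0L)
      stop_format("coordinate matrix must have 3*n_sites columns")
    ns <- ncol(coords) %/% 3L
    arr <- array(NA_real_, dim = c(nrow(coords), ns, 3L))
    for (k in 1:3) arr[, , k] <- coords[, seq(k, ncol(coords), by = 3L), drop = FALSE]
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop_format("coords must be a frames x sites x 3 array")
  if (!all(is.finite(coords))) stop_format("non-finite coordinates")
  n_sites <- dim(coords)[2L]
  if (is.null(site_residue)) site_residue <- seq_len(n_sites) - 1L
  site_residue <- as.integer(site_residue)
  if (length(site_residue) != n_sites)
    stop_config("site_residue length must equal number of sites")
  need <- partition_residues(partition)
  missing_res <- setdiff(need, site_residue)
  if (length(missing_res))
    stop_config(paste0("partition references residues absent from topology: ",
                       paste(head(missing_res, 5L), collapse = ", ")))
  if (!is.null(frame_times)) {
    if (length(frame_times) != dim(coords)[1L])
      stop_config("frame_times length must equal number of frames")
    if (any(diff(frame_times) <= 0))
      stop_config("frame_times must be strictly increasing")
  }
  structure(
    list(coords = coords, partition = partition,
         site_residue = site_residue, frame_times = frame_times,
         source_tag = source_tag),
    class = "bmbs_ensemble"
  )
}

#' @export
print.bmbs_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Ensemble: %d frames, %d sites, %d domains%s\n",
              d[1L], d[2L], n_domains(x$partition),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens A `bmbs_ensemble`.
#' @return Integer.
#' @export
n_frames <- function(ens) dim(ens$coords)[1L]

# Site indices (into coords columns) of the unmasked residues of domain i,
# in residue order.
domain_sites <- function(ens, i) {
  res <- unmasked_residues(ens$partition, i)
  idx <- match(res, ens$site_residue)
  if (anyNA(idx)) stop_config("domain residues missing from site map")
  idx
}

# Fixed-width GRO reader (nm units already); returns list(coords matrix
# n_atoms x 3, resno, atom names). Minimal: single-frame topology use only.
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_format("truncated GRO file")
  n_atoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n_atoms) || length(lines) < 2L + n_atoms)
    stop_format("malformed GRO file")
  rows <- lines[3:(2L + n_atoms)]
  resno <- as.integer(substr(rows, 1L, 5L))
  aname <- trimws(substr(rows, 11L, 15L))
  x <- as.numeric(substr(rows, 21L, 28L))
  y <- as.numeric(substr(rows, 29L, 36L))
  z <- as.numeric(substr(rows, 37L, 44L))
  if (anyNA(c(x, y, z))) stop_format("unparseable GRO coordinates")
  list(xyz = cbind(x, y, z), resno = resno, aname = aname)
}

# Pick one backbone site per residue from atom names: prefer CA (atomistic),
# then BB (MARTINI backbone bead), else the first atom of the residue.
select_backbone <- function(aname, resno) {
  idx <- seq_along(aname)
  pick <- tapply(idx, resno, function(ii) {
    ca <- ii[aname[ii] == "CA"]
    if (length(ca)) return(ca[1L])
    bb <- ii[aname[ii] == "BB"]
    if (length(bb)) return(bb[1L])
    ii[1L]
  })
  sel <- as.integer(pick[order(as.integer(names(pick)))])
  sel[order(sel)]
}

#' Load an ensemble from trajectory or table files
#'
#' Supported inputs: a multi-model PDB (topology_path only), a PDB/GRO
#' topology plus a DCD trajectory, or a plain columnar CSV/TSV table of
#' per-frame coordinates (site-major xyz column order: x1,y1,z1,x2,...).
#' One backbone site per residue is selected (C-alpha for atomistic models,
#' the BB bead for MARTINI-style coarse-grained ones). PDB/DCD coordinates
#' (Angstrom) are converted to nm; GRO and tables are read as nm.
#'
#' @param topology_path Path to PDB/GRO topology, multi-model PDB, or
#'   CSV/TSV coordinate table.
#' @param trajectory_path Optional DCD trajectory path.
#' @param partition A [domain_partition()] or path to a partition config
#'   file ([read_partition_config()]).
#' @param frame_times,source_tag Passed to [ensemble()].
#' @return A `bmbs_ensemble`.
#' @export
load_ensemble <- function(topology_path, trajectory_path = NULL, partition,
                          frame_times = NULL, source_tag = NULL) {
  if (!file.exists(topology_path))
    stop_config(paste("no such file:", topology_path))
  if (is.character(partition)) partition <- read_partition_config(partition)
  ext <- tolower(tools::file_ext(topology_path))
  tag <- source_tag %||% basename(topology_path)

  if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    tab <- as.matrix(read.table(topology_path, sep = sep, header = FALSE,
                                comment.char = "#"))
    if (!is.numeric(tab) || ncol(tab) %% 3L != 0L)
      stop_format("coordinate table must be numeric with 3*n_sites columns")
    ns <- ncol(tab) %/% 3L
    coords <- array(NA_real_, dim = c(nrow(tab), ns, 3L))
    for (k in 1:3) coords[, , k] <- tab[, seq(k, ncol(tab), by = 3L), drop = FALSE]
    return(ensemble(coords, partition, frame_times = frame_times,
                    source_tag = tag))
  }

  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
    aname <- pdb$atom$elety
    resno <- pdb$atom$resno
    sel <- select_backbone(aname, resno)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    nfr <- nrow(xyz)
    take <- as.vector(t(outer(sel, 1:3, function(i, k) 3L * (i - 1L) + k)))
    coords <- array(NA_real_, dim = c(nfr, length(sel), 3L))
    for (f in seq_len(nfr)) {
      coords[f, , ] <- matrix(xyz[f, take], ncol = 3L, byrow = TRUE) / 10
    }
    site_res <- resno[sel] - min(resno[sel])  # 0-based chain positions
    if (!is.null(trajectory_path)) {
      text <- tolower(tools::file_ext(trajectory_path))
      if (text != "dcd")
        stop_format(paste("unsupported trajectory format:", text,
                          "(supported: dcd, or a multi-model pdb topology)"))
      trj <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      nfr <- nrow(trj)
      coords <- array(NA_real_, dim = c(nfr, length(sel), 3L))
      for (f in seq_len(nfr)) {
        coords[f, , ] <- matrix(trj[f, take], ncol = 3L, byrow = TRUE) / 10
      }
    }
    return(ensemble(coords, partition, site_residue = site_res,
                    frame_times = frame_times, source_tag = tag))
  }

  if (ext == "gro") {
    g <- read_gro(topology_path)
    sel <- select_backbone(g$aname, g$resno)
    coords <- array(g$xyz[sel, , drop = FALSE], dim = c(1L, length(sel), 3L))
    coords[1L, , ] <- g$xyz[sel, ]
    site_res <- g$resno[sel] - min(g$resno[sel])
    if (!is.null(trajectory_path)) {
      if (tolower(tools::file_ext(trajectory_path)) != "dcd")
        stop_format("GRO topologies pair with DCD trajectories only")
      trj <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      take <- as.vector(t(outer(sel, 1:3, function(i, k) 3L * (i - 1L) + k)))
      nfr <- nrow(trj)
      coords <- array(NA_real_, dim = c(nfr, length(sel), 3L))
      for (f in seq_len(nfr)) {
        coords[f, , ] <- matrix(trj[f, take], ncol = 3L, byrow = TRUE) / 10
      }
    }
    return(ensemble(coords, partition, site_residue = site_res,
                    frame_times = frame_times, source_tag = tag))
  }

  stop_format(paste0("unknown topology format: .", ext,
                     " (supported: pdb, gro, csv, tsv)"))
}

#' Write an ensemble as a multi-model C-alpha PDB
#'
#' One `MODEL` block per frame, one `CA` atom per site, coordinates written
#' in Angstrom. Suitable as hand-off format for external back-mapping tools
#' and for round-tripping through [load_ensemble()].
#'
#' @param ens A `bmbs_ensemble`.
#' @param path Output path.
#' @param frames Optional frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(ens))
  con <- file(path, "w")
  on.exit(close(con))
  ns <- dim(ens$coords)[2L]
  for (mi in seq_along(frames)) {
    f <- frames[mi]
    writeLines(sprintf("MODEL     %4d", mi), con)
    xyz <- ens$coords[f, , , drop = TRUE] * 10  # nm -> Angstrom
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(ns), ens$site_residue + 1L, xyz[, 1L], xyz[, 2L], xyz[, 3L])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Pairwise domain centre-of-geometry distances
#'
#' For each frame, the symmetric matrix of Euclidean distances between the
#' centres of geometry of all domain pairs, computed over unmasked sites
#' only. This is the observable used to colour 2D conformational maps by
#' inter-moiety separation (open vs. contact states).
#'
#' @param ens A `bmbs_ensemble`.
#' @return Array `frames x D x D` (nm) with zero diagonals; domain labels on
#'   the dimnames.
#' @export
cog_distances <- function(ens) {
  D <- n_domains(ens$partition)
  if (D < 2L) stop_config("need at least 2 domains")
  sites <- lapply(seq_len(D), function(i) domain_sites(ens, i))
  nf <- n_frames(ens)
  out <- array(0, dim = c(nf, D, D),
               dimnames = list(NULL, ens$partition$labels, ens$partition$labels))
  cogs <- array(NA_real_, dim = c(nf, D, 3L))
  for (i in seq_len(D)) {
    ss <- sites[[i]]
    for (k in 1:3)
      cogs[, i, k] <- rowMeans(ens$coords[, ss, k, drop = FALSE])
  }
  for (i in seq_len(D - 1L)) for (j in (i + 1L):D) {
    d <- sqrt(rowSums((cogs[, i, , drop = FALSE] - cogs[, j, , drop = FALSE])^2))
    out[, i, j] <- d
    out[, j, i] <- d
  }
  out
}
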