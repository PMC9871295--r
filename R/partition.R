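#' Domain partition of a multi-domain chain
#'
#' Describes which chain positions (residues) belong to which rigid-ish
#' domain (moiety), and which residues are masked out of all feature and
#' centre-of-geometry calculations. For a K48-linked tri-ubiquitin chain the
#' three moieties are conventionally called distal, middle and proximal,
#' where "proximal" is the unit with the free C-terminus. Highly flexible
#' tail residues (the last four of each ubiquitin unit) are typically masked.
#'
#' Residue indices are 0-based internally. Configuration files may use
#' 1-based biology numbering via their `index_base` key (see
#' [read_partition_config()]).
#'
#' @param domains List of integer vectors, one per domain, each giving the
#'   0-based residue indices of that domain. Domains must be disjoint and at
#'   least two are required.
#' @param masked Integer vector of 0-based residue indices excluded from
#'   features and CoG computations (default none). Masked residues stay in
#'   stored coordinates.
#' @param labels Optional character vector of per-domain names; defaults to
#'   `"A"`, `"B"`, ... in domain order.
#' @return An object of class `bmbs_partition`.
#' @export
#' @examples
#' p <- domain_partition(list(0:1, 2:3, 4:5))
#' n_domains(p)
domain_partition <- function(domains, masked = integer(), labels = NULL) {
  if (!is.list(domains) || length(domains) < 2L)
    stop_config("a partition needs at least 2 domains")
  domains <- lapply(domains, function(d) sort(unique(as.integer(d))))
  if (any(vapply(domains, length, 1L) == 0L))
    stop_config("empty domain in partition")
  all_res <- unlist(domains)
  if (anyDuplicated(all_res))
    stop_config("domains are not disjoint")
  if (any(all_res < 0L))
    stop_config("negative residue index in partition")
  masked <- sort(unique(as.integer(masked)))
  if (is.null(labels)) labels <- LETTERS[seq_along(domains)]
  if (length(labels) != length(domains))
    stop_config("labels length must match number of domains")
  for (i in seq_along(domains)) {
    if (length(setdiff(domains[[i]], masked)) == 0L)
      stop_config(sprintf("domain %s has no unmasked residues", labels[i]))
  }
  structure(
    list(domains = domains, masked = masked, labels = labels),
    class = "bmbs_partition"
  )
}

#' @export
print.bmbs_partition <- function(x, ...) {
  cat("Domain partition:", length(x$domains), "domains\n")
  for (i in seq_along(x$domains)) {
    d <- x$domains[[i]]
    nm <- length(setdiff(d, x$masked))
    cat(sprintf("  %s: %d residues (%d unmasked)\n", x$labels[i], length(d), nm))
  }
  if (length(x$masked)) cat("  masked:", length(x$masked), "residues\n")
  invisible(x)
}

#' Number of domains in a partition
#' @param partition A [domain_partition()].
#' @return Integer count.
#' @export
n_domains <- function(partition) length(partition$domains)

#' Unmasked residues of one domain
#' @param partition A [domain_partition()].
#' @param i Domain index (1-based).
#' @return Sorted 0-based residue indices.
#' @export
unmasked_residues <- function(partition, i) {
  setdiff(partition$domains[[i]], partition$masked)
}

# All residues referenced by the partition (masked or not).
partition_residues <- function(partition) sort(unlist(partition$domains))

#' Convenience partition for a tri-ubiquitin-like chain
#'
#' Three consecutive domains of `unit_size` residues each; the last
#' `tail_mask` residues of every unit (the flexible C-terminal tail) are
#' masked. Defaults give 76-residue units with residues 73-76 (1-based)
#' masked, i.e. 72 unmasked residues per moiety.
#'
#' @param unit_size Residues per domain (default 76).
#' @param tail_mask Number of trailing residues masked per domain (default 4).
#' @return A `bmbs_partition` labelled distal/middle/proximal.
#' @export
tri_ub_partition <- function(unit_size = 76L, tail_mask = 4L) {
  unit_size <- as.integer(unit_size)
  tail_mask <- as.integer(tail_mask)
  if (tail_mask >= unit_size) stop_config("tail_mask must be < unit_size")
  doms <- lapply(0:2, function(k) seq.int(k * unit_size, (k + 1L) * unit_size - 1L))
  masked <- if (tail_mask > 0L) {
    unlist(lapply(doms, function(d) tail(d, tail_mask)))
  } else integer()
  domain_partition(doms, masked, labels = c("distal", "middle", "proximal"))
}

#' Read a domain-partition configuration file
#'
#' Small declarative key-value format, one statement per line:
#' \preformatted{
#' # comment
#' index_base = 1
#' domain distal = 1-76
#' domain middle = 77-152
#' domain proximal = 153-228
#' mask = 73-76, 149-152, 225-228
#' }
#' Ranges are inclusive and may be single numbers; `index_base` (0 or 1,
#' default 0) says how residues are numbered in the file. Internally indices
#' are 0-based.
#'
#' @param path Path to the configuration file.
#' @return A `bmbs_partition`.
#' @export
#' @examples
#' cfg <- system.file("extdata", "tri_ub_partition.cfg", package = "bmbsr")
#' read_partition_config(cfg)
read_partition_config <- function(path) {
  if (!file.exists(path)) stop_config(paste("no such partition config:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  base <- 0L
  doms <- list()
  labels <- character()
  masked <- integer()
  parse_ranges <- function(txt) {
    parts <- trimws(strsplit(txt, ",", fixed = TRUE)[[1L]])
    out <- integer()
    for (p in parts[nzchar(parts)]) {
      m <- regmatches(p, regexec("^(-?[0-9]+)\\s*-\\s*(-?[0-9]+)$", p))[[1L]]
      if (length(m) == 3L) {
        out <- c(out, seq.int(as.integer(m[2L]), as.integer(m[3L])))
      } else if (grepl("^-?[0-9]+$", p)) {
        out <- c(out, as.integer(p))
      } else {
        stop_config(paste("cannot parse residue range:", p))
      }
    }
    out
  }
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop_config(paste("cannot parse config line:", ln))
    key <- trimws(kv[2L]); val <- trimws(kv[3L])
    if (key == "index_base") {
      base <- as.integer(val)
      if (!base %in% c(0L, 1L)) stop_config("index_base must be 0 or 1")
    } else if (grepl("^domain\\s+", key)) {
      labels <- c(labels, trimws(sub("^domain\\s+", "", key)))
      doms[[length(doms) + 1L]] <- parse_ranges(val)
    } else if (key == "mask") {
      masked <- c(masked, parse_ranges(val))
    } else {
      stop_config(paste("unknown partition config key:", key))
    }
  }
  if (length(doms) < 2L) stop_config("partition config defines fewer than 2 domains")
  doms <- lapply(doms, function(d) d - base)
  masked <- masked - base
  domain_partition(doms, masked, labels)
}
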