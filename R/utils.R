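#' @useDynLib bmbsr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm optim cor prcomp dist hclust as.dist sd setNames quantile
#' @importFrom utils read.table write.table head tail
NULL

# Classed error helpers. Conditions carry "bmbs_*_error" so callers and tests
# can distinguish configuration problems from format or numeric-domain ones.
bmbs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bmbs_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_config <- function(msg) bmbs_stop(msg, "bmbs_config_error", sys.call(-1))
stop_format <- function(msg) bmbs_stop(msg, "bmbs_format_error", sys.call(-1))
stop_domain <- function(msg) bmbs_stop(msg, "bmbs_domain_error", sys.call(-1))

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded operations are reproducible without
#' clobbering the session stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det forced to +1).
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Squared-distance-safe Euclidean cross-distance between two point sets
# (rows are points). Used everywhere a pairwise block is needed.
cross_dist <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
  sqrt(pmax(d2, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
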