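# Hierarchical density-based clustering (HDBSCAN), built from:
#   1. core distances (distance to the min_samples-th neighbour, self
#      included),
#   2. the mutual-reachability distance max(core_i, core_j, d_ij),
#   3. single-linkage hierarchy on mutual reachability (stats::hclust; the
#      MST route gives the identical dendrogram),
#   4. a condensed tree at min_cluster_size,
#   5. excess-of-mass stability selection.
# Points that never belong to a selected cluster get label -1 (noise).

hdbscan_labels <- function(embedding, min_cluster_size, min_samples,
                           allow_single_cluster = FALSE) {
  X <- as.matrix(embedding)
  n <- nrow(X)
  mcs <- as.integer(min_cluster_size)
  ms <- as.integer(min_samples)
  if (mcs < 2L) stop_config("min_cluster_size must be >= 2")
  if (ms < 1L) stop_config("min_samples must be >= 1")
  if (n < mcs) {
    warning("fewer frames than min_cluster_size: everything is noise")
    return(rep(-1L, n))
  }
  d <- as.matrix(dist(X))
  core <- apply(d, 1L, function(r) sort(r, partial = min(ms, n))[min(ms, n)])
  mr <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mr) <- 0
  hc <- hclust(as.dist(mr), method = "single")
  condensed <- condense_tree(hc, n, mcs)
  select_and_label(condensed, n, allow_single_cluster)
}

# Leaves (original point indices) under a merge-tree node. node > 0 is a
# merge row, node < 0 is leaf -node. Iterative to cope with chained trees.
merge_leaves <- function(merge, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd < 0L) out <- c(out, -nd)
    else stack <- c(stack, merge[nd, 1L], merge[nd, 2L])
  }
  out
}

# Build the condensed cluster tree: walking the dendrogram top-down, a
# split where both sides hold >= mcs points creates two child clusters;
# smaller sides fall out of the current cluster at that height. Heights are
# converted to density levels lambda = 1/height.
condense_tree <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  nm <- nrow(merge)
  sizes <- integer(nm)
  for (m in seq_len(nm)) {
    sz <- function(x) if (x < 0L) 1L else sizes[x]
    sizes[m] <- sz(merge[m, 1L]) + sz(merge[m, 2L])
  }
  lam <- function(h) 1 / max(h, 1e-12)

  # cluster records grow as splits are found
  birth <- numeric(0); stability <- numeric(0)
  parent <- integer(0); kids <- list()
  leaf_cluster <- integer(n); leaf_lambda <- numeric(n)

  new_cluster <- function(b, par) {
    birth <<- c(birth, b); stability <<- c(stability, 0)
    parent <<- c(parent, par); kids[[length(kids) + 1L]] <<- integer(0)
    id <- length(birth)
    if (par > 0L) kids[[par]] <<- c(kids[[par]], id)
    id
  }
  root <- new_cluster(lam(height[nm]), 0L)

  node_size <- function(x) if (x < 0L) 1L else sizes[x]
  stack_node <- nm
  stack_cl <- root
  while (length(stack_node)) {
    m <- stack_node[[length(stack_node)]]
    cl <- stack_cl[[length(stack_cl)]]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    l <- lam(height[m])
    ch <- merge[m, ]
    s1 <- node_size(ch[1L]); s2 <- node_size(ch[2L])
    if (s1 >= mcs && s2 >= mcs) {
      # true split: all current points leave cl here, two children born
      stability[cl] <- stability[cl] + (s1 + s2) * (l - birth[cl])
      for (k in 1:2) {
        child <- new_cluster(l, cl)
        stack_node <- c(stack_node, ch[k])
        stack_cl <- c(stack_cl, child)
      }
    } else {
      for (k in 1:2) {
        if (node_size(ch[k]) >= mcs) {
          # spine continues inside the same cluster
          stack_node <- c(stack_node, ch[k])
          stack_cl <- c(stack_cl, cl)
        } else {
          lv <- if (ch[k] < 0L) -ch[k] else merge_leaves(merge, ch[k])
          stability[cl] <- stability[cl] + length(lv) * (l - birth[cl])
          leaf_cluster[lv] <- cl
          leaf_lambda[lv] <- l
        }
      }
    }
  }
  list(birth = birth, stability = stability, parent = parent, kids = kids,
       leaf_cluster = leaf_cluster, leaf_lambda = leaf_lambda, root = root)
}

# Excess-of-mass selection plus labelling. Bottom-up: a cluster keeps
# itself if its own stability beats the summed stability of its selected
# descendants; the root participates only when allow_single_cluster.
select_and_label <- function(ct, n, allow_single_cluster) {
  nc <- length(ct$birth)
  sel_stab <- numeric(nc)
  take_self <- logical(nc)
  for (c in nc:1) {
    ch <- ct$kids[[c]]
    if (length(ch) == 0L) {
      sel_stab[c] <- ct$stability[c]
      take_self[c] <- TRUE
    } else {
      s_kids <- sum(sel_stab[ch])
      if (ct$stability[c] >= s_kids && (c != ct$root || allow_single_cluster)) {
        sel_stab[c] <- ct$stability[c]
        take_self[c] <- TRUE
      } else {
        sel_stab[c] <- s_kids
        take_self[c] <- FALSE
      }
    }
  }
  if (!allow_single_cluster) take_self[ct$root] <- FALSE
  # top-down: select the topmost take_self clusters
  selected <- logical(nc)
  stack <- ct$root
  while (length(stack)) {
    c <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (take_self[c]) selected[c] <- TRUE
    else stack <- c(stack, ct$kids[[c]])
  }
  if (ct$root == 1L && length(ct$kids[[ct$root]]) == 0L && !allow_single_cluster)
    selected[ct$root] <- FALSE
  sel_ids <- which(selected)
  if (length(sel_ids) == 0L) return(rep(-1L, n))
  # map each point's owning condensed cluster up to a selected ancestor
  labels <- rep(-1L, n)
  lab_of <- integer(nc)
  lab_of[] <- -1L
  for (i in seq_along(sel_ids)) lab_of[sel_ids[i]] <- i - 1L
  # propagate selected label down the cluster tree
  anc <- function(c) {
    while (c > 0L) {
      if (lab_of[c] >= 0L) return(lab_of[c])
      c <- ct$parent[c]
    }
    -1L
  }
  cluster_label_cache <- vapply(seq_len(nc), anc, 1L)
  owner <- ct$leaf_cluster
  ok <- owner > 0L
  labels[ok] <- cluster_label_cache[owner[ok]]
  labels
}
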