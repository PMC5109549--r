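#' Dissimilarity between two markers
#'
#' `1 - |Pearson r|`: anti-correlated markers are exchangeable explainers of a
#' phenotype up to the sign of their effect, so they must be treated as
#' interchangeable (dissimilarity 0), not opposite.
#'
#' @param geno An imputed `genotype_matrix`.
#' @param i,j Marker indices (or IDs).
#' @return Dissimilarity in `[0, 1]`.
#' @export
marker_dissimilarity <- function(geno, i, j) {
  if (is.character(i)) i <- match(i, marker_ids(geno))
  if (is.character(j)) j <- match(j, marker_ids(geno))
  x <- geno$values[, i]
  y <- geno$values[, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance marker column", call. = FALSE)
  }
  max(0, 1 - abs(stats::cor(x, y)))
}

# column correlations via crossprod (much faster than stats::cor for wide
# matrices); zero-variance columns give NaN, as with stats::cor
fast_cor <- function(x, y = NULL) {
  xc <- sweep(x, 2, colMeans(x))
  xs <- sqrt(colSums(xc^2))
  if (is.null(y)) {
    crossprod(xc) / tcrossprod(xs)
  } else {
    yc <- sweep(y, 2, colMeans(y))
    ys <- sqrt(colSums(yc^2))
    crossprod(xc, yc) / outer(xs, ys)
  }
}

# dissimilarity matrix 1 - |r| for a set of marker columns
dissim_matrix <- function(values) {
  d <- 1 - abs(fast_cor(values))
  d[is.na(d)] <- 1
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# ---- internal raw-tree representation -------------------------------------
# parent/children/height/members over node ids local to the build; leaves
# carry the global marker index in leaf_marker.

tree_leaf <- function(marker) {
  list(parent = NA_integer_, children = list(integer(0)), height = 0,
       leaf_marker = marker, root = 1L)
}

tree_from_hclust <- function(hc, idx) {
  p <- length(idx)
  n_nodes <- 2L * p - 1L
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  height <- numeric(n_nodes)
  leaf_marker <- c(idx, rep(NA_integer_, p - 1L))
  for (i in seq_len(p)) children[[i]] <- integer(0)
  hts <- cummax(pmin(pmax(hc$height, 0), 1))  # monotone, clamped to [0, 1]
  for (r in seq_len(p - 1L)) {
    node <- p + r
    ch <- ifelse(hc$merge[r, ] < 0, -hc$merge[r, ], p + hc$merge[r, ])
    children[[node]] <- as.integer(ch)
    parent[ch] <- node
    height[node] <- hts[r]
  }
  list(parent = parent, children = children, height = height,
       leaf_marker = leaf_marker, root = n_nodes)
}

# graft subtrees onto a joining hclust over their roots; heights are spliced
# monotonically (a join node is at least as high as everything below it)
tree_join <- function(trees, join_hc) {
  k <- length(trees)
  offset <- 0L
  parent <- integer(0); children <- list(); height <- numeric(0)
  leaf_marker <- integer(0); roots <- integer(k)
  for (t in seq_len(k)) {
    tr <- trees[[t]]
    m <- length(tr$parent)
    parent <- c(parent, tr$parent + offset)
    children <- c(children, lapply(tr$children, function(ch) ch + offset))
    height <- c(height, tr$height)
    leaf_marker <- c(leaf_marker, tr$leaf_marker)
    roots[t] <- tr$root + offset
    offset <- offset + m
  }
  if (k == 1) {
    return(list(parent = parent, children = children, height = height,
                leaf_marker = leaf_marker, root = roots[1]))
  }
  join_nodes <- integer(nrow(join_hc$merge))
  for (r in seq_len(nrow(join_hc$merge))) {
    node <- offset + r
    ch <- vapply(join_hc$merge[r, ], function(m)
      if (m < 0) roots[-m] else join_nodes[m], integer(1))
    h <- max(min(max(join_hc$height[r], 0), 1), height[ch])
    parent <- c(parent, NA_integer_)
    children <- c(children, list(ch))
    height <- c(height, h)
    leaf_marker <- c(leaf_marker, NA_integer_)
    parent[ch] <- node
    join_nodes[r] <- node
  }
  list(parent = parent, children = children, height = height,
       leaf_marker = leaf_marker, root = offset + nrow(join_hc$merge))
}

# canonical marker_hierarchy from a raw tree: leaves renumbered to their
# marker index, internal nodes topologically (children before parents)
canonicalize_tree <- function(tree, ids) {
  p <- sum(!is.na(tree$leaf_marker))
  n_nodes <- length(tree$parent)
  new_id <- integer(n_nodes)
  new_id[!is.na(tree$leaf_marker)] <- tree$leaf_marker[!is.na(tree$leaf_marker)]
  internal <- which(is.na(tree$leaf_marker))
  # topological order: repeatedly take internal nodes whose children are done
  done <- !is.na(tree$leaf_marker)
  next_id <- p
  remaining <- internal
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(v)
      all(done[tree$children[[v]]]), logical(1))]
    for (v in ready[order(tree$height[ready])]) {
      next_id <- next_id + 1L
      new_id[v] <- next_id
      done[v] <- TRUE
    }
    remaining <- setdiff(remaining, ready)
  }
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  height <- numeric(n_nodes)
  members <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) {
    nv <- new_id[v]
    height[nv] <- tree$height[v]
    if (!is.na(tree$parent[v])) parent[nv] <- new_id[tree$parent[v]]
    if (is.na(tree$leaf_marker[v])) {
      ch <- new_id[tree$children[[v]]]
      children[[nv]] <- ch
    } else {
      children[[nv]] <- integer(0)
      members[[nv]] <- tree$leaf_marker[v]
    }
  }
  # members bottom-up (internal ids are topologically ordered)
  for (nv in (p + 1L):n_nodes) {
    if (n_nodes == p) break
    members[[nv]] <- sort(unlist(members[children[[nv]]]))
  }
  # children ordered by smallest member index (deterministic cut order)
  for (nv in seq_len(n_nodes)) {
    ch <- children[[nv]]
    if (length(ch) > 1) {
      children[[nv]] <- ch[order(vapply(members[ch], min, integer(1)))]
    }
  }
  structure(
    list(n_markers = p, n_nodes = n_nodes, parent = parent,
         children = children, height = height, members = members,
         root = new_id[tree$root], marker_ids = ids),
    class = "marker_hierarchy"
  )
}

#' Genome-wide hierarchical clustering of markers
#'
#' Builds one tree over all (deduplicated) markers from the pairwise
#' dissimilarity `1 - |r|`; every node of the tree is a candidate cluster for
#' the hierarchical association test. Clustering is always genome-wide, never
#' per chromosome: population structure correlates physically unlinked
#' markers, and such markers must be able to co-cluster.
#'
#' For `p <= max_partition_size` the tree is the exact average-linkage
#' agglomeration. Above that, a two-stage scheme keeps the cost manageable:
#' a seeded k-medoids pass partitions the markers into pieces of at most
#' `max_partition_size`, exact average linkage is run within each piece, and
#' the piece roots are joined by average linkage over their medoids, with
#' heights spliced monotonically.
#'
#' @param geno An imputed, deduplicated `genotype_matrix`.
#' @param max_partition_size Largest marker set clustered exactly.
#' @param seed Seed for the coarse partitioning stage (ignored when the exact
#'   path is taken); the result is deterministic given matrix and seed.
#' @return A `marker_hierarchy`.
#' @export
build_hierarchy <- function(geno, max_partition_size = 2000, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- n_markers(geno)
  if (p == 0) stop("no markers to cluster", call. = FALSE)
  if (anyNA(geno$values)) {
    stop("impute missing genotypes before clustering", call. = FALSE)
  }
  tree <- with_local_seed(seed, build_tree(geno$values, seq_len(p),
                                           max_partition_size))
  canonicalize_tree(tree, marker_ids(geno))
}

build_tree <- function(values, idx, max_partition_size) {
  m <- length(idx)
  if (m == 1) return(tree_leaf(idx))
  if (m <= max_partition_size) {
    d <- dissim_matrix(values[, idx, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    return(tree_from_hclust(hc, idx))
  }
  parts <- coarse_partition(values, idx, max_partition_size)
  trees <- lapply(parts, function(pi) build_tree(values, pi,
                                                 max_partition_size))
  med <- vapply(parts, function(pi)
    medoid_index(values, pi, sample_cap = 1000L), integer(1))
  dj <- dissim_matrix(values[, med, drop = FALSE])
  join_hc <- stats::hclust(stats::as.dist(dj), method = "average")
  tree_join(trees, join_hc)
}

# seeded k-medoids-style coarse partitioning on 1 - |r|
coarse_partition <- function(values, idx, max_partition_size, n_iter = 4L) {
  m <- length(idx)
  k <- max(2L, ceiling(m / max_partition_size))
  med <- sort(sample(idx, k))
  assign <- NULL
  for (it in seq_len(n_iter)) {
    d <- 1 - abs(fast_cor(values[, idx, drop = FALSE],
                          values[, med, drop = FALSE]))
    d[is.na(d)] <- 1
    assign <- max.col(-d, ties.method = "first")
    new_med <- med
    for (g in seq_len(k)) {
      mem <- idx[assign == g]
      if (length(mem) == 0) next
      new_med[g] <- medoid_index(values, mem, sample_cap = 500L)
    }
    if (all(new_med == med)) break
    med <- new_med
  }
  # keep tight twins together: a marker strongly correlated with an earlier
  # marker joins that marker's partition (the k-medoids pass can split a
  # near-duplicate pair across a partition boundary)
  nn_block <- 512L
  for (start in seq(1, m, by = nn_block)) {
    loc <- start:min(start + nn_block - 1L, m)
    cc <- abs(fast_cor(values[, idx[loc], drop = FALSE],
                       values[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0
    cc[cbind(seq_along(loc), loc)] <- 0  # self
    best <- max.col(cc, ties.method = "first")
    strong <- which(cc[cbind(seq_along(loc), best)] >= 0.5 & idx[best] < idx[loc])
    for (s in strong) assign[loc[s]] <- assign[best[s]]
  }
  parts <- split(idx, assign)
  parts <- parts[lengths(parts) > 0]
  # a partition that failed to shrink would recurse forever; split it evenly
  # in genome order instead
  if (length(parts) == 1) {
    parts <- split(idx, ceiling(seq_along(idx) / max_partition_size))
  }
  unname(parts)
}

# medoid of a member set: member minimizing total dissimilarity to the others
# (sum estimated on a sampled subset when the set is large); ties -> first in
# genome order
medoid_index <- function(values, members, sample_cap = Inf) {
  members <- sort(members)
  if (length(members) == 1) return(members)
  ref <- if (length(members) > sample_cap) {
    sort(sample(members, sample_cap))
  } else members
  cc <- abs(fast_cor(values[, members, drop = FALSE],
                     values[, ref, drop = FALSE]))
  cc[is.na(cc)] <- 0
  sums <- rowSums(1 - cc)
  # tolerance tie-break toward the earliest member in genome order
  members[which(sums <= min(sums) + 1e-9)[1]]
}

#' Medoid marker of a cluster
#'
#' The member minimizing the sum of dissimilarities (`1 - |r|`) to all other
#' members; ties are broken toward the earliest marker in genome order. QTCs
#' are summarized by, and regressed through, their medoids.
#'
#' @param geno An imputed `genotype_matrix`.
#' @param members Marker indices of the cluster (nonempty).
#' @return A single marker index.
#' @export
cluster_medoid <- function(geno, members) {
  if (length(members) == 0) stop("empty member set", call. = FALSE)
  medoid_index(geno$values, as.integer(members))
}

#' Children of a hierarchy node
#'
#' @param hierarchy A `marker_hierarchy`.
#' @param node_id Node id (leaves are `1..p` in marker order).
#' @return Integer vector of child node ids, ordered by smallest member
#'   index; empty for a leaf.
#' @export
cut_children <- function(hierarchy, node_id) {
  stopifnot(inherits(hierarchy, "marker_hierarchy"))
  if (length(node_id) != 1 || is.na(node_id) || node_id < 1 ||
      node_id > hierarchy$n_nodes) {
    stop("unknown node id: ", node_id, call. = FALSE)
  }
  hierarchy$children[[node_id]]
}

#' Hierarchy nodes as a tibble
#'
#' @param hierarchy A `marker_hierarchy`.
#' @return Tibble with `node_id`, `parent_id`, `height`, `n_members`,
#'   `is_leaf`.
#' @export
hierarchy_nodes <- function(hierarchy) {
  tibble::tibble(
    node_id = seq_len(hierarchy$n_nodes),
    parent_id = hierarchy$parent,
    height = hierarchy$height,
    n_members = lengths(hierarchy$members),
    is_leaf = lengths(hierarchy$children) == 0
  )
}

#' @export
print.marker_hierarchy <- function(x, ...) {
  cat(sprintf("<marker_hierarchy> %d markers, %d nodes, root height %.3f\n",
              x$n_markers, x$n_nodes, x$height[x$root]))
  invisible(x)
}

#' Check the structural invariants of a marker hierarchy
#'
#' Verifies that children partition their parent's member set, that heights
#' are monotone (child below parent, leaves at 0) and that every marker sits
#' in exactly one leaf. Errors on the first violation.
#'
#' @param hierarchy A `marker_hierarchy`.
#' @return `TRUE`, invisibly.
#' @export
validate_hierarchy <- function(hierarchy) {
  h <- hierarchy
  p <- h$n_markers
  stopifnot(identical(sort(unlist(h$members[seq_len(p)])), seq_len(p)))
  if (!identical(h$members[[h$root]], seq_len(p))) {
    stop("root must contain all markers", call. = FALSE)
  }
  for (v in seq_len(h$n_nodes)) {
    ch <- h$children[[v]]
    if (length(ch) == 0) {
      if (h$height[v] != 0) stop("leaf with nonzero height", call. = FALSE)
      next
    }
    mem <- sort(unlist(h$members[ch]))
    if (!identical(mem, h$members[[v]])) {
      stop("children do not partition node ", v, call. = FALSE)
    }
    if (any(h$height[ch] > h$height[v] + 1e-12)) {
      stop("height not monotone at node ", v, call. = FALSE)
    }
    if (h$height[v] < 0 || h$height[v] > 1 + 1e-12) {
      stop("height outside [0, 1] at node ", v, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Serialize / restore a marker hierarchy
#'
#' The hierarchy is written as a documented JSON object (marker IDs, per-node
#' parent and height, leaf marker assignment); member sets are reconstructed
#' on read, so the round trip is lossless.
#'
#' @param hierarchy A `marker_hierarchy`.
#' @param path Output path.
#' @return `path` (write) or the restored `marker_hierarchy` (read).
#' @export
write_hierarchy <- function(hierarchy, path) {
  leaf_marker <- rep(NA_integer_, hierarchy$n_nodes)
  leaf_marker[seq_len(hierarchy$n_markers)] <- seq_len(hierarchy$n_markers)
  obj <- list(
    format = "qtcgwas_hierarchy_v1",
    marker_ids = hierarchy$marker_ids,
    parent = hierarchy$parent,
    height = hierarchy$height,
    leaf_marker = leaf_marker
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "qtcgwas_hierarchy_v1")) {
    stop("not a qtcgwas hierarchy file", call. = FALSE)
  }
  n_nodes <- length(obj$parent)
  p <- length(obj$marker_ids)
  parent <- as.integer(obj$parent)
  children <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) children[[v]] <- integer(0)
  for (v in which(!is.na(parent))) {
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  }
  members <- vector("list", n_nodes)
  for (v in seq_len(p)) members[[v]] <- v
  for (v in (p + 1L):n_nodes) {
    if (n_nodes == p) break
    members[[v]] <- sort(unlist(members[children[[v]]]))
  }
  for (v in seq_len(n_nodes)) {
    ch <- children[[v]]
    if (length(ch) > 1) {
      children[[v]] <- ch[order(vapply(members[ch], min, integer(1)))]
    }
  }
  structure(
    list(n_markers = p, n_nodes = n_nodes, parent = parent,
         children = children, height = as.numeric(obj$height),
         members = members, root = which(is.na(parent)),
         marker_ids = as.character(obj$marker_ids)),
    class = "marker_hierarchy"
  )
}
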