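# Node permutation schemes. Reordering nodes changes nothing about the
# mathematics (the permuted matrix still eliminates parent-before-child at
# identical operation count); what it changes is memory locality: whether
# the parents of a consecutive block of nodes are themselves consecutive,
# the property SIMD lanes need for coalesced loads.

#' Construct a permutation from a forward map
#' @param forward integer vector: `forward[old]` is the new index.
#' @return an `nc_permutation` with `forward` and `inverse` maps.
#' @export
make_permutation <- function(forward) {
  forward <- as.integer(forward)
  n <- length(forward)
  if (anyNA(forward) || !setequal(forward, seq_len(n)))
    nc_stop("nc_integrity_error", "forward map is not a bijection on 1..%d", n)
  inverse <- integer(n)
  inverse[forward] <- seq_len(n)
  structure(list(forward = forward, inverse = inverse), class = "nc_permutation")
}

#' @rdname make_permutation
#' @param perm an `nc_permutation`.
#' @export
invert_permutation <- function(perm) make_permutation(perm$inverse)

# Per-node depth from the root of its cell (root = 0).
node_depth <- function(parent) {
  n <- length(parent)
  depth <- integer(n)
  for (i in seq_len(n))
    depth[i] <- if (parent[i] == 0L) 0L else depth[parent[i]] + 1L
  depth
}

local_parent <- function(model, k) {
  ix <- model$cell_nodes[[k]]
  pos <- integer(model$n_nodes)
  pos[ix] <- seq_along(ix)
  p <- model$parent[ix]
  lp <- integer(length(ix))
  nz <- p != 0L
  lp[nz] <- pos[p[nz]]
  lp
}

#' Interleaved node ordering
#'
#' Within each block of N topologically identical cells, node j of cell c
#' moves to `block_offset + j*N + c`: corresponding compartments of the N
#' cells become adjacent, so N SIMD lanes working on corresponding nodes
#' load consecutive addresses, and each lane's parent block is the
#' previous row of N. Root-to-leaf order of j is preserved, so the permuted
#' model still satisfies parent-before-child.
#'
#' @param model an `nc_model` whose cells are ordered type-contiguously.
#' @return an `nc_permutation`.
#' @export
interleaved_order <- function(model) {
  types <- model$cells$type
  if (is.unsorted(match(types, unique(types))))
    nc_stop("nc_type_error", "cells must be grouped contiguously by type")
  forward <- integer(model$n_nodes)
  offset <- 0L
  for (ty in unique(types)) {
    ks <- which(types == ty)
    lp <- lapply(ks, function(k) local_parent(model, k))
    if (length(ks) > 1 && !all(vapply(lp[-1], identical, logical(1), lp[[1]])))
      nc_stop("nc_type_error", "cells of type %s are not topologically identical", ty)
    N <- length(ks)
    k_nodes <- length(model$cell_nodes[[ks[1]]])
    for (ci in seq_along(ks)) {
      ix <- model$cell_nodes[[ks[ci]]]
      forward[ix] <- offset + (seq_along(ix) - 1L) * N + ci
    }
    offset <- offset + N * k_nodes
  }
  make_permutation(forward)
}

# Within-cell ranks that keep children of the same branch node maximally
# separated: at each depth, nodes are ordered child-position-major (all
# first children in parent-rank order, then all second children, ...), so
# two siblings sit about half the depth-row apart.
sibling_separated_ranks <- function(lp) {
  n <- length(lp)
  depth <- node_depth(lp)
  rank <- integer(n)
  for (dk in sort(unique(depth))) {
    at <- which(depth == dk)
    if (dk == 0L) { rank[at] <- seq_along(at) - 1L; next }
    childpos <- integer(length(at))
    for (j in seq_along(at)) {
      sibs <- at[lp[at] == lp[at[j]]]
      childpos[j] <- match(at[j], sibs)
    }
    ord <- at[order(childpos, rank[lp[at]], at)]
    rank[ord] <- seq_along(ord) - 1L
  }
  rank
}

#' Constant-depth node ordering
#'
#' All nodes at the same depth from their root become adjacent; within a
#' depth, nodes are ordered by their sibling-separating within-cell rank,
#' then type and cell, so corresponding nodes of identical cells stay
#' adjacent while children of the same branch node are kept as far apart as
#' possible. Depth-major order trivially preserves parent-before-child.
#'
#' @param model an `nc_model`.
#' @return an `nc_permutation`.
#' @export
constant_depth_order <- function(model) {
  n <- model$n_nodes
  depth <- integer(n); rank <- integer(n)
  cellpos <- integer(n); typev <- integer(n)
  for (k in seq_along(model$cell_nodes)) {
    ix <- model$cell_nodes[[k]]
    lp <- local_parent(model, k)
    depth[ix] <- node_depth(lp)
    rank[ix] <- sibling_separated_ranks(lp)
    cellpos[ix] <- k
    typev[ix] <- model$cells$type[k]
  }
  ord <- order(depth, rank, typev, cellpos)
  forward <- integer(n)
  forward[ord] <- seq_len(n)
  make_permutation(forward)
}

#' Relabel a model under a node permutation
#'
#' Consistently remaps every node reference: parent array, per-node geometry,
#' cell-to-node maps, mechanism insertion nodes, gap-junction peer offsets,
#' and spike-watcher nodes. The permuted model must (and is checked to)
#' still satisfy parent-before-child.
#'
#' @param model an `nc_model`.
#' @param perm an `nc_permutation` over the model's nodes.
#' @return the permuted model.
#' @export
apply_permutation <- function(model, perm) {
  stopifnot(inherits(perm, "nc_permutation"))
  fw <- perm$forward; inv <- perm$inverse
  if (length(fw) != model$n_nodes)
    nc_stop("nc_integrity_error", "permutation size %d != node count %d",
            length(fw), model$n_nodes)
  m <- model
  p_old <- model$parent[inv]
  p_new <- integer(m$n_nodes)
  nz <- p_old != 0L
  p_new[nz] <- fw[p_old[nz]]
  m$parent <- p_new
  m$area <- model$area[inv]
  m$cm_node <- model$cm_node[inv]
  m$g_axial <- model$g_axial[inv]
  m$cell_of_node <- model$cell_of_node[inv]
  m$cell_nodes <- lapply(model$cell_nodes, function(ix) fw[ix])
  m$insertions <- lapply(model$insertions, function(ins) {
    ins$node <- fw[ins$node]
    if (ins$mech == "gap" && !is.na(ins$params$peer_node))
      ins$params$peer_node <- fw[ins$params$peer_node]
    ins
  })
  if (nrow(m$presyns) > 0)
    m$presyns$watch_node <- as.integer(fw[model$presyns$watch_node])
  bad <- which(m$parent != 0L & m$parent >= seq_len(m$n_nodes))
  if (length(bad) > 0)
    nc_stop("nc_integrity_error",
            "permutation breaks parent-before-child at node %d", bad[1])
  m
}

#' Parent-access locality metric
#'
#' Partitions the non-root nodes, in index order, into consecutive groups of
#' `warp_size` (a trailing partial group is ignored). A group counts as
#' contiguous when its parents form a consecutive ascending run -- the
#' pattern that lets `warp_size` SIMD lanes load their parents in one
#' coalesced transaction instead of a strided gather.
#'
#' @param parent 1-based parent vector (0 = root).
#' @param warp_size lanes per group (>= 2).
#' @return fraction of full groups that are contiguous, in `[0, 1]`.
#' @export
parent_contiguity <- function(parent, warp_size = 32L) {
  warp_size <- as.integer(warp_size)
  if (warp_size < 2) nc_stop("nc_parameter_error", "warp_size must be >= 2")
  nr <- which(parent != 0L)
  nwarp <- length(nr) %/% warp_size
  if (nwarp == 0) return(1)
  ok <- 0L
  for (w in seq_len(nwarp)) {
    p <- parent[nr[(w - 1L) * warp_size + seq_len(warp_size)]]
    if (all(diff(p) == 1L)) ok <- ok + 1L
  }
  ok / nwarp
}
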