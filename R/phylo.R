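# Neighbor-Joining tree estimation, bootstrap bipartition support, marker
# concatenation, monophyly tests and Newick round trips. Trees are plain ape
# "phylo" objects (unrooted; internal nodes of degree 3), so they plot and
# serialize with the standard toolchain.

#' Concatenate aligned marker blocks into a supermatrix
#'
#' @param blocks Named list of [aligned_block()]s sharing one accession set.
#' @param marker_order Character vector giving the concatenation order
#'   (default: the list's names).
#' @return An `aligned_block` with attribute `offsets`: a tibble
#'   (`marker_id`, `start`, `end`) of 0-based half-open column ranges.
#' @export
concatenate_blocks <- function(blocks, marker_order = names(blocks)) {
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    stop_validation("blocks must be a named list of aligned blocks")
  }
  missing_mk <- setdiff(marker_order, names(blocks))
  if (length(missing_mk) > 0) {
    stop_validation("no block supplied for marker '%s'", missing_mk[1])
  }
  blocks <- blocks[marker_order]
  ids <- names(blocks[[1]])
  for (m in marker_order[-1]) {
    extra <- setdiff(names(blocks[[m]]), ids)
    absent <- setdiff(ids, names(blocks[[m]]))
    if (length(extra) + length(absent) > 0) {
      stop_validation(
        "accession sets differ between '%s' and '%s' (only in %s: %s)",
        marker_order[1], m,
        if (length(absent) > 0) marker_order[1] else m,
        if (length(absent) > 0) absent[1] else extra[1])
    }
  }
  widths <- unname(vapply(blocks, function(b) attr(b, "width"), numeric(1)))
  ends <- cumsum(widths)
  offsets <- tibble::tibble(marker_id = marker_order,
                            start = ends - widths, end = ends)
  joined <- Reduce(function(acc, b) paste0(acc, unclass(b)[ids]),
                   blocks, init = rep("", length(ids)))
  out <- aligned_block(setNames(joined, ids))
  attr(out, "offsets") <- offsets
  out
}

# Internal: assemble an ape phylo from an edge list over arbitrary node ids.
# tips 1..n keep their ids; internal nodes are renumbered n+1, n+2, ... in
# preorder from `root_id`, giving a valid cladewise edge matrix.
edges_to_phylo <- function(parent, child, length_, n_tips, tip_labels, root_id) {
  children <- split(seq_along(parent), parent)
  lookup <- function(id) children[[as.character(id)]]
  next_internal <- n_tips + 1L
  edge <- matrix(0L, nrow = length(parent), ncol = 2)
  edge_len <- numeric(length(parent))
  k <- 0L
  # iterative preorder DFS; internal nodes renumbered in visit order so the
  # root becomes n_tips + 1 as ape expects
  new_id_map <- new.env(parent = emptyenv())
  assign(as.character(root_id), next_internal, envir = new_id_map)
  next_internal <- next_internal + 1L
  stack <- list(root_id)
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node_new <- get(as.character(node), envir = new_id_map)
    kids <- lookup(node)
    # visit in creation order for determinism
    for (e in kids) {
      ch <- child[e]
      if (ch > n_tips) {
        assign(as.character(ch), next_internal, envir = new_id_map)
        ch_new <- next_internal
        next_internal <- next_internal + 1L
      } else {
        ch_new <- ch
      }
      k <- k + 1L
      edge[k, ] <- c(node_new, ch_new)
      edge_len[k] <- length_[e]
      if (ch > n_tips) stack[[length(stack) + 1L]] <- ch
    }
  }
  phy <- list(edge = edge, edge.length = edge_len, tip.label = tip_labels,
              Nnode = next_internal - n_tips - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j`. Ties in Q are broken
#' deterministically by the lexicographically smallest pair of current
#' indices. Negative branch-length estimates are clamped to zero; the total
#' clamped deficit is recorded in the tree's `"clamped"` attribute and
#' reported via a message.
#'
#' @param dm A [distance_matrix()] result, or a plain symmetric numeric
#'   matrix with dimnames.
#' @return An unrooted `phylo` tree (degenerate single-edge tree for 2 taxa).
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist_matrix")) {
    if (any(dm$undefined[upper.tri(dm$undefined)])) {
      stop_computation("distance matrix contains undefined pairs; cannot build NJ tree")
    }
    d <- dm$values
  } else {
    d <- as.matrix(dm)
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (anyNA(d)) stop_computation("distance matrix contains NA entries")
  n <- nrow(d)
  if (n < 2) stop_validation("NJ needs at least 2 taxa")
  labels <- rownames(d)

  if (n == 2) {
    phy <- list(edge = matrix(c(3L, 1L, 3L, 2L), ncol = 2, byrow = TRUE),
                edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
                tip.label = labels, Nnode = 1L)
    class(phy) <- "phylo"
    attr(phy, "clamped") <- 0
    return(phy)
  }

  ids <- seq_len(n)           # node ids of active clusters (tips 1..n)
  next_id <- n + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  clamped <- 0
  D <- d

  while (length(ids) > 3) {
    r <- length(ids)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    m <- min(Q)
    hit <- which(Q == m, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]

    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { clamped <- clamped - bi; bi <- 0 }
    if (bj < 0) { clamped <- clamped - bj; bj <- 0 }

    u <- next_id; next_id <- next_id + 1L
    parent <- c(parent, u, u)
    child <- c(child, ids[i], ids[j])
    elen <- c(elen, bi, bj)

    keep <- setdiff(seq_len(r), c(i, j))
    newrow <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow),
               c(newrow, 0))
    ids <- c(ids[keep], u)
  }

  # terminal star of three
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bb <- c(b1, b2, b3)
  neg <- bb < 0
  clamped <- clamped + sum(-bb[neg])
  bb[neg] <- 0
  center <- next_id
  parent <- c(parent, rep(center, 3))
  child <- c(child, ids)
  elen <- c(elen, bb)

  phy <- edges_to_phylo(parent, child, elen, n, labels, center)
  attr(phy, "clamped") <- clamped
  if (clamped > 0) {
    rlang::inform(sprintf(
      "nj_tree: %g of negative branch length clamped to zero", clamped))
  }
  phy
}

#' Sum of all branch lengths of a tree
#'
#' @param tree A `phylo`.
#' @return Numeric total.
#' @export
total_branch_length <- function(tree) {
  sum(tree$edge.length)
}

# Internal: canonical keys of the non-trivial bipartitions (splits) induced
# by a tree's internal edges. Returns a character vector named by the child
# node of each internal edge.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(setNames(character(0), character(0)))
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  internal_children <- po$edge[po$edge[, 2] > n, 2]
  keys <- vapply(internal_children, function(v) {
    split_key(sets[[v]], n)
  }, character(1))
  keep <- vapply(internal_children, function(v) {
    k <- length(sets[[v]])
    k >= 2 && k <= n - 2
  }, logical(1))
  setNames(keys[keep], internal_children[keep])
}

# Canonical representation of a bipartition: the side not containing tip 1,
# as a sorted index string (tip order = tip.label order of the reference).
split_key <- function(side, n) {
  side <- sort(unique(side))
  if (1 %in% side) side <- setdiff(seq_len(n), side)
  paste(side, collapse = ",")
}

#' Test whether a leaf set is monophyletic on an unrooted tree
#'
#' True iff some edge of the tree induces the bipartition
#' (leaf set | complement). Singletons, the full leaf set, and complements of
#' singletons are trivially monophyletic (tip edges induce them).
#'
#' @param tree A `phylo`.
#' @param leaf_set Non-empty character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, leaf_set) {
  leaf_set <- unique(as.character(leaf_set))
  if (length(leaf_set) == 0) stop_validation("leaf set is empty")
  idx <- match(leaf_set, tree$tip.label)
  if (anyNA(idx)) {
    stop_validation("unknown leaf '%s'", leaf_set[which(is.na(idx))[1]])
  }
  n <- length(tree$tip.label)
  k <- length(idx)
  if (k <= 1 || k >= n - 1) return(TRUE)
  key <- split_key(idx, n)
  key %in% tree_bipartitions(tree)
}

#' Bootstrap support for a Neighbor-Joining tree
#'
#' Builds the NJ tree of the full alignment, then resamples alignment columns
#' with replacement `replicates` times, rebuilds the tree each time, and
#' scores each internal edge of the original tree by the percentage of
#' replicate trees containing the same leaf bipartition. Supports are stored
#' as numeric node labels on the internal node below each edge (the root
#' label is `NA`).
#'
#' @param block An [aligned_block()] or concatenated alignment.
#' @param model Distance model passed to [distance_matrix()].
#' @param replicates Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional default).
#' @param seed Integer seed; runs with the same seed are identical.
#' @param gamma_shape Optional gamma shape for `k2p_gamma`.
#' @return The original-data NJ `phylo` with `node.label` support percentages
#'   and attribute `"replicates"`.
#' @export
bootstrap_support <- function(block, model = "num_diff", replicates = 1000,
                              seed, gamma_shape = NULL) {
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1) {
    stop_validation("replicates must be >= 1")
  }
  replicates <- as.integer(replicates)
  if (missing(seed) || is.null(seed)) {
    stop_validation("a seed is required for the bootstrap")
  }
  if (!inherits(block, "aligned_block")) block <- aligned_block(block)

  build <- function(enc_cols) {
    dm <- dist_from_encoded(enc_cols, model, gamma_shape)
    nj_tree(dm)
  }
  enc <- encode_alignment(block)
  base_tree <- suppressMessages(nj_tree(distance_matrix(block, model = model,
                                                        gamma_shape = gamma_shape)))
  keys <- tree_bipartitions(base_tree)
  counts <- setNames(rep(0L, length(keys)), keys)

  set.seed(seed)
  n_sites <- ncol(enc)
  for (b in seq_len(replicates)) {
    cols <- sample.int(n_sites, n_sites, replace = TRUE)
    rep_tree <- suppressMessages(build(enc[, cols, drop = FALSE]))
    rep_keys <- tree_bipartitions(rep_tree)
    hits <- keys %in% rep_keys
    counts[hits] <- counts[hits] + 1L
  }
  support <- 100 * counts / replicates

  n <- length(base_tree$tip.label)
  node_label <- rep(NA_real_, base_tree$Nnode)
  key_nodes <- as.integer(names(keys))
  node_label[key_nodes - n] <- support
  base_tree$node.label <- node_label
  attr(base_tree, "replicates") <- replicates
  attr(base_tree, "seed") <- seed
  base_tree
}

# distance matrix straight from an encoded (integer) alignment; used inside
# the bootstrap loop to avoid re-encoding strings each replicate.
dist_from_encoded <- function(enc, model, gamma_shape = NULL) {
  n <- nrow(enc)
  ids <- rownames(enc)
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  if (model == "k2p_gamma" && is.null(gamma_shape)) gamma_shape <- 1
  gs <- if (model == "k2p_gamma") gamma_shape else NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- pair_stats_enc(enc[i, ], enc[j, ])
      v <- if (st$n == 0) {
        NA_real_
      } else if (model %in% c("k2p", "k2p_gamma")) {
        k2p_distance(st$P, st$Q, gs)
      } else if (model == "p") {
        st$diffs / st$n
      } else {
        as.numeric(st$diffs)
      }
      values[i, j] <- values[j, i] <- v
    }
  }
  if (anyNA(values)) {
    stop_computation("undefined distance pair in bootstrap replicate")
  }
  values
}

#' Write a tree in Newick format
#'
#' Branch lengths keep at least 6 significant digits; numeric node labels
#' (bootstrap supports) are written after internal closing parentheses as
#' integer percentages.
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$node.label) && is.numeric(tree$node.label)) {
    lab <- ifelse(is.na(tree$node.label), "",
                  sprintf("%d", as.integer(round(tree$node.label))))
    tree$node.label <- lab
  }
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a tree from a Newick file
#'
#' @param path Newick file path.
#' @return A `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_validation("Newick file not found: '%s'", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) {
    stop_validation("malformed Newick in '%s'", path)
  }
  tree
}
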