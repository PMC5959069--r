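#' UPGMA (average-linkage) clustering of a dissimilarity matrix
#'
#' Unweighted pair-group agglomeration: the distance between two clusters is
#' the arithmetic mean of all cross-pair dissimilarities, and each merge node
#' sits at half the merge distance, so every leaf is equidistant from the
#' root (the tree is ultrametric by construction). Ties in the minimum
#' pairwise distance are broken by the lexicographic order of the smallest
#' member label of each cluster, making the tree deterministic across runs
#' and platforms.
#'
#' @param d a symmetric, zero-diagonal, non-negative square matrix with
#'   labels (e.g. a component of [pairwise_beta_matrices()]), or a
#'   [stats::dist] object
#' @return an object of class \code{upgma_tree}: \code{labels} (leaf
#'   labels), \code{merge} (hclust-style merge table: negative entries are
#'   leaves, positive entries earlier merges), \code{height} (merge
#'   distances, non-decreasing), \code{node_height} (half the merge
#'   distance, the plotted node heights)
#' @seealso [tree_to_newick()]
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2L) stop("need at least 2 items")
  if (any(d < 0)) stop("negative dissimilarities")
  if (any(abs(d - t(d)) > 1e-12)) stop("asymmetric dissimilarity matrix")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  active <- seq_len(n)
  id <- -seq_len(n)             # hclust convention: negative = leaf
  size <- rep(1L, n)
  min_label <- labels           # smallest member label per cluster, for ties
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      dij <- cur[i, j]
      if (dij < best_d - 1e-15) {
        best <- c(i, j); best_d <- dij
      } else if (abs(dij - best_d) <= 1e-15) {
        # tie: prefer the pair whose sorted smallest-member labels come first
        cand <- sort(c(min_label[i], min_label[j]))
        inc <- sort(c(min_label[best[1L]], min_label[best[2L]]))
        if (cand[1L] < inc[1L] ||
            (cand[1L] == inc[1L] && cand[2L] < inc[2L]))
          best <- c(i, j)
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # unweighted average: pool all cross pairs via size weights
    others <- setdiff(seq_len(k), c(i, j))
    newd <- (size[i] * cur[i, others] + size[j] * cur[j, others]) /
      (size[i] + size[j])
    keep <- others
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newd),
                 c(newd, 0))
    id <- c(id[keep], step)
    size <- c(size[keep], size[i] + size[j])
    min_label <- c(min_label[keep], min(min_label[c(i, j)]))
    active <- seq_len(k - 1L)
  }
  structure(list(labels = labels, merge = merge, height = height,
                 node_height = height / 2),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree over %d leaves; merge heights %.4g to %.4g\n",
              length(x$labels), min(x$node_height), max(x$node_height)))
  invisible(x)
}

#' Convert a UPGMA tree to hclust
#'
#' Heights are the node heights (half the merge distances), so
#' [stats::cophenetic()] on the result returns the full merge distance
#' between leaves.
#'
#' @param x an [upgma()] tree
#' @return an object of class \code{hclust}
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "upgma_tree"))
  structure(list(merge = x$merge, height = x$node_height,
                 order = newick_leaf_order(x), labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "dissimilarity"),
            class = "hclust")
}

newick_leaf_order <- function(x) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(x$merge[node, 1L]), walk(x$merge[node, 2L]))
  }
  walk(nrow(x$merge))
}

quote_label <- function(lab) {
  if (grepl("[][ ():;,']", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Newick serialization of a UPGMA tree
#'
#' Branch lengths are differences of node heights (leaves sit at height 0),
#' so re-parsing the string reproduces the leaf set and the cophenetic
#' heights exactly. Labels containing spaces or Newick metacharacters are
#' single-quoted.
#'
#' @param t an [upgma()] tree
#' @param digits significant digits for branch lengths
#' @return a single Newick string terminated by \code{";"}
#' @export
tree_to_newick <- function(t, digits = 10) {
  stopifnot(inherits(t, "upgma_tree"))
  fmt <- function(v) format(v, digits = digits, trim = TRUE,
                            scientific = FALSE, nsmall = 1)
  min_lab <- function(node) {
    if (node < 0L) return(t$labels[-node])
    min(vapply(t$merge[node, ], min_lab, character(1)))
  }
  children <- function(node) {
    kids <- t$merge[node, ]
    kids[order(vapply(kids, min_lab, character(1)))]
  }
  node_str <- function(node, parent_h) {
    if (node < 0L) {
      lab <- t$labels[-node]
      return(paste0(quote_label(lab), ":", fmt(parent_h)))
    }
    h <- t$node_height[node]
    kids <- vapply(children(node), node_str, character(1), parent_h = h)
    paste0("(", paste(kids, collapse = ","), "):", fmt(parent_h - h))
  }
  root <- nrow(t$merge)
  h <- t$node_height[root]
  kids <- vapply(children(root), node_str, character(1), parent_h = h)
  paste0("(", paste(kids, collapse = ","), ");")
}

#' Cluster sites by a beta-diversity component
#'
#' Convenience wrapper: UPGMA tree of one component of the pairwise
#' Sorensen-family decomposition (turnover or nestedness-resultant), the
#' panels typically shown for hierarchically sampled communities.
#'
#' @param pb a [pairwise_beta_matrices()] result
#' @param component \code{"beta_sim"}, \code{"beta_sne"} or
#'   \code{"beta_sor"}
#' @return an [upgma()] tree
#' @export
cluster_beta <- function(pb, component = c("beta_sim", "beta_sne",
                                           "beta_sor")) {
  stopifnot(inherits(pb, "pairwise_beta"))
  component <- match.arg(component)
  upgma(pb[[component]])
}
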