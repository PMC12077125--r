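# Community and metabolite dissimilarity measures, written out from their
# definitions (these primitives are the analytical core of the pipeline and
# are validated against brute-force oracles in the test suite).

#' Bray-Curtis dissimilarity
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}. Two all-zero vectors are
#' maximally similar by convention (0, with a warning).
#'
#' @param x,y non-negative abundance vectors over the same features.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must share a feature space")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  denom <- sum(x + y)
  if (denom == 0) {
    warning("both vectors are all-zero; returning 0")
    return(0)
  }
  sum(abs(x - y)) / denom
}

#' Gower dissimilarity for mixed-scale measurements
#'
#' Mean over features of the range-normalized absolute difference
#' \eqn{|x_i - y_i| / r_i}. Zero-range features carry no information and
#' are excluded with a warning.
#'
#' @param x,y numeric vectors over the same features.
#' @param ranges per-feature ranges \eqn{r_i > 0} (typically max - min over
#'   the full sample set).
#' @return dissimilarity in \[0, 1\] when observations lie within the ranges.
#' @export
gower <- function(x, y, ranges) {
  if (length(x) != length(y) || length(x) != length(ranges)) {
    stop("x, y and ranges must have equal length")
  }
  usable <- ranges > 0
  if (!any(usable)) stop("all features have zero range")
  if (!all(usable)) {
    warning(sum(!usable), " zero-range feature(s) excluded from Gower distance")
  }
  mean(abs(x[usable] - y[usable]) / ranges[usable])
}

# Postorder accumulation of per-edge descendant-tip abundance masses for a
# set of abundance vectors (rows) over tree tips.
edge_masses <- function(tree, abundances) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # mass[k, v] = summed abundance of sample k over tips descending node v
  mass <- matrix(0, nrow(abundances), n_node)
  mass[, seq_len(n_tip)] <- abundances[, tree$tip.label, drop = FALSE]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    mass[, parent] <- mass[, parent] + mass[, child]
  }
  # per original edge: mass below its child node
  mass[, tree$edge[, 2L], drop = FALSE]
}

#' Weighted UniFrac distance
#'
#' Phylogeny-aware dissimilarity: each branch contributes its length times
#' the absolute difference in the total relative abundance of the taxa
#' descending it, \eqn{\sum_b \ell_b |A_b - B_b|} (raw form). The
#' normalized form divides by \eqn{\sum_j d_j (A_j + B_j)}, where
#' \eqn{d_j} is tip `j`'s root-to-tip distance, bounding the distance by 1.
#'
#' @param x,y named relative-abundance vectors; names must all be tips of
#'   `tree`.
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @param normalized return the normalized form (default `FALSE`: the raw
#'   weighted UniFrac of standard 16S pipelines).
#' @return non-negative dissimilarity (at most 1 when normalized).
#' @export
weighted_unifrac <- function(x, y, tree, normalized = FALSE) {
  if (is.null(names(x)) || is.null(names(y))) stop("abundance vectors must be named by taxon")
  missing <- setdiff(union(names(x), names(y)), tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ab <- matrix(0, 2L, length(tree$tip.label),
               dimnames = list(NULL, tree$tip.label))
  ab[1L, names(x)] <- x
  ab[2L, names(y)] <- y
  m <- edge_masses(tree, ab)
  raw <- sum(tree$edge.length * abs(m[1L, ] - m[2L, ]))
  if (!normalized) return(raw)
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depth) <- tree$tip.label
  denom <- sum(depth * (ab[1L, ] + ab[2L, ]))
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise distance matrix over samples
#'
#' Builds the symmetric sample x sample dissimilarity matrix for one of the
#' supported metrics. Rows of `m` are samples.
#'
#' @param m samples x features abundance/measurement matrix with rownames.
#' @param metric `"bray_curtis"`, `"gower"`, `"euclidean"` or
#'   `"weighted_unifrac"`.
#' @param tree required for `"weighted_unifrac"`.
#' @param normalized passed to [weighted_unifrac()].
#' @return object of class `dist_matrix`: the labeled symmetric matrix with
#'   attribute `metric`.
#' @export
distance_matrix <- function(m, metric = c("bray_curtis", "gower", "euclidean",
                                          "weighted_unifrac"),
                            tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric == "euclidean") {
    d[] <- as.matrix(stats::dist(m, method = "euclidean"))
  } else if (metric == "gower") {
    ranges <- apply(m, 2L, function(col) diff(range(col)))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- suppressWarnings(gower(m[i, ], m[j, ], ranges))
    }
  } else if (metric == "bray_curtis") {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  } else {
    if (is.null(tree)) stop("weighted_unifrac requires a tree")
    missing <- setdiff(colnames(m), tree$tip.label)
    if (length(missing)) {
      stop("taxa missing from tree: ", paste(missing, collapse = ", "))
    }
    ab <- matrix(0, n, length(tree$tip.label),
                 dimnames = list(rownames(m), tree$tip.label))
    ab[, colnames(m)] <- m
    masses <- edge_masses(tree, ab)
    depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    tip_tot <- as.numeric(ab %*% depth)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      raw <- sum(tree$edge.length * abs(masses[i, ] - masses[j, ]))
      d[i, j] <- d[j, i] <- if (normalized) {
        den <- tip_tot[i] + tip_tot[j]
        if (den == 0) 0 else raw / den
      } else raw
    }
  }
  structure(d, metric = metric, class = c("dist_matrix", "matrix", "array"))
}
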