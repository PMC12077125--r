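# Glycomic profile normalization, phyloglycomic clustering, size-bin
# summaries and novel-fiber classification.

#' Normalize linkage peak areas to monosaccharide composition
#'
#' Glycosidic linkages ionize at different rates (terminal linkages in
#' particular inflate their raw peak areas), so raw areas are not comparable
#' across parent sugars. For each monosaccharide `m`, the raw areas of the
#' linkages annotated to `m` are rescaled so that they sum exactly to the
#' measured abundance of `m`; the normalized linkage composition then sums
#' to 1 overall. A monosaccharide with nonzero abundance but no annotated
#' linkage mass receives an explicit `unannotated-<m>` feature (the linkage
#' catalogue is never comprehensive), with a warning.
#'
#' @param p a [glycan_profile()].
#' @return the profile with `linkage_norm` filled (a named vector of
#'   fractions summing to 1).
#' @export
normalize_linkages <- function(p) {
  stopifnot(inherits(p, "glycan_profile"))
  if (any(p$linkage_raw < 0)) stop("negative raw linkage areas")
  norm <- numeric(0)
  for (m in names(p$mono_abundance)) {
    am <- p$mono_abundance[[m]]
    lk <- names(p$linkage_raw)[p$linkage_parent == m]
    total <- sum(p$linkage_raw[lk])
    if (am <= 0) {
      if (length(lk)) norm[lk] <- 0
      next
    }
    if (total <= 0) {
      warning(sprintf("no annotated linkage area for '%s'; assigning its mass to 'unannotated-%s'",
                      m, m))
      norm[[paste0("unannotated-", m)]] <- am
    } else {
      norm[lk] <- p$linkage_raw[lk] / total * am
    }
  }
  p$linkage_norm <- norm
  p
}

#' Assemble a fibers x features profile matrix
#'
#' Stacks one glycomic layer across fibers into a labeled matrix with the
#' union of features as columns; features absent from a fiber are 0. Rows
#' are compositions (sum 1).
#'
#' @param fibers list of [glycan_profile()].
#' @param layer `"mono"` (monosaccharide composition) or `"linkage"`
#'   (normalized linkage composition; requires [normalize_linkages()]).
#' @return numeric matrix fibers x features.
#' @export
build_profile_matrix <- function(fibers, layer = c("mono", "linkage")) {
  layer <- match.arg(layer)
  vecs <- lapply(fibers, function(p) {
    stopifnot(inherits(p, "glycan_profile"))
    if (layer == "mono") return(p$mono_abundance)
    if (is.null(p$linkage_norm)) {
      stop(sprintf("linkage layer requested but '%s' has not been normalized; run normalize_linkages() first",
                   p$fiber_id))
    }
    p$linkage_norm
  })
  features <- unique(unlist(lapply(vecs, names)))
  m <- matrix(0, length(fibers), length(features),
              dimnames = list(vapply(fibers, `[[`, character(1), "fiber_id"),
                              features))
  for (i in seq_along(vecs)) m[i, names(vecs[[i]])] <- vecs[[i]]
  m
}

#' Hierarchical phyloglycomic grouping of fibers
#'
#' Agglomerative clustering of fiber profiles on Euclidean distance,
#' cut into `k` groups. Group ids are letters assigned by dendrogram
#' left-to-right order, so relabeling is stable and readable. The cut
#' height separating the `k`-group and `(k-1)`-group solutions is recorded
#' so the labels can be reproduced from the dendrogram alone.
#'
#' @param m fibers x features matrix from [build_profile_matrix()].
#' @param k number of groups, `1 <= k <= nrow(m)`.
#' @param linkage_method agglomeration method for [stats::hclust()]
#'   (default `"complete"`, the convention of standard heatmap tooling).
#' @return object of class `phyloglycomic_grouping`: list with `dendrogram`
#'   (an `hclust`), `labels` (named character vector fiber -> group letter),
#'   `k`, `cut_height`, `linkage_method`.
#' @export
phyloglycomic_cluster <- function(m, k, linkage_method = "complete") {
  stopifnot(is.matrix(m))
  n <- nrow(m)
  if (n < 2) stop("at least 2 fibers are required for clustering")
  if (k < 1 || k > n) stop(sprintf("k must lie in [1, %d]", n))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = linkage_method)
  raw <- stats::cutree(hc, k = k)
  # relabel clusters by first appearance in dendrogram leaf order
  order_first <- unique(raw[hc$order])
  letters_map <- stats::setNames(group_letters(k), order_first)
  labels <- stats::setNames(unname(letters_map[as.character(raw)]), names(raw))
  heights <- sort(hc$height)
  cut_height <- if (k == 1) {
    max(hc$height) + 1
  } else if (k == n) {
    0
  } else {
    # any height strictly between the (n-k)th and (n-k+1)th merges gives k groups
    mean(heights[c(n - k, n - k + 1L)])
  }
  structure(
    list(dendrogram = hc, labels = labels, k = k,
         cut_height = cut_height, linkage_method = linkage_method),
    class = "phyloglycomic_grouping"
  )
}

#' @export
print.phyloglycomic_grouping <- function(x, ...) {
  cat(sprintf("<phyloglycomic_grouping> %d fibers in %d groups (%s linkage)\n",
              length(x$labels), x$k, x$linkage_method))
  print(table(x$labels))
  invisible(x)
}

# Parse size-bin labels like "0.21-0.93", "105-851", ">1000", "<0.2" into
# (lower, upper) kDa bounds.
parse_size_bin <- function(labels) {
  lo <- hi <- numeric(length(labels))
  for (i in seq_along(labels)) {
    lab <- gsub("–", "-", trimws(labels[i]))  # en-dash tolerated
    if (grepl("^>", lab)) {
      lo[i] <- as.numeric(sub("^>", "", lab)); hi[i] <- Inf
    } else if (grepl("^<", lab)) {
      lo[i] <- 0; hi[i] <- as.numeric(sub("^<", "", lab))
    } else {
      parts <- as.numeric(strsplit(lab, "-", fixed = TRUE)[[1L]])
      if (length(parts) != 2L || anyNA(parts)) {
        stop("cannot parse size-bin label: ", labels[i])
      }
      lo[i] <- parts[1L]; hi[i] <- parts[2L]
    }
  }
  data.frame(label = labels, lower_kda = lo, upper_kda = hi,
             stringsAsFactors = FALSE)
}

#' Summarize a fiber's size-bin distribution
#'
#' Reports the dominant size bin (ties broken toward the smallest size
#' range) and the fraction of molecules at least as large as a threshold
#' (default 1000 kDa, the scale at which some fiber pools keep half their
#' mass as very large material).
#'
#' @param p a [glycan_profile()] with `size_bins`.
#' @param large_threshold_kda lower bound defining "large" molecules.
#' @return list with `dominant_bin`, `dominant_fraction`,
#'   `fraction_above_threshold`, `threshold_kda`, and the parsed
#'   `bins` table with cumulative fractions (smallest size first).
#' @export
size_distribution_summary <- function(p, large_threshold_kda = 1000) {
  stopifnot(inherits(p, "glycan_profile"))
  if (is.null(p$size_bins) || !length(p$size_bins)) {
    stop("profile has no size_bins")
  }
  bins <- parse_size_bin(names(p$size_bins))
  bins$fraction <- as.numeric(p$size_bins)
  ord <- order(bins$lower_kda, bins$upper_kda)
  bins <- bins[ord, ]
  bins$cumulative <- cumsum(bins$fraction)
  # dominant bin: max fraction, ties -> smallest size range
  dom <- which(bins$fraction == max(bins$fraction))[1L]
  frac_large <- sum(bins$fraction[bins$lower_kda >= large_threshold_kda])
  list(dominant_bin = bins$label[dom],
       dominant_fraction = bins$fraction[dom],
       fraction_above_threshold = frac_large,
       threshold_kda = large_threshold_kda,
       bins = bins)
}

#' Classify a novel fiber into a fitted phyloglycomic grouping
#'
#' Predicts the group of an unseen fiber as the group with the smallest
#' mean distance between the novel profile and the group's reference
#' members, using Euclidean distance on the monosaccharide layer or
#' Bray-Curtis dissimilarity on the (normalized) linkage layer. Features
#' unseen in the references are zero-filled on both sides; if the novel
#' fiber carries most of its mass on features absent from every reference,
#' the prediction is still returned but flagged with a warning.
#'
#' @param novel a [glycan_profile()] (normalized first when
#'   `layer = "linkage"`).
#' @param reference_fibers the fibers the grouping was fitted on.
#' @param grouping a [phyloglycomic_cluster()] result on those fibers.
#' @param layer `"mono"` or `"linkage"`.
#' @param distance `"euclidean"` or `"bray_curtis"`.
#' @return list with `predicted_group`, `group_distances` (sorted ascending
#'   mean distances), `fiber_distances` (per reference fiber), and
#'   `off_support` (fraction of the novel profile's mass on features absent
#'   from all references).
#' @export
classify_novel_fiber <- function(novel, reference_fibers, grouping,
                                 layer = c("mono", "linkage"),
                                 distance = c("euclidean", "bray_curtis")) {
  layer <- match.arg(layer)
  distance <- match.arg(distance)
  stopifnot(inherits(grouping, "phyloglycomic_grouping"))
  ref <- build_profile_matrix(reference_fibers, layer)
  if (!all(rownames(ref) %in% names(grouping$labels))) {
    stop("grouping was not fitted on these reference fibers")
  }
  nov <- build_profile_matrix(list(novel), layer)
  feats <- union(colnames(ref), colnames(nov))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(feats), dimnames = list(rownames(m), feats))
    out[, colnames(m)] <- m
    out
  }
  ref <- pad(ref); nov <- pad(nov)[1L, ]
  off_support <- sum(nov[setdiff(feats, colnames(build_profile_matrix(reference_fibers, layer)))])
  if (off_support > 0.5) {
    warning(sprintf("%.0f%% of the novel profile lies on features unseen in the references; distances are near-maximal",
                    100 * off_support))
  }
  d <- apply(ref, 1L, function(r) {
    if (distance == "euclidean") sqrt(sum((r - nov)^2)) else bray_curtis(r, nov)
  })
  groups <- grouping$labels[rownames(ref)]
  mean_d <- tapply(d, groups, mean)
  mean_d <- sort(mean_d)
  list(predicted_group = names(mean_d)[1L],
       group_distances = mean_d,
       fiber_distances = sort(d),
       off_support = off_support)
}
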