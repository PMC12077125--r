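# Determinism scoring of donor responses: per-donor normalization of a
# joint ordination to the untreated control, displacement vectors, mean
# pairwise cosine similarity, and k-means clustering of treatment
# trajectories.

#' Normalize ordination coordinates to each donor's untreated control
#'
#' Given a single joint ordination over all donors x treatments (at one
#' time point), subtracts each donor's untreated coordinates from all of
#' that donor's sample coordinates, placing every untreated control at the
#' origin. The remaining vectors are the donor's displacement under each
#' treatment.
#'
#' @param ord an [nmds()] result (or any object with a `coordinates`
#'   matrix), rows named by sample id; alternatively a bare coordinate
#'   matrix.
#' @param samples data.frame with columns `sample_id`, `donor_id`,
#'   `treatment` covering the ordination rows.
#' @return object of class `displacement_set`: data.frame with columns
#'   `donor_id`, `treatment`, and one `dim<k>` column per ordination axis;
#'   attribute `origin_policy = "untreated_to_origin"`.
#' @export
normalize_shifts <- function(ord, samples) {
  coords <- if (is.matrix(ord)) ord else ord$coordinates
  req <- c("sample_id", "donor_id", "treatment")
  if (!all(req %in% names(samples))) {
    stop("samples must contain columns: ", paste(req, collapse = ", "))
  }
  samples <- samples[samples$sample_id %in% rownames(coords), , drop = FALSE]
  if (!nrow(samples)) stop("no metadata rows match the ordination")
  out <- list()
  for (donor in unique(samples$donor_id)) {
    rows <- samples[samples$donor_id == donor, , drop = FALSE]
    ctrl <- rows$sample_id[rows$treatment == "untreated"]
    if (length(ctrl) == 0L) stop("donor without an untreated sample: ", donor)
    if (length(ctrl) > 1L) stop("duplicate untreated samples for donor: ", donor)
    origin <- coords[ctrl, ]
    disp <- sweep(coords[rows$sample_id, , drop = FALSE], 2L, origin, "-")
    out[[donor]] <- data.frame(donor_id = donor, treatment = rows$treatment,
                               disp, row.names = NULL,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  names(res)[-(1:2)] <- paste0("dim", seq_len(ncol(coords)))
  rownames(res) <- NULL
  structure(res, origin_policy = "untreated_to_origin",
            class = c("displacement_set", "data.frame"))
}

displacement_vectors <- function(ds, treatment) {
  stopifnot(inherits(ds, "displacement_set"))
  rows <- ds[ds$treatment == treatment, , drop = FALSE]
  if (!nrow(rows)) stop("no displacements for treatment: ", treatment)
  m <- as.matrix(rows[, grep("^dim", names(rows)), drop = FALSE])
  rownames(m) <- rows$donor_id
  m
}

#' Cosine similarity of two vectors
#'
#' \eqn{u \cdot v / (\lVert u \rVert \lVert v \rVert)}; undefined for
#' zero-norm input (error — aggregation-level functions exclude such
#' vectors explicitly).
#'
#' @param u,v numeric vectors of equal length.
#' @return similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Mean pairwise cosine similarity of donor displacements
#'
#' The determinism score for one treatment: cosine similarity between every
#' unordered pair of donors' displacement vectors, averaged. A score near 1
#' means all donors moved in the same direction under the treatment
#' (glycan-driven response); near 0, donors moved in unrelated directions.
#' Donors with an exactly zero displacement are excluded (cosine is
#' undefined at zero) and counted in the output.
#'
#' @param ds a [normalize_shifts()] result.
#' @param treatment fiber id to score.
#' @return list with `score`, `n_pairs`, `n_donors_used`, `n_excluded`.
#' @export
mean_pairwise_cosine <- function(ds, treatment) {
  m <- displacement_vectors(ds, treatment)
  norms <- sqrt(rowSums(m^2))
  usable <- norms > 0
  n_excluded <- sum(!usable)
  m <- m[usable, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 donors with nonzero displacement")
  unit <- m / sqrt(rowSums(m^2))
  g <- unit %*% t(unit)
  pairs <- g[lower.tri(g)]
  list(score = mean(pairs), n_pairs = length(pairs),
       n_donors_used = nrow(m), n_excluded = n_excluded)
}

#' Score every treatment in a displacement set
#'
#' @param ds a [normalize_shifts()] result.
#' @param treatments treatments to score (default: all except untreated).
#' @return data.frame with one row per treatment: `treatment`, `score`,
#'   `n_pairs`, `n_excluded`.
#' @export
determinism_scores <- function(ds, treatments = NULL) {
  if (is.null(treatments)) {
    treatments <- setdiff(unique(ds$treatment), "untreated")
  }
  rows <- lapply(treatments, function(tr) {
    s <- mean_pairwise_cosine(ds, tr)
    data.frame(treatment = tr, score = s$score, n_pairs = s$n_pairs,
               n_excluded = s$n_excluded, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' K-means clustering of mean treatment trajectories
#'
#' Averages each treatment's displacement over donors and clusters the
#' resulting mean vectors with k-means (multiple restarts, best inertia
#' kept, deterministic given `seed`).
#'
#' @param ds a [normalize_shifts()] result.
#' @param k number of clusters, `1 <= k <=` number of treatments.
#' @param seed integer seed.
#' @param n_start random restarts (default 10).
#' @return list with `cluster` (named treatment -> cluster id),
#'   `centers`, `inertia` (total within-cluster sum of squares).
#' @export
kmeans_trajectories <- function(ds, k, seed = 1L, n_start = 10) {
  treatments <- setdiff(unique(ds$treatment), "untreated")
  means <- t(vapply(treatments,
                    function(tr) colMeans(displacement_vectors(ds, tr)),
                    numeric(sum(grepl("^dim", names(ds))))))
  rownames(means) <- treatments
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(means)) stop("k exceeds the number of treatments")
  set.seed(as.integer(seed))
  if (k == nrow(means)) {
    return(list(cluster = stats::setNames(seq_len(k), treatments),
                centers = means, inertia = 0))
  }
  if (nrow(unique(means)) < k) {
    # degenerate: fewer distinct mean vectors than clusters; assign by
    # first-occurrence order of the distinct vectors, extra clusters empty
    key <- apply(means, 1L, paste, collapse = "\r")
    cl <- as.integer(factor(key, levels = unique(key)))
    centers <- unique(means)
    return(list(cluster = stats::setNames(cl, treatments), centers = centers,
                inertia = 0))
  }
  km <- stats::kmeans(means, centers = k, nstart = n_start)
  list(cluster = stats::setNames(km$cluster, treatments),
       centers = km$centers, inertia = km$tot.withinss)
}
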