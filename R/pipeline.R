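# End-to-end determinism scoring: distance matrix on one data layer at the
# analysis end point, joint NMDS over all donors x treatments, per-donor
# untreated normalization, and mean pairwise cosine similarity per fiber.

#' Determinism scores for every fiber in a fermentation dataset
#'
#' Runs the shift analysis end to end on one data layer: builds the
#' dissimilarity matrix over all samples at `time_h` (all donors and
#' treatments jointly), embeds it with [nmds()], normalizes each donor's
#' coordinates to its untreated control with [normalize_shifts()], and
#' scores every fiber with [mean_pairwise_cosine()].
#'
#' @param ds a [fermentation_dataset()].
#' @param layer `"metabolites"` (SCFA profiles) or `"taxa"` (community
#'   composition).
#' @param metric dissimilarity for [distance_matrix()]; defaults to
#'   Bray-Curtis for metabolites and weighted UniFrac for taxa.
#' @param time_h analysis end point (default 24 h).
#' @param dims,n_restarts,seed passed to [nmds()].
#' @return list with `scores` (data.frame from [determinism_scores()]),
#'   `ordination`, `displacements`.
#' @export
fermentation_shift_scores <- function(ds,
                                      layer = c("metabolites", "taxa"),
                                      metric = NULL, time_h = 24, dims = 2,
                                      n_restarts = 2, seed = 1L) {
  layer <- match.arg(layer)
  stopifnot(inherits(ds, "fermentation_dataset"))
  meta <- ds$samples[ds$samples$time_h == time_h, , drop = FALSE]
  if (!nrow(meta)) stop("no samples at time ", time_h, " h")
  m <- ds[[layer]][meta$sample_id, , drop = FALSE]
  if (is.null(metric)) {
    metric <- if (layer == "metabolites") "bray_curtis" else "weighted_unifrac"
  }
  d <- distance_matrix(m, metric, tree = ds$tree)
  ord <- nmds(d, dims = dims, n_restarts = n_restarts, seed = seed)
  disp <- normalize_shifts(ord, meta)
  list(scores = determinism_scores(disp), ordination = ord,
       displacements = disp)
}
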