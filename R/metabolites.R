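# SCFA end-product summaries: max-scaled heatmap tables, hierarchical
# ordering of treatments and metabolites, butyrate:propionate ratios,
# donor-penetrance CCDF curves, and taxon-metabolite correlation.

#' Scale a treatment x metabolite table to per-metabolite maxima
#'
#' Sets the maximum measured value of each metabolite column to 100% and
#' expresses all other values relative to it, the standard scaling for
#' cross-metabolite heatmaps. All-zero columns stay zero (warning).
#'
#' @param table numeric matrix, treatments x metabolites, values >= 0.
#' @return matrix of the same shape in \[0, 100\].
#' @export
scale_to_max <- function(table) {
  stopifnot(is.matrix(table) || is.data.frame(table))
  m <- as.matrix(table)
  if (any(m < 0, na.rm = TRUE)) stop("negative concentrations")
  maxima <- apply(m, 2L, max, na.rm = TRUE)
  zero <- maxima == 0
  if (any(zero)) {
    warning("all-zero metabolite column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
    maxima[zero] <- 1
  }
  sweep(m, 2L, maxima, "/") * 100
}

#' Row and column ordering for an SCFA heatmap
#'
#' Clusters treatments (rows) and metabolites (columns) independently with
#' hierarchical clustering on Euclidean distance and returns both orders
#' and dendrograms, ready for heatmap rendering.
#'
#' @param scaled numeric matrix (typically from [scale_to_max()]), at
#'   least 2 rows and 2 columns.
#' @param linkage_method agglomeration method (default `"complete"`).
#' @return list with `row_order`, `col_order` (label vectors),
#'   `row_dendrogram`, `col_dendrogram` (`hclust` objects).
#' @export
cluster_heatmap_data <- function(scaled, linkage_method = "complete") {
  m <- as.matrix(scaled)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  if (any(!is.finite(m))) stop("non-finite values")
  hr <- stats::hclust(stats::dist(m), method = linkage_method)
  hc <- stats::hclust(stats::dist(t(m)), method = linkage_method)
  list(row_order = rownames(m)[hr$order], col_order = colnames(m)[hc$order],
       row_dendrogram = hr, col_dendrogram = hc)
}

#' Butyrate:propionate ratio of one sample
#'
#' Scalar summary of the metabolic skew of a fermentation. Zero propionate
#' makes the ratio undefined; it is returned as `NA` with a warning rather
#' than infinity.
#'
#' @param metabolites named concentration vector containing `butyrate` and
#'   `propionate` (ug/mL).
#' @return the dimensionless ratio, or `NA` when propionate is 0.
#' @export
butyrate_propionate_ratio <- function(metabolites) {
  for (need in c("butyrate", "propionate")) {
    if (!need %in% names(metabolites)) stop("metabolite absent: ", need)
  }
  p <- metabolites[["propionate"]]
  if (p == 0) {
    warning("propionate is 0; butyrate:propionate ratio undefined, returning NA")
    return(NA_real_)
  }
  metabolites[["butyrate"]] / p
}

#' Donor-penetrance CCDF of a metabolite
#'
#' Complementary cumulative distribution across donors: the fraction of
#' donors whose fermentation reached at least each concentration level,
#' \eqn{S(c) = \#\{v_d \ge c\}/N} (inclusive thresholds). Evaluated at all
#' observed values plus any extra grid points.
#'
#' @param values named per-donor concentrations (ug/mL), >= 0.
#' @param metabolite metabolite name recorded in the curve.
#' @param time_h analysis time point recorded in the curve.
#' @param grid optional additional threshold values.
#' @return object of class `ccdf_curve`: list with `metabolite`, `time_h`,
#'   `thresholds` (ascending), `survival`, `n_donors`,
#'   `step_convention = "right_continuous_inclusive"`.
#' @export
ccdf_curve <- function(values, metabolite = "butyrate", time_h = 24,
                       grid = NULL) {
  if (!length(values)) stop("no donor values")
  if (any(values < 0)) stop("negative concentrations")
  thresholds <- sort(unique(c(values, grid)))
  survival <- vapply(thresholds, function(c) mean(values >= c), numeric(1))
  structure(
    list(metabolite = metabolite, time_h = time_h, thresholds = thresholds,
         survival = survival, n_donors = length(values),
         step_convention = "right_continuous_inclusive"),
    class = "ccdf_curve"
  )
}

#' Evaluate a CCDF at arbitrary thresholds
#'
#' @param curve a [ccdf_curve()].
#' @param c concentration threshold(s).
#' @return survival fraction(s) `S(c)`.
#' @export
ccdf_survival_at <- function(curve, c) {
  vapply(c, function(ci) {
    idx <- curve$thresholds >= ci
    if (!any(idx)) return(0)
    # survival is constant between observed values; S(c) equals the
    # survival at the smallest observed threshold >= c
    curve$survival[which(idx)[1L]]
  }, numeric(1))
}

#' Concentration level reached by at least a fraction of donors
#'
#' The largest threshold `c` with `S(c) >= q`: the metabolite level that at
#' least a fraction `q` of donors were able to produce (e.g. the level half
#' the cohort reaches at `q = 0.5`).
#'
#' @param curve a [ccdf_curve()].
#' @param q fraction of donors, `0 < q <= 1`.
#' @return concentration (ug/mL).
#' @export
level_at_survival <- function(curve, q) {
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  ok <- curve$survival >= q
  if (!any(ok)) stop("no threshold reaches survival ", q)
  max(curve$thresholds[ok])
}

#' @export
print.ccdf_curve <- function(x, ...) {
  cat(sprintf("<ccdf_curve> %s at %g h over %d donors; S spans [%.2f, %.2f] across %d thresholds\n",
              x$metabolite, x$time_h, x$n_donors, min(x$survival),
              max(x$survival), length(x$thresholds)))
  invisible(x)
}

#' Pearson correlation between a taxon and a metabolite
#'
#' Pairs one taxon's relative abundance with one metabolite's concentration
#' across all samples at a given time point and reports the Pearson
#' correlation with its two-sided t-test p-value.
#'
#' @param ds a [fermentation_dataset()].
#' @param taxon taxon id (column of the taxa matrix).
#' @param metabolite metabolite name.
#' @param time_h time point to pair at (default 24).
#' @return list with `r`, `p_value`, `n`.
#' @export
taxon_metabolite_correlation <- function(ds, taxon, metabolite, time_h = 24) {
  stopifnot(inherits(ds, "fermentation_dataset"))
  ids <- ds$samples$sample_id[ds$samples$time_h == time_h]
  ids <- intersect(ids, intersect(rownames(ds$taxa), rownames(ds$metabolites)))
  x <- ds$taxa[ids, taxon]
  y <- ds$metabolites[ids, metabolite]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
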