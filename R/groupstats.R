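# Group-comparison statistics for bifidogenicity claims and structural
# feature attribution: Kruskal-Wallis, Dunn's test against a reference
# treatment with Benjamini-Hochberg correction, and random-forest feature
# importance.

#' Kruskal-Wallis rank test across treatment groups
#'
#' Nonparametric one-way analysis of variance on ranks with tie
#' correction; the chi-square approximation with `a - 1` degrees of
#' freedom gives the p-value. When every observation is tied the statistic
#' is 0 by convention and the result is flagged.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   total n >= 3).
#' @return list with `h`, `p_value`, `df`, `all_tied` flag.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop("need total n >= 3")
  if (length(unique(values)) == 1L) {
    return(list(h = 0, p_value = 1, df = length(groups) - 1L, all_tied = TRUE))
  }
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, labels)
  list(h = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), all_tied = FALSE)
}

#' Dunn's test of every treatment against a reference
#'
#' Post-hoc rank comparison following Kruskal-Wallis, restricted to the
#' comparisons against one reference treatment (e.g. a known bifidogenic
#' comparator). For treatment `t` with mean pooled-rank \eqn{\bar R_t},
#' \deqn{z_t = \frac{\bar R_t - \bar R_{ref}}
#'   {\sqrt{\left[\frac{N(N+1)}{12} - \frac{\sum (\tau^3 - \tau)}{12(N-1)}\right]
#'    \left(\frac{1}{n_t} + \frac{1}{n_{ref}}\right)}}}
#' with mid-ranks and the usual tie-correction term. Two-sided normal
#' p-values are Benjamini-Hochberg adjusted over the family of
#' vs-reference comparisons only; treatments whose adjusted p is >= alpha
#' are flagged as not significantly different from the reference.
#'
#' @param groups named list of numeric vectors (treatment -> observations);
#'   must include `reference`. Each compared group needs n >= 2.
#' @param reference name of the reference treatment.
#' @param alpha significance level for the not-different flag.
#' @return object of class `posthoc_result`: data.frame `comparisons` with
#'   columns `treatment`, `reference`, `z`, `p_raw`, `p_adjusted`,
#'   `significant`, `not_different_from_reference`; plus `alpha` and
#'   `reference` attributes.
#' @export
dunn_vs_reference <- function(groups, reference, alpha = 0.05) {
  if (!reference %in% names(groups)) stop("reference group missing: ", reference)
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) stop("all observations tied; ranks carry no information")
  labels <- rep(names(groups), lengths(groups))
  n_total <- length(values)
  r <- rank(values)  # mid-ranks
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n_total - 1))
  var_core <- n_total * (n_total + 1) / 12 - tie_term
  mean_rank <- tapply(r, labels, mean)
  n_g <- tapply(r, labels, length)
  others <- setdiff(names(groups), reference)
  z <- vapply(others, function(t) {
    (mean_rank[[t]] - mean_rank[[reference]]) /
      sqrt(var_core * (1 / n_g[[t]] + 1 / n_g[[reference]]))
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  comparisons <- data.frame(
    treatment = others, reference = reference, z = unname(z),
    p_raw = unname(p_raw), p_adjusted = unname(p_adj),
    significant = unname(p_adj < alpha),
    not_different_from_reference = unname(p_adj >= alpha),
    stringsAsFactors = FALSE)
  structure(comparisons, alpha = alpha, reference = reference,
            class = c("posthoc_result", "data.frame"))
}

#' Random-forest importance of glycomic features for a response
#'
#' Fits a random-forest regression (500 trees, 5 candidate variables per
#' split by default) of a numeric response — typically endpoint butyrate —
#' on fiber structural features, and returns the permutation importances
#' ranked. The deliverable is the feature ranking; the fitted forest is
#' returned for inspection only.
#'
#' @param features samples x features numeric matrix (>= 10 samples).
#' @param response numeric vector, one value per sample.
#' @param n_trees number of trees (default 500).
#' @param m_try candidate variables per split (default 5, capped at the
#'   number of features).
#' @param seed integer seed.
#' @return list with `ranking` (data.frame `feature`, `importance`, sorted
#'   decreasing), `model`, `seed`.
#' @export
rf_feature_importance <- function(features, response, n_trees = 500,
                                  m_try = 5, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need at least 10 samples")
  if (length(response) != nrow(features)) stop("response length mismatch")
  if (stats::sd(response) == 0) stop("constant response")
  m_try <- min(m_try, ncol(features))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = features, y = response,
                                    ntree = n_trees, mtry = m_try,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1L]
  ord <- order(imp, decreasing = TRUE)
  list(ranking = data.frame(feature = names(imp)[ord],
                            importance = unname(imp[ord]),
                            stringsAsFactors = FALSE),
       model = fit, seed = as.integer(seed))
}
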