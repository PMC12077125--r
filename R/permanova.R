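# Distance-based permutational multivariate analysis of variance.

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng > 1L) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / ng
    }
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

permanova_f <- function(d2, groups, a, n) {
  ss <- permanova_ss(d2, groups)
  (ss[["among"]] / (a - 1)) / (ss[["within"]] / (n - a))
}

# All distinct assignments of the multiset of group labels to positions.
enumerate_label_permutations <- function(groups) {
  rec <- function(remaining) {
    if (!length(remaining)) return(list(character(0)))
    out <- list()
    for (g in unique(remaining)) {
      rest <- remaining[-match(g, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(g, tail)
    }
    out
  }
  rec(sort(groups))
}

n_distinct_permutations <- function(groups) {
  counts <- table(groups)
  exp(lgamma(length(groups) + 1) - sum(lgamma(counts + 1)))
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance. The pseudo-F
#' statistic is built from squared inter-sample distances:
#' \eqn{SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2},
#' \eqn{F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(N-a)}}.
#' The p-value permutes group labels; when the number of distinct
#' relabelings does not exceed `n_perm` the full enumeration is used and
#' the p-value is exact, otherwise `n_perm` random permutations are drawn
#' and the +1-corrected Monte-Carlo estimate
#' \eqn{(1 + \#\{F^\pi \ge F\}) / (1 + n_{perm})} is reported.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (length `nrow(d)`), >= 2 groups.
#' @param n_perm number of permutations, >= 99.
#' @param seed integer seed for the permutation stream.
#' @return list with `f` (pseudo-F), `p_value`, `df` (among, within),
#'   `ss` (total/within/among), `n_perm_used`, `exhaustive` flag, and
#'   `degenerate` flag (TRUE when all distances are equal, leaving F
#'   undefined or 0).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("groups must match the distance matrix")
  a <- length(unique(groups))
  if (a < 2) stop("need at least 2 groups")
  if (any(table(groups) < 1)) stop("empty group")
  if (n_perm < 99) stop("n_perm must be >= 99")
  n <- nrow(d)
  d2 <- d^2
  ss <- permanova_ss(d2, groups)
  degenerate <- ss[["within"]] <= .Machine$double.eps * n^2 ||
    isTRUE(all.equal(stats::sd(d[lower.tri(d)]), 0))
  f_obs <- if (ss[["within"]] <= 0) {
    if (ss[["among"]] <= 0) 0 else Inf
  } else {
    (ss[["among"]] / (a - 1)) / (ss[["within"]] / (n - a))
  }

  if (n_distinct_permutations(groups) <= n_perm) {
    perms <- enumerate_label_permutations(groups)
    f_perm <- vapply(perms, function(g) permanova_f(d2, g, a, n), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
    exhaustive <- TRUE
  } else {
    set.seed(as.integer(seed))
    f_perm <- vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, groups[sample.int(n)], a, n)
    }, numeric(1))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
    exhaustive <- FALSE
  }
  list(f = unname(f_obs), p_value = unname(p), df = c(among = a - 1, within = n - a),
       ss = ss, n_perm_used = n_used, exhaustive = exhaustive,
       degenerate = unname(degenerate))
}
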