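# Non-metric multidimensional scaling by iterative stress majorization:
# alternate a Guttman-transform configuration update with monotone
# regression of the configuration distances on the rank order of the input
# dissimilarities. Quality is Kruskal's stress-1.

#' Kruskal stress-1
#'
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} over sample pairs, where `d`
#' are configuration distances and `dhat` the monotone-regressed
#' disparities.
#' @keywords internal
kruskal_stress1 <- function(d, dhat) {
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

# Factory for the monotone (isotonic) regression of configuration
# distances on the ascending order of the dissimilarities delta. The
# ordering and tie blocks of delta are fixed across iterations, so they
# are computed once; tied dissimilarities are pooled (tied blocks share a
# fitted value, obtained by isotonic regression on block means).
make_disparity_fn <- function(delta) {
  ord <- order(delta)
  block <- cumsum(c(TRUE, diff(delta[ord]) > 0))
  sizes <- tabulate(block)
  has_ties <- any(sizes > 1L)
  inv <- integer(length(delta))
  inv[ord] <- seq_along(delta)
  function(d) {
    z <- d[ord]
    if (has_ties) {
      z <- (rowsum(z, block)[, 1L] / sizes)[block]
    }
    stats::isoreg(z)$yf[inv]
  }
}

lower_tri_dist <- function(x) {
  as.numeric(stats::dist(x))
}

# One Guttman transform update of configuration X toward disparities dhat.
guttman_update <- function(x, dhat, d) {
  n <- nrow(x)
  ratio <- matrix(0, n, n)
  ratio[lower.tri(ratio)] <- ifelse(d > 0, dhat / d, 0)
  ratio <- ratio + t(ratio)
  b <- -ratio
  diag(b) <- rowSums(ratio)
  (b %*% x) / n
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `dims` dimensions preserving the rank
#' order of dissimilarities. Each restart alternates monotone regression
#' (pooled ties) with a Guttman-transform majorization step; a step-halving
#' safeguard guarantees the stress-1 trace never increases within a
#' restart. The first restart starts from classical metric scaling, later
#' restarts from seeded random configurations; the best-stress solution is
#' returned with coordinates centered on the origin.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [distance_matrix()]).
#' @param dims embedding dimension, >= 2.
#' @param n_restarts number of starts (>= 1).
#' @param seed integer seed; results are deterministic given it.
#' @param maxit,tol iteration cap and stress-change convergence tolerance
#'   per restart.
#' @return object of class `ordination`: list with `coordinates`
#'   (samples x dims, column means 0), `stress` (Kruskal stress-1),
#'   `converged`, `n_restarts`, `seed`, and `stress_trace` of the winning
#'   restart.
#' @export
nmds <- function(d, dims = 2, n_restarts = 4, seed = 1L, maxit = 200,
                 tol = 1e-6) {
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(!is.finite(d))) stop("non-finite dissimilarities")
  if (dims < 2) stop("dims must be >= 2")
  n <- nrow(d)
  if (n < dims + 1) stop("need at least dims + 1 samples")
  delta <- d[lower.tri(d)]
  disparities <- make_disparity_fn(delta)
  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      x <- suppressWarnings(stats::cmdscale(d, k = dims))
      if (ncol(x) < dims) {
        x <- cbind(x, matrix(stats::rnorm(n * (dims - ncol(x)), 0, 1e-4), n))
      }
    } else {
      x <- matrix(stats::rnorm(n * dims), n, dims)
    }
    dd <- lower_tri_dist(x)
    if (all(dd == 0)) dd <- dd + 1e-12
    dhat <- disparities(dd)
    stress <- kruskal_stress1(dd, dhat)
    trace <- stress
    converged <- FALSE
    for (it in seq_len(maxit)) {
      x_new <- guttman_update(x, dhat, dd)
      dd_new <- lower_tri_dist(x_new)
      dhat_new <- disparities(dd_new)
      stress_new <- kruskal_stress1(dd_new, dhat_new)
      # safeguard: step-halve toward the previous configuration if the
      # majorization step overshot in stress-1 terms
      halvings <- 0L
      while (stress_new > stress && halvings < 8L) {
        x_new <- (x_new + x) / 2
        dd_new <- lower_tri_dist(x_new)
        dhat_new <- disparities(dd_new)
        stress_new <- kruskal_stress1(dd_new, dhat_new)
        halvings <- halvings + 1L
      }
      if (stress_new > stress) { converged <- TRUE; break }
      improvement <- stress - stress_new
      x <- x_new; dd <- dd_new; dhat <- dhat_new; stress <- stress_new
      trace <- c(trace, stress)
      if (improvement < tol) { converged <- TRUE; break }
    }
    if (is.null(best) || stress < best$stress) {
      best <- list(x = x, stress = stress, converged = converged, trace = trace)
    }
  }
  coords <- scale(best$x, center = TRUE, scale = FALSE)
  dimnames(coords) <- list(rownames(d), paste0("NMDS", seq_len(dims)))
  structure(
    list(coordinates = coords[, , drop = FALSE], stress = best$stress,
         converged = best$converged, n_restarts = n_restarts,
         seed = as.integer(seed), stress_trace = best$trace),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples in %d dimensions, stress-1 = %.4f (%s, %d restarts, seed %d)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "max iterations", x$n_restarts,
              x$seed))
  invisible(x)
}
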