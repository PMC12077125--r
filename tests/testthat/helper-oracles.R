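# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Brute-force weighted UniFrac: for every branch, enumerate its descendant
# tips by explicit recursion over the edge list.
brute_unifrac <- function(x, y, tree, normalized = FALSE) {
  n_tip <- length(tree$tip.label)
  descend_tips <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descend_tips))
  }
  xa <- setNames(rep(0, n_tip), tree$tip.label); xa[names(x)] <- x
  ya <- setNames(rep(0, n_tip), tree$tip.label); ya[names(y)] <- y
  raw <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[descend_tips(tree$edge[e, 2])]
    raw <- raw + tree$edge.length[e] * abs(sum(xa[tips]) - sum(ya[tips]))
  }
  if (!normalized) return(raw)
  root <- n_tip + 1L
  depth_of <- function(tip) {
    d <- 0; node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      d <- d + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    d
  }
  denom <- sum(vapply(seq_len(n_tip), function(i) {
    depth_of(i) * (xa[i] + ya[i])
  }, numeric(1)))
  if (denom == 0) 0 else raw / denom
}

# Hand-ranked Kruskal-Wallis H with tie correction.
kw_oracle <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- vapply(values, function(v) sum(values < v) + (sum(values == v) + 1) / 2,
              numeric(1))
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Hand-ranked Dunn z statistics vs a reference group.
dunn_oracle <- function(groups, reference) {
  values <- unlist(groups)
  n <- length(values)
  r <- vapply(values, function(v) sum(values < v) + (sum(values == v) + 1) / 2,
              numeric(1))
  lab <- rep(names(groups), lengths(groups))
  ties <- table(values)
  sigma2 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  sapply(setdiff(names(groups), reference), function(t) {
    (mean(r[lab == t]) - mean(r[lab == reference])) /
      sqrt(sigma2 * (1 / sum(lab == t) + 1 / sum(lab == reference)))
  })
}

# Random glycan profile with annotated linkages, for closure properties.
random_profile <- function(seed, n_mono = 4) {
  set.seed(seed)
  monos <- paste0("M", seq_len(n_mono))
  mono <- rgamma(n_mono, 2); mono <- setNames(mono / sum(mono), monos)
  raw <- numeric(0); parent <- character(0)
  for (m in monos) {
    k <- sample(0:3, 1)
    if (k > 0) {
      nm <- paste0(seq_len(k), "-", m)
      raw <- c(raw, setNames(runif(k, 1, 100), nm))
      parent <- c(parent, setNames(rep(m, k), nm))
    }
  }
  glycan_profile(sprintf("rp_%d", seed), mono, raw, parent)
}

# Tiny fermentation dataset with explicit structure, for validation tests.
tiny_dataset <- function(drop_control_for = NULL, extra_taxon = FALSE) {
  donors <- c("d1", "d2")
  treatments <- c("untreated", "fibA")
  rows <- expand.grid(donor_id = donors, treatment = treatments,
                      time_h = c(0, 24), stringsAsFactors = FALSE)
  rows$sample_id <- sprintf("%s.%s.%g", rows$donor_id, rows$treatment, rows$time_h)
  if (!is.null(drop_control_for)) {
    rows <- rows[!(rows$donor_id == drop_control_for &
                     rows$treatment == "untreated" & rows$time_h == 24), ]
  }
  taxa_names <- c("t1", "t2", if (extra_taxon) "t_missing")
  taxa <- matrix(1 / length(taxa_names), nrow(rows), length(taxa_names),
                 dimnames = list(rows$sample_id, taxa_names))
  metab <- matrix(100, nrow(rows), 2,
                  dimnames = list(rows$sample_id, c("butyrate", "propionate")))
  tree <- ape::read.tree(text = "(t1:1,t2:1);")
  fermentation_dataset(rows, taxa, metab, tree = tree)
}

# Independent exhaustive PERMANOVA oracle for tiny two-group designs:
# enumerates every distinct assignment of the labels via combn.
exhaustive_p_two_groups <- function(d, groups) {
  n <- length(groups)
  g1 <- unique(groups)[1]
  k <- sum(groups == g1)
  f_of <- function(assign) {
    lab <- rep(unique(groups)[2], n)
    lab[assign] <- g1
    a <- 2
    d2 <- d^2
    ss_t <- sum(d2[lower.tri(d2)]) / n
    ss_w <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d2[idx, idx]
      ss_w <- ss_w + sum(sub[lower.tri(sub)]) / length(idx)
    }
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(which(groups == g1))
  fs <- apply(combn(n, k), 2, f_of)
  mean(fs >= f_obs - 1e-12)
}
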