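make_coords <- function(entries) {
  m <- do.call(rbind, lapply(entries, `[[`, "xy"))
  rownames(m) <- vapply(entries, `[[`, character(1), "id")
  meta <- data.frame(
    sample_id = rownames(m),
    donor_id = vapply(entries, `[[`, character(1), "donor"),
    treatment = vapply(entries, `[[`, character(1), "treatment"),
    stringsAsFactors = FALSE)
  list(coords = m, meta = meta)
}

test_that("untreated controls map to the origin and shifts to differences", {
  cf <- make_coords(list(
    list(id = "u1", donor = "d1", treatment = "untreated", xy = c(2, 3)),
    list(id = "x1", donor = "d1", treatment = "fiberX", xy = c(4, 3)),
    list(id = "y1", donor = "d1", treatment = "fiberY", xy = c(2, 3))))
  disp <- normalize_shifts(cf$coords, cf$meta)
  expect_equal(unlist(disp[disp$treatment == "untreated", c("dim1", "dim2")]),
               c(dim1 = 0, dim2 = 0))
  expect_equal(unlist(disp[disp$treatment == "fiberX", c("dim1", "dim2")]),
               c(dim1 = 2, dim2 = 0))
  expect_equal(unlist(disp[disp$treatment == "fiberY", c("dim1", "dim2")]),
               c(dim1 = 0, dim2 = 0))
})

test_that("multi-donor displacement recomputes elementwise", {
  set.seed(2)
  entries <- list()
  truth <- list()
  for (d in c("d1", "d2", "d3")) {
    origin <- rnorm(2)
    entries[[length(entries) + 1]] <-
      list(id = paste0(d, ".u"), donor = d, treatment = "untreated", xy = origin)
    for (f in c("f1", "f2")) {
      xy <- rnorm(2)
      entries[[length(entries) + 1]] <-
        list(id = paste0(d, ".", f), donor = d, treatment = f, xy = xy)
      truth[[paste0(d, ".", f)]] <- xy - origin
    }
  }
  cf <- make_coords(entries)
  disp <- normalize_shifts(cf$coords, cf$meta)
  for (d in c("d1", "d2", "d3")) for (f in c("f1", "f2")) {
    row <- disp[disp$donor_id == d & disp$treatment == f, ]
    expect_equal(c(row$dim1, row$dim2), truth[[paste0(d, ".", f)]])
  }
})

test_that("missing or duplicate untreated controls are errors", {
  cf <- make_coords(list(
    list(id = "a", donor = "d1", treatment = "fiberX", xy = c(1, 1))))
  expect_error(normalize_shifts(cf$coords, cf$meta), "without an untreated")
  cf2 <- make_coords(list(
    list(id = "a", donor = "d1", treatment = "untreated", xy = c(0, 0)),
    list(id = "b", donor = "d1", treatment = "untreated", xy = c(1, 1))))
  expect_error(normalize_shifts(cf2$coords, cf2$meta), "uplicate")
})

test_that("cosine similarity covers the canonical directions", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(2, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero")
})

make_disp <- function(vectors, treatment = "f") {
  df <- data.frame(donor_id = names(vectors), treatment = treatment,
                   dim1 = vapply(vectors, `[`, numeric(1), 1),
                   dim2 = vapply(vectors, `[`, numeric(1), 2),
                   stringsAsFactors = FALSE)
  structure(df, origin_policy = "untreated_to_origin",
            class = c("displacement_set", "data.frame"))
}

test_that("mean pairwise cosine enumerates unordered donor pairs", {
  ds <- make_disp(list(d1 = c(1, 0), d2 = c(1, 0), d3 = c(0, 1)))
  res <- mean_pairwise_cosine(ds, "f")
  expect_equal(res$score, 1 / 3)
  expect_equal(res$n_pairs, 3L)

  same <- make_disp(list(d1 = c(2, 1), d2 = c(4, 2), d3 = c(6, 3)))
  expect_equal(mean_pairwise_cosine(same, "f")$score, 1)

  with_zero <- make_disp(list(d1 = c(1, 0), d2 = c(1, 0), d3 = c(0, 0)))
  res0 <- mean_pairwise_cosine(with_zero, "f")
  expect_equal(res0$n_excluded, 1L)
  expect_equal(res0$n_pairs, 1L)
  expect_equal(res0$score, 1)
})

test_that("scores are invariant to donor order and global rotation", {
  set.seed(5)
  vecs <- lapply(1:8, function(i) rnorm(2))
  names(vecs) <- paste0("d", 1:8)
  base <- mean_pairwise_cosine(make_disp(vecs), "f")$score
  shuffled <- mean_pairwise_cosine(make_disp(vecs[sample(8)]), "f")$score
  expect_equal(base, shuffled)
  theta <- 0.77
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rotated <- lapply(vecs, function(v) as.numeric(rot %*% v))
  expect_lt(abs(mean_pairwise_cosine(make_disp(rotated), "f")$score - base),
            1e-9)
})

test_that("donor translation before normalization changes nothing", {
  set.seed(6)
  entries <- list(list(id = "u", donor = "d1", treatment = "untreated",
                       xy = c(1, 2)),
                  list(id = "a", donor = "d1", treatment = "f1", xy = c(3, 5)))
  cf <- make_coords(entries)
  d0 <- normalize_shifts(cf$coords, cf$meta)
  shifted <- sweep(cf$coords, 2, c(10, -4), "+")
  d1 <- normalize_shifts(shifted, cf$meta)
  expect_equal(d0$dim1, d1$dim1)
  expect_equal(d0$dim2, d1$dim2)
})

test_that("k-means separates well-spaced trajectory groups", {
  vecs <- c(lapply(1:4, function(i) c(5, 5) + rnorm(2, 0, 0.1)),
            lapply(1:4, function(i) c(-5, 0) + rnorm(2, 0, 0.1)))
  df <- data.frame(donor_id = "d1",
                   treatment = paste0("t", 1:8),
                   dim1 = vapply(vecs, `[`, numeric(1), 1),
                   dim2 = vapply(vecs, `[`, numeric(1), 2),
                   stringsAsFactors = FALSE)
  ds <- structure(df, class = c("displacement_set", "data.frame"))
  km <- kmeans_trajectories(ds, k = 2, seed = 1)
  expect_equal(ari(km$cluster, rep(1:2, each = 4)), 1.0)

  km_all <- kmeans_trajectories(ds, k = 8, seed = 1)
  expect_equal(length(unique(km_all$cluster)), 8L)

  same <- ds; same$dim1 <- 1; same$dim2 <- 1
  km_same <- kmeans_trajectories(same, k = 2, seed = 1)
  expect_equal(km_same$inertia, 0)
  expect_error(kmeans_trajectories(ds, k = 0), "k must be")
})
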