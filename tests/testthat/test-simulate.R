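small_cfg <- function(...) {
  args <- list(n_donors = 6, n_taxa = 40,
               guild_sizes = c(butyrate_producer = 6,
                               propionate_producer = 4,
                               bifidobacteria = 3))
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

test_that("identical config and seed reproduce the dataset bit for bit", {
  a <- simulate_study(small_cfg(seed = 11))
  b <- simulate_study(small_cfg(seed = 11))
  expect_identical(a$dataset$metabolites, b$dataset$metabolites)
  expect_identical(a$dataset$taxa, b$dataset$taxa)
  expect_identical(lapply(a$fibers, `[[`, "mono_abundance"),
                   lapply(b$fibers, `[[`, "mono_abundance"))
  c_ <- simulate_study(small_cfg(seed = 12))
  expect_false(identical(a$dataset$metabolites, c_$dataset$metabolites))
})

test_that("generated communities and fiber compositions are closed", {
  st <- simulate_study(small_cfg(seed = 5))
  expect_lt(max(abs(rowSums(st$dataset$taxa) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(st$donors) - 1)), 1e-9)
  for (f in st$fibers) {
    expect_lt(abs(sum(f$mono_abundance) - 1), 1e-9)
    expect_lt(abs(sum(f$size_bins) - 1), 1e-9)
  }
})

test_that("infinite Dirichlet concentration collapses fibers onto templates", {
  cfg <- small_cfg(dirichlet_concentration = 1e7, seed = 3)
  fibers <- simulate_fibers(cfg)
  groups <- attr(fibers, "true_groups")
  for (i in seq_along(fibers)) {
    tmpl <- cfg$mono_templates[match(groups[i], group_letters(cfg$n_groups)), ]
    expect_lt(max(abs(fibers[[i]]$mono_abundance - tmpl)), 1e-3)
  }
})

test_that("bias-free linkage areas reproduce the linkage split", {
  lt <- list(Glc = list(split = c("T-Glc" = 0.3, "4-Glc" = 0.7),
                        bias = c("T-Glc" = 1, "4-Glc" = 1)))
  tmpl <- matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g2"), "Glc"))
  cfg <- simulation_config(n_groups = 2, n_fibers = 2, mono_templates = tmpl,
                           linkage_templates = lt,
                           size_templates = matrix(c(rep(0.2, 5), rep(0.2, 5)),
                                                   2, 5, byrow = TRUE),
                           seed = 1)
  fibers <- simulate_fibers(cfg)
  shares <- fibers[[1]]$linkage_raw / sum(fibers[[1]]$linkage_raw)
  expect_equal(unname(shares[c("T-Glc", "4-Glc")]), c(0.3, 0.7),
               tolerance = 1e-12)
})

test_that("planted groups are tighter within than between (seed 7)", {
  cfg <- simulation_config(n_groups = 2, n_fibers = 10,
                           dirichlet_concentration = 200, seed = 7)
  fibers <- simulate_fibers(cfg)
  m <- build_profile_matrix(fibers, "mono")
  d <- as.matrix(dist(m))
  g <- attr(fibers, "true_groups")
  within <- d[outer(g, g, "==") & upper.tri(d)]
  between <- d[outer(g, g, "!=") & upper.tri(d)]
  expect_lt(max(within), min(between))
})

test_that("donor presence sparsity follows the Bernoulli model", {
  cfg <- simulation_config(n_donors = 20, n_taxa = 100, presence_prob = 1,
                           seed = 3)
  expect_true(all(simulate_donors(cfg) > 0))

  cfg <- simulation_config(n_donors = 20, n_taxa = 100, presence_prob = 0.5,
                           seed = 3)
  donors <- simulate_donors(cfg)
  expect_gt(mean(attr(donors, "present_fraction")), 0.4)
  expect_lt(mean(attr(donors, "present_fraction")), 0.6)
})

test_that("a taxon with presence probability 0 is excluded and flagged", {
  pp <- c(0, rep(0.8, 39))
  cfg <- small_cfg(presence_prob = pp, seed = 2)
  donors <- suppressMessages(simulate_donors(cfg))
  expect_true(all(donors[, "taxon_001"] == 0))
  expect_true("taxon_001" %in% attr(donors, "never_present"))
})

test_that("untreated communities equal the donor baseline", {
  cfg <- small_cfg(seed = 9, noise_sd = 0)
  st <- simulate_study(cfg)
  ds <- st$dataset
  for (d in rownames(st$donors)) {
    id <- sprintf("%s.untreated.24h", d)
    expect_equal(unname(ds$taxa[id, ]), unname(st$donors[d, ]),
                 tolerance = 1e-12)
  }
})

test_that("donors lacking the butyrate guild produce only baseline butyrate", {
  yield <- rbind(
    butyrate_producer = c(acetate = 0, propionate = 0, butyrate = 5000, lactate = 0),
    propionate_producer = c(acetate = 0, propionate = 4000, butyrate = 0, lactate = 0),
    bifidobacteria = c(acetate = 3000, propionate = 0, butyrate = 0, lactate = 1000),
    other = c(acetate = 500, propionate = 0, butyrate = 0, lactate = 0))
  pp <- c(rep(0, 6), rep(0.9, 34))  # first 6 taxa are the butyrate guild
  cfg <- small_cfg(presence_prob = pp, yield = yield, noise_sd = 0, seed = 4)
  st <- simulate_study(cfg)
  buty <- st$dataset$metabolites[, "butyrate"]
  expect_equal(unname(buty), rep(cfg$baseline_metabolite[["butyrate"]],
                                 length(buty)), tolerance = 1e-9)
})

test_that("fully glycan-driven responses give parallel metabolite shifts", {
  cfg <- simulation_config(n_donors = 2, n_taxa = 40, lambda = 1,
                           noise_sd = 1e-6, presence_prob = 1,
                           guild_sizes = c(butyrate_producer = 6,
                                           propionate_producer = 4,
                                           bifidobacteria = 3),
                           n_fibers = 4, seed = 21)
  fibers <- simulate_fibers(cfg)
  donors <- simulate_donors(cfg)
  donors[2, ] <- donors[1, ]  # donors share both presence and abundances
  ds <- simulate_fermentation(fibers, donors, cfg)
  shift_cos <- function(ds, tr) {
    shifts <- sapply(rownames(donors), function(d) {
      ds$metabolites[sprintf("%s.%s.24h", d, tr), ] -
        ds$metabolites[sprintf("%s.untreated.24h", d), ]
    })
    cosine_similarity(shifts[, 1], shifts[, 2])
  }
  for (tr in names(fibers)) expect_gt(shift_cos(ds, tr), 0.99)

  # donors sharing presence but not abundances still respond near-parallel
  donors2 <- simulate_donors(cfg)
  ds2 <- simulate_fermentation(fibers, donors2, cfg)
  for (tr in names(fibers)) expect_gt(shift_cos(ds2, tr), 0.9)
})

test_that("functional redundancy buffers the loss of one guild member", {
  cfg <- small_cfg(noise_sd = 0, lambda = 1, presence_prob = 1, seed = 8,
                   n_donors = 2)
  fibers <- simulate_fibers(cfg)
  donors <- simulate_donors(cfg)
  buty_taxa <- paste0("taxon_00", 1:6)  # the butyrate guild
  drop <- function(donors, taxa) {
    donors[, taxa] <- 0
    sweep(donors, 1, rowSums(donors), "/")
  }
  buty24 <- function(dn) {
    ds <- simulate_fermentation(fibers, dn, cfg)
    ds$metabolites["donor_01.fiber_01.24h", "butyrate"]
  }
  full <- buty24(donors)
  one_out <- buty24(drop(donors, buty_taxa[1]))
  all_out <- buty24(drop(donors, buty_taxa))
  expect_lt(abs(full - one_out), abs(full - all_out))
  expect_gt(abs(full - all_out), 0)
})
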