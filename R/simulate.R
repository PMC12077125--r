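# Seeded generative model for a multi-donor fiber fermentation screen.
#
# The generator produces the three layers the analysis pipeline consumes:
# fiber glycomic profiles drawn around per-group composition templates,
# donor baseline communities with taxon presence sparsity, and
# post-fermentation communities + SCFA concentrations in which the balance
# between glycan-driven and donor-idiosyncratic response is a single knob
# (`lambda`).

default_monosaccharides <- function() {
  c("Glc", "Gal", "Man", "Xyl", "Ara", "Fru", "GalA")
}

# Composition templates for the five canonical fiber families:
# glucans, galacto/glucomannans, (arabino)xylans, arabinan/pectins, galactans.
default_mono_templates <- function() {
  m <- rbind(
    glucan    = c(Glc = 0.85, Gal = 0.03, Man = 0.03, Xyl = 0.04, Ara = 0.02, Fru = 0.02, GalA = 0.01),
    mannan    = c(Glc = 0.15, Gal = 0.20, Man = 0.58, Xyl = 0.02, Ara = 0.02, Fru = 0.01, GalA = 0.02),
    xylan     = c(Glc = 0.08, Gal = 0.03, Man = 0.02, Xyl = 0.57, Ara = 0.26, Fru = 0.01, GalA = 0.03),
    pectin    = c(Glc = 0.04, Gal = 0.10, Man = 0.02, Xyl = 0.04, Ara = 0.48, Fru = 0.02, GalA = 0.30),
    galactan  = c(Glc = 0.05, Gal = 0.72, Man = 0.03, Xyl = 0.03, Ara = 0.12, Fru = 0.02, GalA = 0.03)
  )
  sweep(m, 1, rowSums(m), "/")
}

# Per-monosaccharide linkage splits (fractions) and ionization bias factors.
# Terminal linkages ionize more efficiently, so their bias is > 1: raw peak
# areas deliberately break monosaccharide closure until normalized.
default_linkage_templates <- function() {
  list(
    Glc  = list(split = c("T-Glc" = 0.25, "3-Glc" = 0.30, "4-Glc" = 0.45),
                bias  = c("T-Glc" = 1.6, "3-Glc" = 1.0, "4-Glc" = 1.0)),
    Gal  = list(split = c("T-Gal" = 0.40, "4-Gal" = 0.60),
                bias  = c("T-Gal" = 1.6, "4-Gal" = 1.0)),
    Man  = list(split = c("T-Man" = 0.30, "4-Man" = 0.70),
                bias  = c("T-Man" = 1.6, "4-Man" = 1.0)),
    Xyl  = list(split = c("T-Xyl" = 0.20, "2-Xyl" = 0.50, "2,4-Xyl" = 0.30),
                bias  = c("T-Xyl" = 1.6, "2-Xyl" = 1.0, "2,4-Xyl" = 0.8)),
    Ara  = list(split = c("T-Ara" = 0.60, "5-Ara" = 0.40),
                bias  = c("T-Ara" = 1.6, "5-Ara" = 1.0)),
    Fru  = list(split = c("T-Fru" = 0.30, "2-Fru" = 0.70),
                bias  = c("T-Fru" = 1.6, "2-Fru" = 1.0)),
    GalA = list(split = c("4-GalA" = 1.0),
                bias  = c("4-GalA" = 1.0))
  )
}

default_size_bins <- function() {
  c("0.21-0.93", "0.93-7.76", "7.76-105", "105-851", ">1000")
}

# Most fiber pools are dominated by sub-100 kDa material; the galactan-like
# group carries a large >1000 kDa tail (as arabinogalactan-type fibers do).
default_size_templates <- function() {
  rbind(
    glucan   = c(0.25, 0.35, 0.25, 0.10, 0.05),
    mannan   = c(0.10, 0.30, 0.35, 0.15, 0.10),
    xylan    = c(0.15, 0.35, 0.30, 0.15, 0.05),
    pectin   = c(0.05, 0.20, 0.35, 0.25, 0.15),
    galactan = c(0.03, 0.07, 0.15, 0.20, 0.55)
  )
}

# Guild preference directions over monosaccharides: which glycomic features
# each functional guild responds to. Butyrate producers respond to glucans
# and xylans, propionate producers to arabinan/pectin material,
# bifidobacteria to galactose/fructose-rich substrates.
default_guild_preference <- function() {
  rbind(
    butyrate_producer   = c(Glc = 0.50, Gal = 0.00, Man = 0.05, Xyl = 0.30, Ara = 0.00, Fru = 0.15, GalA = 0.00),
    propionate_producer = c(Glc = 0.00, Gal = 0.05, Man = 0.15, Xyl = 0.00, Ara = 0.40, Fru = 0.00, GalA = 0.40),
    bifidobacteria      = c(Glc = 0.05, Gal = 0.45, Man = 0.00, Xyl = 0.10, Ara = 0.15, Fru = 0.25, GalA = 0.00),
    other               = c(Glc = 0.00, Gal = 0.00, Man = 0.00, Xyl = 0.00, Ara = 0.00, Fru = 0.00, GalA = 0.00)
  )
}

# Fermentation end-product yields (ug/mL per unit guild relative abundance).
default_yield <- function() {
  rbind(
    butyrate_producer   = c(acetate = 1500, propionate = 200, butyrate = 6000, lactate = 0),
    propionate_producer = c(acetate = 1000, propionate = 4500, butyrate = 0, lactate = 0),
    bifidobacteria      = c(acetate = 3000, propionate = 0, butyrate = 0, lactate = 1800),
    other               = c(acetate = 800, propionate = 100, butyrate = 50, lactate = 100)
  )
}

#' Configuration of the synthetic fermentation study
#'
#' Assembles (and validates) every parameter of the generative model. The
#' defaults mimic the scale of a desk-size multi-donor screen: 20 donors,
#' 100 taxa, 12 fibers drawn from 5 phyloglycomic groups plus an untreated
#' control, sampled at 0/6/10/24 h.
#'
#' @param n_groups number of phyloglycomic groups (rows of `mono_templates`
#'   used); at least 2.
#' @param n_fibers total fibers, assigned to groups round-robin.
#' @param mono_templates groups x monosaccharides matrix of composition
#'   templates (rows sum to 1).
#' @param dirichlet_concentration within-group tightness of fiber
#'   compositions (larger = tighter around the template).
#' @param linkage_templates per-monosaccharide list of `split` (fractions)
#'   and `bias` (ionization factors >= 0), see
#'   `glycoferm:::default_linkage_templates()`.
#' @param size_templates groups x size-bin matrix of size-distribution
#'   templates.
#' @param n_donors,n_taxa cohort and community sizes.
#' @param presence_prob per-taxon Bernoulli presence probability (recycled
#'   to `n_taxa`); the default gives a core of prevalent taxa plus a
#'   variable tail so that donors share only part of their communities.
#' @param guild_sizes named integer vector: taxa per functional guild
#'   (butyrate_producer, propionate_producer, bifidobacteria); the rest are
#'   "other".
#' @param guild_preference guilds x monosaccharides response-direction
#'   matrix.
#' @param affinity_scale mean per-taxon response strength multiplying the
#'   guild preference (dimensionless exponent units).
#' @param yield guilds x metabolites yield matrix (ug/mL per unit
#'   responder relative abundance).
#' @param baseline_metabolite named background concentrations (ug/mL).
#' @param lambda determinism weight in \[0, 1\]: 1 = response fully
#'   glycan-driven, 0 = fully donor-idiosyncratic.
#' @param epsilon_sd scale of the donor-idiosyncratic response exponent.
#' @param noise_sd measurement noise on metabolite concentrations (ug/mL).
#' @param time_grid sampling times in hours.
#' @param seed integer seed governing every draw.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_groups = 5,
                              n_fibers = 12,
                              mono_templates = default_mono_templates(),
                              dirichlet_concentration = 200,
                              linkage_templates = default_linkage_templates(),
                              size_templates = default_size_templates(),
                              n_donors = 20,
                              n_taxa = 100,
                              presence_prob = NULL,
                              guild_sizes = c(butyrate_producer = 15,
                                              propionate_producer = 10,
                                              bifidobacteria = 8),
                              guild_preference = default_guild_preference(),
                              affinity_scale = 6,
                              yield = default_yield(),
                              baseline_metabolite = c(acetate = 500, propionate = 150,
                                                      butyrate = 100, lactate = 50),
                              lambda = 0.9,
                              epsilon_sd = 2,
                              noise_sd = 25,
                              time_grid = c(0, 6, 10, 24),
                              seed = 1L) {
  if (n_groups > nrow(mono_templates)) {
    stop("n_groups exceeds the number of template rows supplied")
  }
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (dirichlet_concentration <= 0) stop("dirichlet_concentration must be > 0")
  if (any(c(epsilon_sd, noise_sd, affinity_scale) < 0)) {
    stop("scale parameters must be >= 0")
  }
  for (i in seq_len(nrow(mono_templates))) {
    assert_closed(mono_templates[i, ], what = sprintf("mono template %d", i))
  }
  if (is.null(presence_prob)) {
    n_core <- round(0.3 * n_taxa)
    presence_prob <- c(rep(0.95, n_core), rep(0.35, n_taxa - n_core))
  }
  presence_prob <- rep_len(presence_prob, n_taxa)
  if (any(presence_prob < 0 | presence_prob > 1)) {
    stop("presence_prob must lie in [0, 1]")
  }
  if (sum(guild_sizes) > n_taxa) stop("guild_sizes exceed n_taxa")
  structure(
    list(n_groups = n_groups, n_fibers = n_fibers,
         mono_templates = mono_templates[seq_len(n_groups), , drop = FALSE],
         dirichlet_concentration = dirichlet_concentration,
         linkage_templates = linkage_templates,
         size_templates = size_templates[seq_len(n_groups), , drop = FALSE],
         n_donors = n_donors, n_taxa = n_taxa,
         presence_prob = presence_prob,
         guild_sizes = guild_sizes, guild_preference = guild_preference,
         affinity_scale = affinity_scale, yield = yield,
         baseline_metabolite = baseline_metabolite,
         lambda = lambda, epsilon_sd = epsilon_sd, noise_sd = noise_sd,
         time_grid = time_grid, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) {
    # all-zero draw can only happen when alpha is tiny; fall back to uniform
    # over the supported components
    x <- as.numeric(alpha > 0)
  }
  x / sum(x)
}

#' Simulate fiber glycomic profiles
#'
#' Draws `n_fibers` fibers assigned round-robin to phyloglycomic groups.
#' Monosaccharide compositions follow a Dirichlet around the group template
#' with concentration `dirichlet_concentration`; raw linkage peak areas are
#' monosaccharide share x linkage split x ionization bias (so they violate
#' monosaccharide closure until [normalize_linkages()] is applied); size-bin
#' distributions follow a Dirichlet around the group's size template.
#'
#' @param cfg a [simulation_config()].
#' @return list of [glycan_profile()] objects with `group_label` set to the
#'   true group; the named character vector of true labels is attached as
#'   attribute `"true_groups"`.
#' @export
simulate_fibers <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_groups < 2) stop("at least 2 phyloglycomic groups are required")
  set.seed(derive_seed(cfg$seed, 101L))
  groups <- group_letters(cfg$n_groups)
  assign <- rep_len(groups, cfg$n_fibers)
  monos <- colnames(cfg$mono_templates)
  fibers <- vector("list", cfg$n_fibers)
  for (i in seq_len(cfg$n_fibers)) {
    g <- match(assign[i], groups)
    mono <- rdirichlet1(cfg$dirichlet_concentration * cfg$mono_templates[g, ])
    names(mono) <- monos
    raw <- numeric(0)
    parent <- character(0)
    for (m in monos) {
      lt <- cfg$linkage_templates[[m]]
      if (is.null(lt) || mono[[m]] <= 0) next
      areas <- 100 * mono[[m]] * lt$split * lt$bias[names(lt$split)]
      raw <- c(raw, areas)
      parent <- c(parent, stats::setNames(rep(m, length(areas)), names(areas)))
    }
    size <- rdirichlet1(100 * cfg$size_templates[g, ])
    names(size) <- default_size_bins()
    fibers[[i]] <- glycan_profile(
      fiber_id = sprintf("fiber_%02d", i),
      mono_abundance = mono / sum(mono),
      linkage_raw = raw, linkage_parent = parent,
      size_bins = size / sum(size),
      group_label = assign[i]
    )
  }
  names(fibers) <- vapply(fibers, `[[`, character(1), "fiber_id")
  attr(fibers, "true_groups") <- stats::setNames(assign, names(fibers))
  fibers
}

#' Simulate donor baseline communities
#'
#' Each donor's community is a Bernoulli presence mask over taxa (driving
#' donor-specific sparsity) with log-normal abundances among present taxa,
#' closed to sum 1. Donors that would end up with no taxa at all are
#' resampled (bounded retries, with a warning).
#'
#' @param cfg a [simulation_config()].
#' @return `n_donors x n_taxa` matrix of relative abundances with donor and
#'   taxon names; per-donor fraction of taxa present and fraction of
#'   donor-unique taxa are attached as attributes `"present_fraction"` and
#'   `"unique_fraction"`; taxa absent from every donor are listed in
#'   attribute `"never_present"`.
#' @export
simulate_donors <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, 202L))
  taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  # per-taxon typical log-abundance, shared across donors so that communities
  # overlap where presence overlaps
  base_log <- stats::rnorm(cfg$n_taxa, mean = 0, sd = 1)
  donors <- matrix(0, cfg$n_donors, cfg$n_taxa,
                   dimnames = list(sprintf("donor_%02d", seq_len(cfg$n_donors)), taxa))
  for (d in seq_len(cfg$n_donors)) {
    for (try in seq_len(100L)) {
      mask <- stats::rbinom(cfg$n_taxa, 1L, cfg$presence_prob) == 1L
      if (any(mask)) break
      if (try == 100L) stop("could not draw a non-empty donor community")
      warning(sprintf("donor %d drew an all-absent community; resampling", d))
    }
    ab <- exp(base_log + stats::rnorm(cfg$n_taxa, 0, 0.6)) * mask
    donors[d, ] <- ab / sum(ab)
  }
  present <- donors > 0
  prevalence <- colSums(present)
  attr(donors, "present_fraction") <- rowMeans(present)
  attr(donors, "unique_fraction") <-
    apply(present, 1, function(p) if (any(p)) sum(p & prevalence == 1) / sum(p) else 0)
  never <- colnames(donors)[prevalence == 0]
  if (length(never)) {
    message(length(never), " taxa absent from every donor: ",
            paste(never, collapse = ", "))
  }
  attr(donors, "never_present") <- never
  donors
}

#' Simulate a random phylogeny over the taxa
#'
#' Coalescent-style random tree (via [ape::rcoal()]) used as the phylogeny
#' input for weighted UniFrac analyses of simulated communities.
#'
#' @param cfg a [simulation_config()].
#' @return a rooted `phylo` object with `n_taxa` tips named `taxon_###`.
#' @export
simulate_taxa_tree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, 303L))
  ape::rcoal(cfg$n_taxa, tip.label = sprintf("taxon_%03d", seq_len(cfg$n_taxa)))
}

guild_assignment <- function(cfg) {
  guilds <- rep("other", cfg$n_taxa)
  i <- 1L
  for (g in names(cfg$guild_sizes)) {
    n <- cfg$guild_sizes[[g]]
    guilds[seq.int(i, length.out = n)] <- g
    i <- i + n
  }
  stats::setNames(guilds, sprintf("taxon_%03d", seq_len(cfg$n_taxa)))
}

genus_for_guild <- function(guild, k) {
  pool <- switch(guild,
    butyrate_producer = c("Clostridium", "Roseburia", "Eubacterium", "Anaerobutyricum"),
    propionate_producer = c("Bacteroides", "Phascolarctobacterium", "Prevotella"),
    bifidobacteria = "Bifidobacterium",
    c("Blautia", "Dorea", "Faecalibacterium", "Ruminococcus", "Collinsella")
  )
  pool[((k - 1L) %% length(pool)) + 1L]
}

# Monotone fraction of the 24 h endpoint effect realized by each time point.
metabolite_ramp <- function(time_grid, metabolite) {
  t_norm <- time_grid / max(time_grid)
  if (metabolite == "lactate") {
    # produced early, then consumed: peaks mid-fermentation
    ramp <- pmin(2.4 * t_norm, 1.0) * exp(-1.1 * pmax(t_norm - 0.42, 0))
    ramp[time_grid == 0] <- 0
    ramp
  } else {
    1 - exp(-3 * t_norm)
  }
}

#' Simulate fermentation outcomes for every donor x treatment
#'
#' The generative bridge between fiber structure and community/metabolite
#' response. For each donor and fiber, taxa respond through an exponential
#' tilt of the donor's baseline composition:
#' \deqn{x'_t \propto x_t \exp(r(t) \eta_t), \quad
#'       \eta_t = \lambda (a_t \cdot f) + (1 - \lambda)\epsilon_{d,t}}
#' where `f` is the fiber's monosaccharide composition, `a_t` the taxon's
#' guild-derived affinity row, and `eps` a donor-idiosyncratic exponent
#' drawn once per (donor, taxon) and reused across treatments. Untreated
#' controls have `eta = 0`, so their expected composition is the baseline.
#' Absent taxa never respond. Metabolites accumulate as baseline +
#' yield^T x (guild-aggregated endpoint abundance) scaled by a per-metabolite
#' time ramp (lactate peaks mid-fermentation), plus Gaussian measurement
#' noise truncated at 0. OD600 rises and pH falls monotonically with total
#' metabolite production.
#'
#' @param fibers list of [glycan_profile()] from [simulate_fibers()].
#' @param donors donor x taxa baseline matrix from [simulate_donors()].
#' @param cfg the same [simulation_config()] used upstream.
#' @return a [fermentation_dataset()] carrying taxa and metabolite matrices
#'   for every donor x treatment x time point, a taxonomy table with guild
#'   and genus labels, and the coalescent taxa phylogeny. Ground truth is
#'   attached as attributes `"lambda"`, `"guild_map"` and `"affinity"`.
#' @export
simulate_fermentation <- function(fibers, donors, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, 404L))
  taxa <- colnames(donors)
  n_taxa <- length(taxa)
  monos <- colnames(cfg$mono_templates)
  guilds <- guild_assignment(cfg)[taxa]

  # per-taxon affinity rows: guild preference direction scaled by a
  # log-normal per-taxon strength (functional redundancy within guilds)
  strength <- exp(stats::rnorm(n_taxa, log(cfg$affinity_scale), 0.25))
  affinity <- cfg$guild_preference[guilds, , drop = FALSE] * strength
  rownames(affinity) <- taxa

  # donor-idiosyncratic response exponents, one draw per (donor, taxon)
  epsilon <- matrix(stats::rnorm(nrow(donors) * n_taxa, 0, cfg$epsilon_sd),
                    nrow(donors), n_taxa, dimnames = dimnames(donors))

  treatments <- c(names(fibers), "untreated")
  metabolites <- colnames(cfg$yield)
  ramps <- vapply(metabolites, function(m) metabolite_ramp(cfg$time_grid, m),
                  numeric(length(cfg$time_grid)))
  community_ramp <- 1 - exp(-3 * cfg$time_grid / max(cfg$time_grid))

  n_rows <- nrow(donors) * length(treatments) * length(cfg$time_grid)
  samples <- vector("list", n_rows)
  taxa_mat <- matrix(NA_real_, n_rows, n_taxa, dimnames = list(NULL, taxa))
  metab_mat <- matrix(NA_real_, n_rows, length(metabolites),
                      dimnames = list(NULL, metabolites))
  row <- 0L
  for (d in rownames(donors)) {
    x0 <- donors[d, ]
    for (tr in treatments) {
      if (tr == "untreated") {
        eta <- rep(0, n_taxa)
      } else {
        f <- fibers[[tr]]$mono_abundance[monos]
        if (anyNA(f) || ncol(affinity) != length(f)) {
          stop("affinity matrix and fiber glycomic feature vector do not match")
        }
        eta <- cfg$lambda * as.numeric(affinity %*% f) +
          (1 - cfg$lambda) * epsilon[d, ]
      }
      x24 <- x0 * exp(eta)
      x24 <- x24 / sum(x24)
      guild_ab24 <- tapply(x24, guilds, sum)
      effect <- as.numeric(t(cfg$yield[names(guild_ab24), , drop = FALSE]) %*%
                             guild_ab24)
      names(effect) <- metabolites
      for (ti in seq_along(cfg$time_grid)) {
        t_h <- cfg$time_grid[ti]
        row <- row + 1L
        xt <- x0 * exp(community_ramp[ti] * eta)
        xt <- xt / sum(xt)
        conc <- cfg$baseline_metabolite[metabolites] + ramps[ti, ] * effect +
          stats::rnorm(length(metabolites), 0, cfg$noise_sd)
        conc <- pmax(conc, 0)
        total_prod <- sum(ramps[ti, ] * effect)
        od <- 0.05 + 0.9 * (1 - exp(-total_prod / 3000)) + stats::rnorm(1, 0, 0.01)
        ph <- 6.8 - 1.0 * (1 - exp(-total_prod / 4000)) + stats::rnorm(1, 0, 0.02)
        taxa_mat[row, ] <- xt
        metab_mat[row, ] <- conc
        samples[[row]] <- data.frame(
          sample_id = sprintf("%s.%s.%gh", d, tr, t_h),
          donor_id = d, treatment = tr, time_h = t_h,
          od600 = max(od, 0), ph = min(max(ph, 5.6), 7.0),
          stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, samples)
  rownames(taxa_mat) <- samples$sample_id
  rownames(metab_mat) <- samples$sample_id
  taxonomy <- data.frame(
    taxon_id = taxa,
    genus = vapply(seq_along(taxa),
                   function(i) genus_for_guild(guilds[i], i), character(1)),
    guild = unname(guilds),
    stringsAsFactors = FALSE)
  ds <- fermentation_dataset(samples = samples, taxa = taxa_mat,
                             metabolites = metab_mat, taxonomy = taxonomy,
                             tree = simulate_taxa_tree(cfg))
  attr(ds, "lambda") <- cfg$lambda
  attr(ds, "guild_map") <- guilds
  attr(ds, "affinity") <- affinity
  ds
}

#' One-call simulation of the full study
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `fibers`, `donors`, `dataset`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  fibers <- simulate_fibers(cfg)
  donors <- simulate_donors(cfg)
  list(fibers = fibers, donors = donors,
       dataset = simulate_fermentation(fibers, donors, cfg))
}
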