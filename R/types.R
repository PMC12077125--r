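#' Glycan profile of a single fiber
#'
#' Bundles the three glycomic layers measured for one fiber preparation: the
#' monosaccharide composition (fractions summing to 1), raw glycosidic-linkage
#' peak areas annotated with their parent monosaccharide, and a size-bin
#' distribution from size-exclusion chromatography. Linkage peak areas are
#' arbitrary ionization-biased units; [normalize_linkages()] rescales them to
#' the monosaccharide composition and fills `linkage_norm`.
#'
#' @param fiber_id single string identifying the fiber.
#' @param mono_abundance named numeric vector of monosaccharide fractions;
#'   must be non-negative and sum to 1 within `1e-9`.
#' @param linkage_raw named numeric vector of raw linkage peak areas
#'   (arbitrary units, >= 0). May be empty.
#' @param linkage_parent named character vector mapping each linkage name in
#'   `linkage_raw` to its parent monosaccharide; every parent must appear in
#'   `mono_abundance`. By default parents are inferred from linkage names of
#'   the form `"4-Glc"` or `"T-Gal"` (suffix after the last `"-"`).
#' @param size_bins optional named numeric vector of size-bin fractions (bin
#'   labels are kDa intervals such as `"0.21-0.93"` or `">1000"`); must sum
#'   to 1 within `1e-9` when present.
#' @param group_label optional phyloglycomic group id.
#'
#' @return An object of class `glycan_profile`: a list with fields
#'   `fiber_id`, `mono_abundance`, `linkage_raw`, `linkage_parent`,
#'   `linkage_norm` (NULL until [normalize_linkages()] is called),
#'   `size_bins`, `group_label`.
#' @seealso [normalize_linkages()], [build_profile_matrix()]
#' @export
glycan_profile <- function(fiber_id, mono_abundance, linkage_raw = numeric(0),
                           linkage_parent = NULL, size_bins = NULL,
                           group_label = NULL) {
  stopifnot(is.character(fiber_id), length(fiber_id) == 1L)
  if (is.null(names(mono_abundance)) || anyDuplicated(names(mono_abundance))) {
    stop("mono_abundance must have unique names")
  }
  assert_closed(mono_abundance, what = sprintf("mono_abundance of '%s'", fiber_id))
  if (length(linkage_raw)) {
    if (is.null(names(linkage_raw))) stop("linkage_raw must be named")
    if (any(linkage_raw < 0)) stop("linkage_raw peak areas must be non-negative")
    if (is.null(linkage_parent)) {
      linkage_parent <- infer_linkage_parent(names(linkage_raw))
    }
    linkage_parent <- linkage_parent[names(linkage_raw)]
    missing_parent <- setdiff(unique(linkage_parent), names(mono_abundance))
    if (length(missing_parent)) {
      stop("linkage parent monosaccharide(s) absent from mono_abundance: ",
           paste(missing_parent, collapse = ", "))
    }
  } else {
    linkage_parent <- character(0)
  }
  if (!is.null(size_bins)) {
    if (is.null(names(size_bins))) stop("size_bins must be named")
    assert_closed(size_bins, what = sprintf("size_bins of '%s'", fiber_id))
  }
  structure(
    list(fiber_id = fiber_id,
         mono_abundance = mono_abundance,
         linkage_raw = linkage_raw,
         linkage_parent = linkage_parent,
         linkage_norm = NULL,
         size_bins = size_bins,
         group_label = group_label),
    class = "glycan_profile"
  )
}

# "4-Glc" -> "Glc", "2,4-Xyl" -> "Xyl", "T-Gal" -> "Gal".
infer_linkage_parent <- function(linkage_names) {
  parent <- sub("^.*-", "", linkage_names)
  names(parent) <- linkage_names
  parent
}

#' @export
print.glycan_profile <- function(x, ...) {
  cat(sprintf("<glycan_profile> %s\n", x$fiber_id))
  cat("  monosaccharides:",
      paste(sprintf("%s=%.3f", names(x$mono_abundance), x$mono_abundance),
            collapse = " "), "\n")
  cat(sprintf("  linkages: %d raw%s\n", length(x$linkage_raw),
              if (is.null(x$linkage_norm)) " (not normalized)" else ", normalized"))
  if (!is.null(x$size_bins)) {
    cat("  size bins:", paste(names(x$size_bins), collapse = ", "), "\n")
  }
  if (!is.null(x$group_label)) cat("  group:", x$group_label, "\n")
  invisible(x)
}

#' Multi-donor fermentation dataset
#'
#' Container for a batch-fermentation screen: per-sample metadata (donor,
#' treatment, time point), a taxa relative-abundance matrix, a metabolite
#' concentration matrix, optional plate-reader covariates (OD600, pH), a
#' genus-level taxonomy table, and an optional phylogeny over the taxa.
#'
#' @param samples data.frame with columns `sample_id`, `donor_id`,
#'   `treatment` (a fiber id or `"untreated"`), `time_h`, and optionally
#'   `od600` and `ph`. `sample_id` must be unique.
#' @param taxa numeric matrix, samples x taxa, rownames = `sample_id`;
#'   rows are relative abundances summing to 1 (rows of all-NA are allowed
#'   for time points without community data).
#' @param metabolites numeric matrix, samples x metabolites (concentrations
#'   in ug/mL), rownames = `sample_id`.
#' @param taxonomy optional data.frame with columns `taxon_id`, `genus`
#'   (and any further lineage columns).
#' @param tree optional `phylo` object whose tip labels cover the taxa
#'   columns.
#'
#' @return An object of class `fermentation_dataset`.
#' @seealso [validate_dataset()], [simulate_fermentation()]
#' @export
fermentation_dataset <- function(samples, taxa = NULL, metabolites = NULL,
                                 taxonomy = NULL, tree = NULL) {
  req <- c("sample_id", "donor_id", "treatment", "time_h")
  if (!all(req %in% names(samples))) {
    stop("samples must contain columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in samples")
  for (nm in c("taxa", "metabolites")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (is.null(rownames(m)) || !all(rownames(m) %in% samples$sample_id)) {
        stop(nm, " matrix rownames must be sample ids present in samples")
      }
    }
  }
  structure(
    list(samples = samples, taxa = taxa, metabolites = metabolites,
         taxonomy = taxonomy, tree = tree),
    class = "fermentation_dataset"
  )
}

#' @export
print.fermentation_dataset <- function(x, ...) {
  cat(sprintf("<fermentation_dataset> %d samples, %d donors, %d treatments\n",
              nrow(x$samples), length(unique(x$samples$donor_id)),
              length(unique(x$samples$treatment))))
  cat("  time points (h):", paste(sort(unique(x$samples$time_h)), collapse = ", "), "\n")
  if (!is.null(x$taxa)) cat("  taxa matrix:", ncol(x$taxa), "taxa\n")
  if (!is.null(x$metabolites)) {
    cat("  metabolites:", paste(colnames(x$metabolites), collapse = ", "), "\n")
  }
  cat("  phylogeny:", if (is.null(x$tree)) "none" else
    sprintf("%d tips", length(x$tree$tip.label)), "\n")
  invisible(x)
}

#' Validate a fermentation dataset
#'
#' Checks the structural assumptions downstream analyses rely on: every donor
#' has exactly one untreated control at each time point at which it has any
#' record, taxa abundance rows are non-negative and closed to 1, metabolite
#' concentrations are non-negative, and every taxon with community data is a
#' tip of the phylogeny when one is attached.
#'
#' @param ds a [fermentation_dataset()].
#' @param strict if `TRUE`, stop at the first violation instead of returning
#'   the report.
#' @param tol closure tolerance for abundance rows.
#' @return A data.frame report with columns `check`, `where`, `message`;
#'   zero rows when the dataset is clean.
#' @export
validate_dataset <- function(ds, strict = FALSE, tol = 1e-9) {
  stopifnot(inherits(ds, "fermentation_dataset"))
  report <- list()
  note <- function(check, where, message) {
    row <- data.frame(check = check, where = where, message = message,
                      stringsAsFactors = FALSE)
    if (strict) stop(sprintf("[%s] %s: %s", check, where, message))
    report[[length(report) + 1L]] <<- row
  }

  s <- ds$samples
  for (donor in unique(s$donor_id)) {
    times <- unique(s$time_h[s$donor_id == donor])
    for (t in times) {
      n_ctrl <- sum(s$donor_id == donor & s$time_h == t & s$treatment == "untreated")
      if (n_ctrl == 0L) {
        note("missing_control", donor,
             sprintf("no untreated sample at %g h", t))
      } else if (n_ctrl > 1L) {
        note("duplicate_control", donor,
             sprintf("%d untreated samples at %g h", n_ctrl, t))
      }
    }
  }

  if (!is.null(ds$taxa)) {
    for (i in seq_len(nrow(ds$taxa))) {
      row <- ds$taxa[i, ]
      if (all(is.na(row))) next
      if (any(row < 0, na.rm = TRUE)) {
        note("negative_abundance", rownames(ds$taxa)[i], "negative taxa abundance")
      } else if (abs(sum(row) - 1) > tol) {
        note("closure", rownames(ds$taxa)[i],
             sprintf("abundances sum to %.9f, not 1", sum(row)))
      }
    }
    if (!is.null(ds$tree)) {
      missing <- setdiff(colnames(ds$taxa), ds$tree$tip.label)
      if (length(missing)) {
        note("taxon_not_in_tree", "tree",
             paste("taxa absent from tree:", paste(missing, collapse = ", ")))
      }
    }
  }

  if (!is.null(ds$metabolites) && any(ds$metabolites < 0, na.rm = TRUE)) {
    bad <- rownames(ds$metabolites)[apply(ds$metabolites < 0, 1, any)]
    for (b in bad) note("negative_concentration", b, "negative metabolite concentration")
  }

  if (length(report)) do.call(rbind, report) else
    data.frame(check = character(0), where = character(0), message = character(0))
}
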