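#' Treatment design
#'
#' Describes one arm of a factorial coculture experiment: which species
#' are inoculated, whether lytic phage is added, the focal-strain
#' genotype, and the inoculation/transfer schedule. The inoculum is split
#' with the focal species at `focal_fraction` of the total (when present
#' with competitors) and the remainder shared equally; monocultures are
#' density-matched to the same total.
#'
#' @param species_subset non-empty character vector of inoculated species.
#' @param phage logical: is lytic phage added?
#' @param genotype focal-strain label (e.g. `"WT"` or `"CRISPR-KO"`).
#' @param focal the phage-targeted species label (may be absent from the
#'   subset).
#' @param total_inoculum total inoculum, cfu.
#' @param focal_fraction focal share of the inoculum in polycultures.
#' @param dilution_factor per-transfer dilution in (0, 1].
#' @param transfer_interval days between transfers.
#' @param duration experiment length, days (a multiple of
#'   `transfer_interval`).
#' @param replicates replicate count.
#' @param days sampling days.
#' @return An object of class `treatment_design`, including the computed
#'   per-species `inoculum` vector and a `treatment_id` label.
#' @export
treatment_design <- function(species_subset, phage = FALSE, genotype = "WT",
                             focal = species_subset[1],
                             total_inoculum = 1e6, focal_fraction = 0.25,
                             dilution_factor = 0.01, transfer_interval = 1,
                             duration = 10, replicates = 6,
                             days = c(0, 1, 3, 7, 10)) {
  if (!length(species_subset)) stop("species_subset must be non-empty")
  if (anyDuplicated(species_subset)) stop("duplicated species in subset")
  if (dilution_factor <= 0 || dilution_factor > 1)
    stop("dilution_factor must lie in (0, 1]")
  if (duration %% transfer_interval != 0)
    stop("duration must be an integer multiple of transfer_interval")
  n <- length(species_subset)
  if (focal %in% species_subset && n > 1) {
    if (focal_fraction <= 0 || focal_fraction >= 1)
      stop("focal_fraction must lie in (0, 1) when the focal species has competitors")
    inoc <- rep(total_inoculum * (1 - focal_fraction) / (n - 1), n)
    inoc[species_subset == focal] <- total_inoculum * focal_fraction
  } else {
    inoc <- rep(total_inoculum / n, n)
  }
  names(inoc) <- species_subset
  id <- paste0(paste(species_subset, collapse = "+"),
               if (phage) "_phage" else "_nophage", "_", genotype)
  structure(list(species_subset = species_subset, phage = phage,
                 genotype = genotype, focal = focal,
                 total_inoculum = total_inoculum,
                 focal_fraction = focal_fraction, inoculum = inoc,
                 dilution_factor = dilution_factor,
                 transfer_interval = transfer_interval,
                 duration = duration, replicates = replicates,
                 days = days, treatment_id = id),
            class = "treatment_design")
}

#' @export
print.treatment_design <- function(x, ...) {
  cat(sprintf("treatment %s: %d replicates, days %s\n", x$treatment_id,
              x$replicates, paste(x$days, collapse = ",")))
  invisible(x)
}

#' Enumerate a fully factorial coculture design
#'
#' Builds the treatment list of a factorial experiment over all non-empty
#' subsets of the species pool, crossed with phage presence per
#' `phage_rule` and with focal genotypes (genotypes only apply to subsets
#' containing the focal species; other subsets carry genotype `"none"`).
#' Defaults mirror a 4-species, 6-replicate, 10-day serial-transfer
#' design sampled at days 0, 1, 3, 7 and 10.
#'
#' @param species character vector of species labels.
#' @param focal phage-targeted species.
#' @param phage_rule `"all"` (phage arm for every subset), `"focal_only"`
#'   (phage arms only where the focal species is present) or `"none"`.
#' @param genotypes focal genotype labels.
#' @param replicates,days,... passed to [treatment_design].
#' @return List of [treatment_design] objects.
#' @examples
#' d <- generate_design(c("PA", "SA", "AB", "BC"), phage_rule = "none")
#' length(d)  # 15 subsets
#' @export
generate_design <- function(species, focal = species[1],
                            phage_rule = c("all", "focal_only", "none"),
                            genotypes = "WT", replicates = 6,
                            days = c(0, 1, 3, 7, 10), ...) {
  phage_rule <- match.arg(phage_rule)
  if (!length(species)) stop("species must be non-empty")
  subsets <- unlist(lapply(seq_along(species), function(k)
    combn(species, k, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (ss in subsets) {
    phage_levels <- switch(phage_rule,
      none = FALSE,
      all = c(FALSE, TRUE),
      focal_only = if (focal %in% ss) c(FALSE, TRUE) else FALSE)
    geno_levels <- if (focal %in% ss) genotypes else "none"
    for (ph in phage_levels) for (g in geno_levels) {
      out[[length(out) + 1]] <- treatment_design(
        species_subset = ss, phage = ph, genotype = g, focal = focal,
        replicates = replicates, days = days, ...)
    }
  }
  out
}

#' @rdname generate_design
#' @param design a list of [treatment_design] objects.
#' @return `design_table` returns a summary data.frame, one row per
#'   treatment.
#' @export
design_table <- function(design) {
  do.call(rbind, lapply(design, function(d) data.frame(
    treatment_id = d$treatment_id,
    species = paste(d$species_subset, collapse = "+"),
    n_species = length(d$species_subset),
    phage = as.integer(d$phage), genotype = d$genotype,
    replicates = d$replicates, stringsAsFactors = FALSE)))
}
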