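#' Abundance profile of a community sample
#'
#' Normalises per-species densities to proportions over the species
#' present in the sample. When the total density is zero the proportions
#' are undefined and flagged rather than silently set to zero.
#'
#' @param species character labels.
#' @param cfu non-negative densities, cfu/ml.
#' @return An object of class `abundance_profile`: data.frame with
#'   `species`, `cfu`, `proportion`, and attribute `undefined`.
#' @export
abundance_profile <- function(species, cfu) {
  if (length(species) != length(cfu))
    stop("species and cfu must have the same length")
  if (any(cfu < 0)) stop("densities must be >= 0")
  total <- sum(cfu)
  prop <- if (total > 0) cfu / total else rep(NA_real_, length(cfu))
  structure(data.frame(species = species, cfu = cfu, proportion = prop,
                       stringsAsFactors = FALSE),
            undefined = total == 0,
            class = c("abundance_profile", "data.frame"))
}

#' Shannon diversity
#'
#' `H = -sum p_i ln(p_i)` in nats, with `p_i` the proportion of the
#' community made up of species i; terms with `p_i = 0` contribute 0.
#' An all-zero profile is undefined and returns `NA` with a warning,
#' never 0.
#'
#' @param x an [abundance_profile], or a numeric vector of proportions or
#'   raw densities (normalised internally).
#' @return Shannon index in nats, in [0, ln(S)] for S present species.
#' @examples
#' shannon_diversity(c(0.25, 0.25, 0.25, 0.25))  # log(4)
#' @export
shannon_diversity <- function(x) {
  p <- if (inherits(x, "abundance_profile")) x$proportion else as.numeric(x)
  if (all(is.na(p)) || (!any(is.na(p)) && sum(p) == 0)) {
    warning("all-zero abundance profile: Shannon diversity undefined")
    return(NA_real_)
  }
  if (any(p < 0)) stop("proportions must be >= 0")
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Copy-number-adjusted qPCR quantification
#'
#' Converts standard-curve quantities (marker copies/ml) to cfu/ml by
#' dividing by the per-genome marker copy number.
#'
#' @param quantity non-negative copies/ml from the standard curve.
#' @param copy_number integer copies of the marker per genome (>= 1).
#' @return cfu/ml.
#' @seealso [study_copy_numbers] for the four study organisms.
#' @export
qpcr_to_cfu <- function(quantity, copy_number) {
  if (any(copy_number < 1)) stop("copy_number must be >= 1")
  if (any(quantity < 0)) stop("quantity must be >= 0")
  quantity / copy_number
}

#' Marker copy numbers of the four community species
#'
#' Per-genome qPCR marker copy numbers used for density quantification:
#' 4 (P. aeruginosa), 1 (S. aureus), 6 (A. baumannii),
#' 6 (B. cenocepacia).
#'
#' @return Named integer vector.
#' @export
study_copy_numbers <- function() {
  c(PA = 4L, SA = 1L, AB = 6L, BC = 6L)
}

#' Malthusian selection rate
#'
#' Difference in Malthusian parameters of two competing strains per unit
#' time:
#' `r = (ln(A_t / A_prev) - ln(B_t / B_prev)) / interval`.
#' Positive values mean strain A out-multiplied strain B over the
#' interval. All densities must be positive — apply the detection floor
#' upstream before taking logs.
#'
#' @param densA_t,densA_prev strain A densities at the end and start of
#'   the interval, cfu/ml.
#' @param densB_t,densB_prev strain B densities likewise.
#' @param interval elapsed time, days.
#' @return Selection rate, day^-1.
#' @examples
#' selection_rate(2e6, 1e6, 1e6, 1e6)  # log(2): A doubled, B constant
#' @export
selection_rate <- function(densA_t, densA_prev, densB_t, densB_prev,
                           interval = 1) {
  dens <- c(densA_t, densA_prev, densB_t, densB_prev)
  if (any(dens <= 0))
    stop("selection_rate needs positive densities; substitute the detection floor for zeros upstream")
  if (any(interval <= 0)) stop("interval must be > 0")
  (log(densA_t / densA_prev) - log(densB_t / densB_prev)) / interval
}

#' Fold change of final density with versus without phage
#'
#' Ratio of a species' final density in the presence of phage to the
#' matched density in its absence. Zero denominators or numerators must
#' be floored upstream; `floored` values at the detection floor keep a
#' censoring flag on the result.
#'
#' @param final_with_phage,final_no_phage final densities, cfu/ml.
#' @param censored optional logical (recycled) marking floored inputs;
#'   propagated as the `censored` attribute.
#' @return Fold change(s), with attribute `censored`.
#' @export
fold_change <- function(final_with_phage, final_no_phage, censored = FALSE) {
  if (any(final_no_phage <= 0))
    stop("final_no_phage must be > 0; apply the detection floor upstream")
  if (any(final_with_phage < 0)) stop("densities must be >= 0")
  out <- final_with_phage / final_no_phage
  attr(out, "censored") <- rep_len(as.logical(censored), length(out))
  out
}

#' Per-species fold-change table from tidy data
#'
#' Computes phage/no-phage fold changes of final densities for every
#' species in a treatment pair. Replicates are matched either by rank
#' (replicates sorted by density within arm and paired in order — the
#' default, since an experimental pairing is rarely meaningful across
#' independent arms) or collapsed to arm means.
#'
#' @param ts a [community_ts] holding a phage and a no-phage arm of the
#'   same species subset and genotype.
#' @param day sampling day to compare (default: last shared day).
#' @param pairing `"rank"` or `"mean"`.
#' @param floor detection floor substituted for zero densities, cfu/ml.
#' @return data.frame with `species`, `pair` (rank index or "mean"),
#'   `fold_change`, `censored`.
#' @export
fold_change_report <- function(ts, day = NULL,
                               pairing = c("rank", "mean"), floor = 100) {
  pairing <- match.arg(pairing)
  df <- as.data.frame(ts)
  if (is.null(day)) day <- max(df$day)
  df <- df[df$day == day, , drop = FALSE]
  arms <- split(df, df$phage > 0)
  if (length(arms) != 2)
    stop("fold_change_report needs both a phage and a no-phage arm at day ", day)
  no <- arms[["FALSE"]]; yes <- arms[["TRUE"]]
  out <- list()
  for (sp in intersect(unique(no$species), unique(yes$species))) {
    a <- yes[yes$species == sp, ]; b <- no[no$species == sp, ]
    da <- pmax(a$density_cfu_ml, floor); db <- pmax(b$density_cfu_ml, floor)
    ca <- a$censored > 0 | a$density_cfu_ml < floor
    cb <- b$censored > 0 | b$density_cfu_ml < floor
    if (pairing == "mean") {
      fc <- fold_change(mean(da), mean(db), censored = any(ca) || any(cb))
      out[[sp]] <- data.frame(species = sp, pair = "mean",
                              fold_change = as.numeric(fc),
                              censored = attr(fc, "censored"))
    } else {
      if (length(da) != length(db))
        stop(sprintf("unmatched replicate pairing for %s: %d phage vs %d no-phage replicates",
                     sp, length(da), length(db)))
      oa <- order(da); ob <- order(db)
      fc <- fold_change(da[oa], db[ob], censored = ca[oa] | cb[ob])
      out[[sp]] <- data.frame(species = sp, pair = seq_along(da),
                              fold_change = as.numeric(fc),
                              censored = attr(fc, "censored"))
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-treatment summary metrics from tidy data
#'
#' Computes, for every treatment x replicate x day, the Shannon
#' diversity of the community sample and per-species proportions.
#'
#' @param ts a [community_ts].
#' @return data.frame with one row per treatment/replicate/day:
#'   `treatment_id`, `genotype`, `phage`, `replicate`, `day`,
#'   `shannon`, `richness`, `total_cfu_ml`.
#' @export
community_metrics <- function(ts) {
  df <- as.data.frame(ts)
  key <- interaction(df$treatment_id, df$replicate, df$day, drop = TRUE)
  rows <- lapply(split(df, key), function(d) {
    data.frame(treatment_id = d$treatment_id[1], genotype = d$genotype[1],
               phage = d$phage[1], replicate = d$replicate[1],
               day = d$day[1],
               shannon = shannon_diversity(d$density_cfu_ml),
               richness = sum(d$density_cfu_ml > 0),
               total_cfu_ml = sum(d$density_cfu_ml))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$treatment_id, out$replicate, out$day), ]
}
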