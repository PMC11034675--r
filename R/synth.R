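#' Synthetic ground truth for factorial coculture experiments
#'
#' Bundles everything the synthetic-data generator needs: a base gLV
#' parameter set, optional context-dependent coefficient overrides
#' (higher-order structure), an explicit phage-host model for phage
#' treatments, measurement-noise level, detection floor and phage
#' inoculum.
#'
#' Higher-order overrides are lists with elements `i`, `j` (the affected
#' coefficient `beta[i, j]`), `context` (a third species whose presence
#' triggers the override) and `factor` (multiplier applied to the
#' coefficient). They make pairwise fits systematically wrong about
#' larger communities, which is what the pairwise-vs-triplet assembly
#' contrast probes.
#'
#' The phage model splits the focal species into susceptible and
#' resistant compartments: mass-action infection (adsorption x S x P),
#' burst-size phage production, first-order phage decay, first-order
#' susceptible-to-resistant conversion, and a growth-rate cost of
#' resistance. Genotypes differ only in conversion rate and cost.
#'
#' @param params base [glv_params] (default [community_truth_params]).
#' @param hoi list of higher-order overrides (see Details).
#' @param phage list with `adsorption` (ml pfu^-1 day^-1), `burst`
#'   (phage per lysis), `decay` (day^-1).
#' @param genotypes named list; each entry a list with `conversion`
#'   (day^-1) and `cost` (growth-rate fraction lost, in [0, 1)).
#' @param sigma lognormal measurement noise, log10 units.
#' @param floor detection floor, cfu/ml.
#' @param initial_phage phage inoculum, pfu.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params = community_truth_params(),
                            hoi = list(),
                            phage = list(adsorption = 1e-7, burst = 50,
                                         decay = 1.5),
                            genotypes = list(
                              "WT" = list(conversion = 2e-6, cost = 0.05),
                              "CRISPR-KO" = list(conversion = 2e-6,
                                                 cost = 0.15)),
                            sigma = 0.1, floor = 100,
                            initial_phage = 1e6) {
  stopifnot(inherits(params, "glv_params"))
  if (sigma < 0) stop("sigma must be >= 0")
  for (g in genotypes)
    if (g$cost < 0 || g$cost >= 1)
      stop("resistance cost must lie in [0, 1)")
  if (any(unlist(phage) < 0) ||
      any(vapply(genotypes, function(g) g$conversion < 0, TRUE)))
    stop("phage-model rates must be >= 0")
  for (h in hoi) {
    stopifnot(all(c(h$i, h$j, h$context) %in% params$species))
    if (h$factor < 0) stop("override factors must be >= 0")
  }
  structure(list(params = params, hoi = hoi, phage = phage,
                 genotypes = genotypes, sigma = sigma, floor = floor,
                 initial_phage = initial_phage),
            class = "synthetic_truth")
}

#' Default four-species community truth
#'
#' A 4-species parameter set patterned on a focal opportunistic pathogen
#' (PA) that dominates every coculture, a strong secondary competitor
#' (AB) held out only by PA, a mid-strength competitor (SA) able to
#' coexist with AB, and a weak competitor (BC). PA and AB are mutually
#' non-invasible (founder control), so once AB establishes — e.g. after
#' phage suppression of PA — PA cannot reinvade. Growth rates are sized
#' so ~1e6 cfu inocula approach saturation within a day of rich-medium
#' growth; carrying capacities sit at 10^8.5-10^9 cfu/ml.
#'
#' @return A [glv_params] over species PA, SA, AB, BC.
#' @export
community_truth_params <- function() {
  sp <- c("PA", "SA", "AB", "BC")
  r <- c(PA = 10, SA = 7, AB = 8, BC = 6)
  beta <- rbind(
    PA = c(1.0e-8, 2.0e-9, 1.5e-8, 1.0e-9),
    SA = c(2.0e-8, 1.4e-8, 6.0e-9, 4.0e-9),
    AB = c(1.2e-8, 5.0e-9, 1.0e-8, 3.0e-9),
    BC = c(1.5e-8, 6.0e-9, 1.0e-8, 2.0e-8))
  colnames(beta) <- sp
  glv_params(r = r, beta = beta, species = sp)
}

#' @rdname synthetic_truth
#' @return `community_truth` returns a complete [synthetic_truth] with
#'   the default parameters and one higher-order override (AB's
#'   inhibition of SA halved in the presence of BC).
#' @export
community_truth <- function(sigma = 0.1) {
  synthetic_truth(params = community_truth_params(),
                  hoi = list(list(i = "SA", j = "AB", context = "BC",
                                  factor = 0.5)),
                  sigma = sigma)
}

#' Subset parameters with higher-order overrides applied
#'
#' Restricts the truth's base parameters to a species subset and applies
#' every higher-order override whose affected pair and context species
#' are all present.
#'
#' @param truth a [synthetic_truth].
#' @param subset character vector of species.
#' @param apply_hoi apply the overrides (default) or return the plain
#'   restriction.
#' @return A [glv_params] on the subset.
#' @export
effective_params <- function(truth, subset, apply_hoi = TRUE) {
  p <- subset_params(truth$params, subset)
  if (apply_hoi) for (h in truth$hoi) {
    if (all(c(h$i, h$j, h$context) %in% subset))
      p$beta[h$i, h$j] <- p$beta[h$i, h$j] * h$factor
  }
  p
}

# Shared serial-transfer event table (multiplicative dilution of every
# state). With sample = "pre" events sit exactly on the transfer instants
# so coincident outputs report the mature culture; with "post" they are
# nudged 1e-9 d earlier so coincident outputs are post-dilution.
transfer_event_data <- function(state_names, t0, tmax, interval, dilution,
                                sample = "pre") {
  if (tmax - t0 < interval) return(NULL)
  tt <- seq(t0 + interval, tmax, by = interval)
  if (sample == "post") tt <- tt - 1e-9
  ev <- expand.grid(var = state_names, time = tt, stringsAsFactors = FALSE)
  ev$value <- dilution
  ev$method <- "multiply"
  ev[order(ev$time), ]
}

#' Explicit phage-host ground-truth trajectory
#'
#' Integrates the extended system behind phage treatments: the focal
#' species is split into susceptible (S) and resistant (R) compartments
#' embedded in gLV competition with the other subset members, with
#' mass-action infection `adsorption * S * P`, phage production
#' `burst * adsorption * S * P`, first-order phage decay, first-order
#' S -> R conversion, and resistant growth scaled by `1 - cost`. Serial
#' transfers dilute bacteria and phage alike. This is the generator's
#' ground truth only — the fitted models never see an explicit phage
#' state.
#'
#' @param truth a [synthetic_truth].
#' @param treatment a [treatment_design] with phage and the focal species
#'   present.
#' @param times output times, days (default: fine grid over the
#'   treatment's duration).
#' @param mode `"serial_transfer"` (default, per the treatment's
#'   schedule) or `"continuous"`.
#' @param transfer_sample `"pre"` (sample mature culture) or `"post"`.
#' @param initial_resistant_fraction fraction of the focal inoculum that
#'   is already resistant at t = 0 (default 0; set to 1 to start from a
#'   fully resistant host population).
#' @return An object of class `phage_trajectory`: data.frame with `time`,
#'   one density column per species (focal = S + R), `phage_pfu_ml`,
#'   `resistant_fraction`, plus `susceptible`/`resistant` columns.
#' @export
generate_phage_truth <- function(truth, treatment, times = NULL,
                                 mode = c("serial_transfer", "continuous"),
                                 transfer_sample = c("pre", "post"),
                                 initial_resistant_fraction = 0) {
  mode <- match.arg(mode)
  transfer_sample <- match.arg(transfer_sample)
  stopifnot(inherits(treatment, "treatment_design"))
  focal <- treatment$focal
  subset <- treatment$species_subset
  if (!focal %in% subset)
    stop("phage ground truth needs the focal species in the subset")
  if (is.null(times)) times <- seq(0, treatment$duration, by = 0.05)
  p <- effective_params(truth, subset)
  others <- setdiff(subset, focal)
  geno <- truth$genotypes[[treatment$genotype]]
  if (is.null(geno)) geno <- truth$genotypes[[1]]
  ph <- truth$phage

  ns <- length(others)
  state_names <- c(others, "S", "R", "P")
  rf0 <- initial_resistant_fraction
  if (rf0 < 0 || rf0 > 1)
    stop("initial_resistant_fraction must lie in [0, 1]")
  y0 <- c(treatment$inoculum[others],
          S = unname(treatment$inoculum[focal]) * (1 - rf0),
          R = unname(treatment$inoculum[focal]) * rf0,
          P = truth$initial_phage)
  names(y0) <- state_names
  b <- p$beta; r <- p$r
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    Nf <- y["S"] + y["R"]
    dens <- c(y[others], Nf)
    names(dens) <- c(others, focal)
    dens <- dens[subset]
    lv <- as.numeric(b %*% dens)     # per-capita inhibition, subset order
    names(lv) <- subset
    dO <- y[others] * (r[others] - lv[others])
    inf <- ph$adsorption * y["S"] * y["P"]
    dS <- y["S"] * (r[focal] - lv[focal]) - inf - geno$conversion * y["S"]
    dR <- y["R"] * ((1 - geno$cost) * r[focal] - lv[focal]) +
      geno$conversion * y["S"]
    dP <- ph$burst * inf - ph$decay * y["P"]
    list(c(dO, S = unname(dS), R = unname(dR), P = unname(dP)))
  }
  events <- NULL
  if (mode == "serial_transfer") {
    ev <- transfer_event_data(state_names, times[1], times[length(times)],
                              treatment$transfer_interval,
                              treatment$dilution_factor, transfer_sample)
    if (!is.null(ev)) events <- list(data = ev)
  }
  out <- suppressWarnings(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 events = events, rtol = 1e-8, atol = 1e-3,
                 maxsteps = 50000))
  idx <- match(round(times, 9), round(out[, 1], 9))
  if (anyNA(idx) || any(!is.finite(out[idx, ])))
    stop("phage ground-truth integration failed (non-finite state)")
  out <- out[idx, , drop = FALSE]
  m <- pmax(out[, -1, drop = FALSE], 0)
  df <- data.frame(time = out[, 1])
  for (sp in others) df[[sp]] <- m[, sp]
  df[[focal]] <- m[, "S"] + m[, "R"]
  df$susceptible <- m[, "S"]
  df$resistant <- m[, "R"]
  df$phage_pfu_ml <- m[, "P"]
  tot <- m[, "S"] + m[, "R"]
  df$resistant_fraction <- ifelse(tot > 0, m[, "R"] / tot, 1)
  class(df) <- c("phage_trajectory", "data.frame")
  df
}

# Deterministic (noise-free) sample-day densities for one treatment,
# species x day matrix in subset order.
truth_trajectory <- function(truth, treatment, mode = "serial_transfer",
                             transfer_sample = "pre") {
  subset <- treatment$species_subset
  days <- treatment$days
  if (treatment$phage && treatment$focal %in% subset) {
    tr <- generate_phage_truth(truth, treatment, times = days, mode = mode,
                               transfer_sample = transfer_sample)
    t(as.matrix(tr[, subset, drop = FALSE]))
  } else {
    p <- effective_params(truth, subset)
    arr <- glv_integrate(p, matrix(treatment$inoculum[subset], ncol = 1),
                         days, mode, treatment$dilution_factor,
                         treatment$transfer_interval, transfer_sample)
    t(matrix(arr[, , 1], nrow = length(days),
             dimnames = list(NULL, subset)))
  }
}

#' Generate a synthetic factorial dataset
#'
#' Simulates every treatment of a design from the ground truth (explicit
#' phage-host model for phage treatments, plain gLV otherwise) under the
#' treatment's serial-transfer schedule, samples the scheduled days
#' (mature culture, before the same-day dilution), applies multiplicative
#' lognormal measurement noise of `truth$sigma` log10 units per
#' observation and replicate, and censors at the detection floor
#' (recorded density = floor, `censored = 1`). Fully reproducible from
#' the seed.
#'
#' @param truth a [synthetic_truth].
#' @param design list of [treatment_design] objects (see
#'   [generate_design]).
#' @param seed integer seed.
#' @param mode `"serial_transfer"` (default) or `"continuous"` culture.
#' @return A [community_ts] covering all treatments and replicates.
#' @export
generate_dataset <- function(truth, design, seed = 1,
                             mode = c("serial_transfer", "continuous")) {
  mode <- match.arg(mode)
  if (inherits(design, "treatment_design")) design <- list(design)
  with_seed(seed, {
    rows <- vector("list", length(design))
    for (ti in seq_along(design)) {
      trt <- design[[ti]]
      dens <- truth_trajectory(truth, trt, mode = mode)  # species x day
      subset <- trt$species_subset
      nd <- length(trt$days); nsp <- length(subset)
      reps <- vector("list", trt$replicates)
      for (k in seq_len(trt$replicates)) {
        noisy <- dens * 10^matrix(rnorm(nsp * nd, 0, truth$sigma), nsp, nd)
        cens <- noisy <= truth$floor
        noisy[cens] <- truth$floor
        reps[[k]] <- data.frame(
          treatment_id = trt$treatment_id, genotype = trt$genotype,
          phage = as.integer(trt$phage), replicate = k,
          day = rep(trt$days, each = nsp),
          species = rep(subset, nd),
          density_cfu_ml = as.vector(noisy),
          censored = as.integer(as.vector(cens)),
          stringsAsFactors = FALSE)
      }
      rows[[ti]] <- do.call(rbind, reps)
    }
    community_ts(do.call(rbind, rows))
  })
}

#' Benchmark systems for recovery and prediction studies
#'
#' Reference parameter sets whose dynamics make interaction coefficients
#' well expressed in data sampled at days 0, 1, 3, 7 and 10 — the
#' regimes used by the package's Monte-Carlo recovery and
#' assembly-contrast studies. Coefficient recovery requires the
#' interactions to shape the observed trajectories: near-instant
#' saturation leaves only quasi-equilibrium information (a ridge between
#' each row's coefficients), while species censored at the detection
#' floor carry no information at all about their coefficients.
#'
#' `benchmark_pair_params` is a strongly and mutually competing pair on
#' a ~2 day^-1 growth timescale, for continuous-culture recovery
#' studies: the transient spans the sampling window and both
#' off-diagonal effects leave sustained signatures.
#'
#' `benchmark_community_params` is a 4-species system for
#' serial-transfer studies (growth rates above the ln(100) ~ 4.6 day^-1
#' washout limit of daily 1:100 passage) with asymmetric competition
#' tuned so losing species decline slowly and remain above the
#' detection floor through day 10.
#'
#' `benchmark_hoi_truth` wraps a slower-timescale 4-species system with
#' two strong higher-order overrides (one amplified, one attenuated
#' coefficient, each conditional on a third species) and sigma = 0.05
#' noise, for contrasting pairwise-only against triplet-informed
#' assembly on held-out full-community data.
#'
#' @return A [glv_params] (`benchmark_pair_params`,
#'   `benchmark_community_params`) or a [synthetic_truth]
#'   (`benchmark_hoi_truth`).
#' @export
benchmark_pair_params <- function() {
  sp <- c("A", "B")
  glv_params(r = c(A = 2, B = 1.6),
             beta = matrix(c(2e-9, 1.5e-9, 2.5e-9, 3.2e-9), 2, 2,
                           byrow = TRUE, dimnames = list(sp, sp)))
}

#' @rdname benchmark_pair_params
#' @export
benchmark_community_params <- function() {
  sp <- c("PA", "SA", "AB", "BC")
  r <- c(PA = 7, SA = 6, AB = 6.5, BC = 5.5)
  K <- c(1e9, 5e8, 8e8, 3e8)
  beta <- diag(r / K)
  dimnames(beta) <- list(sp, sp)
  fac <- matrix(c(0, .5, .6, .4,
                  1.1, 0, .5, .45,
                  .9, .5, 0, .4,
                  1.15, .6, .55, 0), 4, 4, byrow = TRUE)
  for (i in 1:4) for (j in 1:4)
    if (i != j) beta[i, j] <- fac[i, j] * r[i] / K[j]
  glv_params(r = r, beta = beta, species = sp)
}

#' @rdname benchmark_pair_params
#' @export
benchmark_hoi_truth <- function() {
  sp <- c("PA", "SA", "AB", "BC")
  r <- c(PA = 2, SA = 1.7, AB = 1.8, BC = 1.5)
  K <- c(1e9, 5e8, 8e8, 3e8)
  beta <- diag(r / K)
  dimnames(beta) <- list(sp, sp)
  fac <- matrix(c(0, .5, .6, .4,
                  .9, 0, .5, .45,
                  .8, .5, 0, .4,
                  .95, .6, .55, 0), 4, 4, byrow = TRUE)
  for (i in 1:4) for (j in 1:4)
    if (i != j) beta[i, j] <- fac[i, j] * r[i] / K[j]
  synthetic_truth(params = glv_params(r = r, beta = beta, species = sp),
                  hoi = list(list(i = "SA", j = "PA", context = "AB",
                                  factor = 3),
                             list(i = "AB", j = "SA", context = "BC",
                                  factor = 0.3)),
                  sigma = 0.05)
}
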