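# Internal scale on which interaction coefficients are optimized:
# theta = beta * 1e9, so typical coefficients (1e-12..1e-6 ml cfu^-1 day^-1)
# become O(1e-3..1e3) and the Levenberg-Marquardt steps are well scaled.
THETA_SCALE <- 1e9

# Logistic growth towards K = r/beta_ii, written in the overflow-safe form
# N(t) = K / (1 + (K/N0 - 1) exp(-r t)).
logistic_density <- function(t, r, K, N0) {
  K / (1 + (K / N0 - 1) * exp(-r * t))
}

#' Fit monoculture growth rates
#'
#' Estimates each species' maximal growth rate `r_i` and self-limitation
#' `beta_ii` (equivalently the carrying capacity `K_i = r_i / beta_ii`)
#' from monoculture time series by bounded nonlinear least squares on
#' log10 densities against the logistic solution (continuous mode) or a
#' one-species serial-transfer simulation. Downstream fitting treats the
#' returned `r` as fixed — the first rung of the bottom-up scheme.
#'
#' Initial densities are fixed at each replicate's day-0 observation.
#' Series with no growth signal yield `r` near the zero bound and are
#' flagged `degenerate` (with a warning); series that never approach their
#' plateau leave `beta_ii` unconstrained, which is flagged `weak_K`.
#'
#' @param mono a [community_ts] holding monoculture data only (each
#'   treatment contains a single species); several treatments/replicates
#'   per species are pooled.
#' @param mode,dilution,interval,transfer_sample culture regime under
#'   which the data were collected; see [glv_simulate].
#' @param floor detection floor, cfu/ml; censored points are excluded.
#' @return An object of class `glv_growth_fit`: named vectors `r`
#'   (day^-1), `beta_ii` (ml cfu^-1 day^-1), `K` (cfu/ml), logical flags
#'   `degenerate`, `weak_K` and `weak_r` (profile-flatness diagnostics),
#'   and per-species objective values.
#' @export
fit_growth_rates <- function(mono,
                             mode = c("continuous", "serial_transfer"),
                             dilution = 0.01, interval = 1,
                             transfer_sample = c("pre", "post"),
                             floor = 100) {
  mode <- match.arg(mode)
  transfer_sample <- match.arg(transfer_sample)
  mono <- as.data.frame(mono)
  per_trt <- split(mono$species, mono$treatment_id)
  poly <- names(per_trt)[vapply(per_trt, function(s) length(unique(s)) > 1, TRUE)]
  if (length(poly))
    stop("not monoculture data: treatments with >1 species: ",
         paste(poly, collapse = ", "))
  species <- unique(mono$species)
  res <- list()
  for (sp in species) {
    d <- mono[mono$species == sp, , drop = FALSE]
    d$replicate <- interaction(d$treatment_id, d$replicate, drop = TRUE)
    a <- ts_arrays(d, species = sp)
    if (all(a$cens))
      stop(sprintf("monoculture series for %s is entirely censored", sp))
    res[[sp]] <- fit_one_growth(a, sp, mode, dilution, interval,
                                transfer_sample)
  }
  out <- list(
    r = vapply(res, `[[`, numeric(1), "r"),
    beta_ii = vapply(res, `[[`, numeric(1), "beta_ii"),
    K = vapply(res, `[[`, numeric(1), "K"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    weak_K = vapply(res, `[[`, logical(1), "weak_K"),
    weak_r = vapply(res, `[[`, logical(1), "weak_r"),
    objective = vapply(res, `[[`, numeric(1), "objective"),
    mode = mode)
  class(out) <- "glv_growth_fit"
  out
}

fit_one_growth <- function(a, sp, mode, dilution, interval, transfer_sample) {
  days <- a$days
  obs <- a$obs[, 1, , drop = FALSE]   # [day, 1, rep]
  cens <- a$cens[, 1, , drop = FALSE]
  nrep <- dim(obs)[3]
  N0 <- obs[1, 1, ]
  mask <- !cens & obs > 0
  mask[1, , ] <- FALSE                # day-0 residuals are 0 by construction
  logobs <- log10(obs)

  predict_rep <- function(r, K) {
    if (mode == "continuous") {
      sapply(N0, function(n0) logistic_density(days, r, K, n0))
    } else {
      p <- glv_params(r = setNames(r, sp), beta = matrix(r / K, 1, 1))
      arr <- glv_integrate(p, matrix(N0, nrow = 1), days, "serial_transfer",
                           dilution, interval, transfer_sample)
      matrix(arr[, 1, ], nrow = length(days))
    }
  }
  resid <- function(par) {
    pred <- try(predict_rep(par[1], 10^par[2]), silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred)))
      return(rep(1e4, sum(mask)))
    (log10(pmax(pred, 1e-12)) - logobs[, 1, ])[mask[, 1, ]]
  }
  obj <- function(par) sum(resid(par)^2)

  mean_log <- rowMeans(logobs[, 1, , drop = FALSE], na.rm = TRUE)
  slopes <- diff(mean_log) / diff(days) * log(10)
  r0 <- max(slopes, 1e-3)
  K0 <- max(obs)
  # r capped at 30 day^-1 (~33 min doubling), the fastest rate plausible
  # for these organisms; sparse daily sampling only bounds r from below
  # once a culture saturates within the first interval.
  r_max <- 30
  starts <- list(c(r0, log10(K0)), c(3 * r0, log10(K0) + 1),
                 c(r0 / 3, log10(K0)))
  best <- NULL
  for (s in starts) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = pmin(pmax(s, c(0, 2)), c(r_max, 12)), lower = c(0, 2),
      upper = c(r_max, 12), fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop(sprintf("growth-rate fit failed for %s", sp))
  r_hat <- best$par[1]
  K_hat <- 10^best$par[2]
  o1 <- best$deviance
  degenerate <- r_hat < 1e-2 || max(obs) / max(min(obs), 1) < 1.5
  if (degenerate)
    warning(sprintf("%s: no usable growth signal; r is unidentifiable (fit pinned near the r >= 0 bound)", sp))
  # flatness profiles: K weakly identified when the data never approach
  # the plateau; r weakly identified (upward) when growth saturates
  # within the first sampling interval.
  o2 <- obj(c(r_hat, min(best$par[2] + 1, 12)))
  weak_K <- is.finite(o2) && (o2 - o1) < max(1e-6, 0.01 * o1)
  o3 <- obj(c(min(1.5 * r_hat, r_max), best$par[2]))
  weak_r <- !degenerate && is.finite(o3) &&
    (o3 - o1) < max(1e-6, 0.01 * o1) && r_hat > r0
  list(r = r_hat, beta_ii = r_hat / K_hat, K = K_hat,
       degenerate = degenerate, weak_K = weak_K, weak_r = weak_r,
       objective = o1)
}

#' @export
print.glv_growth_fit <- function(x, ...) {
  cat("monoculture growth fits:\n")
  print(data.frame(r = signif(x$r, 4), K = signif(x$K, 4),
                   beta_ii = signif(x$beta_ii, 4),
                   degenerate = x$degenerate, weak_K = x$weak_K,
                   weak_r = x$weak_r))
  invisible(x)
}

#' Fit interaction coefficients for one species subset
#'
#' Estimates the full `beta` block of a 2- or 3-species (or larger)
#' subcommunity by pooled bounded nonlinear least squares: every replicate
#' trajectory is simulated from its observed day-0 densities under trial
#' coefficients, and squared residuals on the fitting scale (log10 by
#' default) are summed over all uncensored observations of all
#' replicates. Growth rates are fixed (bottom-up scheme); all `beta`
#' entries of the subset, diagonal included, are free unless
#' `fix_diag = TRUE` pins the diagonal to `beta_diag`.
#'
#' The objective is multi-modal, so the optimizer is restarted from
#' `n_starts` seeded initial points: one informed start (diagonal at the
#' monoculture estimate or `r_i` / max observed density, off-diagonals
#' small) plus log-uniform draws of beta over [1e-12, 1e-6]
#' ml cfu^-1 day^-1. The best deviance wins and its start seed is
#' recorded.
#'
#' @param data a [community_ts] with all replicates of one species-subset
#'   treatment (shared sampling days).
#' @param r_fixed named growth-rate vector covering the subset, day^-1.
#' @param beta_diag optional named vector initializing (or, with
#'   `fix_diag`, fixing) the self-limitation terms.
#' @param fix_diag fix the diagonal to `beta_diag` instead of fitting it.
#' @param bounds length-2 search box for every coefficient,
#'   ml cfu^-1 day^-1.
#' @param fitting_scale `"log10"` (residuals on log10 densities) or
#'   `"linear"`.
#' @param n_starts number of optimizer starts.
#' @param seed integer seed controlling the start draws.
#' @param mode,dilution,interval,transfer_sample culture regime matching
#'   the data; see [glv_simulate].
#' @param floor detection floor, cfu/ml.
#' @param censored `"exclude"` drops censored points from the objective;
#'   `"penalize"` adds a one-sided penalty when the model predicts above
#'   the floor at a censored point.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param context optional list with `phage` and `genotype` labels stored
#'   with the result (inferred from the data when absent).
#' @return An object of class `glv_fit`: the estimated `beta` matrix,
#'   the fixed quantities, objective value, convergence diagnostics,
#'   per-species identifiability flags and the fitting context.
#' @export
fit_interactions <- function(data, r_fixed, beta_diag = NULL,
                             fix_diag = FALSE, bounds = c(0, 1e-5),
                             fitting_scale = c("log10", "linear"),
                             n_starts = 16, seed = 1,
                             mode = c("continuous", "serial_transfer"),
                             dilution = 0.01, interval = 1,
                             transfer_sample = c("pre", "post"),
                             floor = 100,
                             censored = c("exclude", "penalize"),
                             maxiter = 100, context = NULL) {
  fitting_scale <- match.arg(fitting_scale)
  mode <- match.arg(mode)
  transfer_sample <- match.arg(transfer_sample)
  censored <- match.arg(censored)
  df <- as.data.frame(data)
  sp <- names(r_fixed)[names(r_fixed) %in% unique(df$species)]
  extra <- setdiff(unique(df$species), names(r_fixed))
  if (length(extra))
    stop("r_fixed does not cover species: ", paste(extra, collapse = ", "))
  n <- length(sp)
  a <- ts_arrays(df, species = sp)
  days <- a$days
  nrep <- dim(a$obs)[3]
  ic <- matrix(a$obs[1, , ], nrow = n)   # day-0 observations, fixed as ICs
  mask <- !a$cens & a$obs > 0
  mask[1, , ] <- FALSE
  unident <- sp[vapply(seq_len(n),
                       function(j) !any(mask[, j, , drop = FALSE]), TRUE)]
  logobs <- log10(pmax(a$obs, 1e-12))
  cmask <- a$cens
  cmask[1, , ] <- FALSE

  free <- matrix(TRUE, n, n, dimnames = list(sp, sp))
  beta_fix <- matrix(0, n, n, dimnames = list(sp, sp))
  if (fix_diag) {
    if (is.null(beta_diag))
      stop("fix_diag = TRUE requires beta_diag")
    diag(free) <- FALSE
    diag(beta_fix) <- beta_diag[sp]
  }
  free_idx <- which(free)
  npar <- length(free_idx)
  rvec <- r_fixed[sp]

  theta_to_beta <- function(theta) {
    b <- beta_fix
    b[free_idx] <- theta / THETA_SCALE
    b
  }
  simulate_pred <- function(beta) {
    p <- glv_params(r = rvec, beta = beta, species = sp)
    glv_integrate(p, ic, days, mode, dilution, interval, transfer_sample)
  }
  n_res <- sum(mask) + if (censored == "penalize") sum(cmask) else 0
  resid <- function(theta) {
    pred <- try(simulate_pred(theta_to_beta(theta)), silent = TRUE)
    if (inherits(pred, "try-error")) return(rep(1e4, n_res))
    r1 <- if (fitting_scale == "log10")
      (log10(pmax(pred, 1e-12)) - logobs)[mask]
    else (pred - a$obs)[mask]
    if (censored == "penalize") {
      pen <- pmax(log10(pmax(pred, 1e-12)) - log10(floor), 0)[cmask]
      r1 <- c(r1, pen)
    }
    r1
  }

  # start values
  diag0 <- if (!is.null(beta_diag)) beta_diag[sp]
           else rvec / apply(a$obs, 2, max)
  informed <- matrix(1e-10, n, n); diag(informed) <- diag0
  lower <- rep(bounds[1] * THETA_SCALE, npar)
  upper <- rep(bounds[2] * THETA_SCALE, npar)
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter)
  best <- NULL; best_seed <- NA_integer_
  for (k in seq_len(n_starts)) {
    seed_k <- seed * 1000L + k
    theta0 <- if (k == 1) informed[free_idx] * THETA_SCALE
              else with_seed(seed_k, 10^runif(npar, -12, -6) * THETA_SCALE)
    theta0 <- pmin(pmax(theta0, lower), upper)
    # iteration-cap warnings are expected for some starts; convergence is
    # reported through the best start's info code instead
    fit <- try(suppressWarnings(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = resid, control = ctrl)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit; best_seed <- seed_k
    }
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, context = context,
                          species = sp, objective = Inf),
                     class = "glv_fit"))
  if (is.null(context)) context <- list()
  context$species <- sp
  if (is.null(context$phage)) context$phage <- unique(df$phage)[1] > 0
  if (is.null(context$genotype)) context$genotype <- unique(df$genotype)[1]

  structure(list(
    context = context, species = sp,
    beta = theta_to_beta(best$par),
    fixed = c(list(r = rvec),
              if (fix_diag) list(beta_diag = beta_diag[sp])),
    free = free, bounds = bounds,
    objective = best$deviance,
    fitting_scale = fitting_scale, mode = mode,
    n_starts = n_starts, best_start_seed = best_seed,
    converged = best$info %in% 1:3,
    unidentifiable = unident,
    n_obs = sum(mask), n_replicates = nrep), class = "glv_fit")
}

#' @export
print.glv_fit <- function(x, ...) {
  cat(sprintf("gLV interaction fit: %s%s%s | objective %.4g | converged: %s\n",
              paste(x$species, collapse = "+"),
              if (isTRUE(x$context$phage)) " +phage" else "",
              if (!is.null(x$context$genotype)) paste0(" (", x$context$genotype, ")") else "",
              x$objective, x$converged))
  if (!is.null(x$beta)) print(signif(x$beta, 4))
  if (length(x$unidentifiable))
    cat("unidentifiable species (no uncensored observations):",
        paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

context_label <- function(ctx) {
  paste0(paste(ctx$species, collapse = "+"),
         if (isTRUE(ctx$phage)) "+phage" else "",
         if (!is.null(ctx$genotype)) paste0("|", ctx$genotype) else "")
}

#' Assemble a community interaction matrix from subset fits
#'
#' Combines `beta` estimates from 2- and/or 3-species fits into the
#' interaction matrix of the full community. Each entry (i, j) is the
#' arithmetic mean of that coefficient over every contributing context
#' admitted by the strategy, with the contributing contexts recorded as
#' provenance; diagonal entries are averaged identically.
#'
#' Strategies: `"pairwise_only"` uses 2-species fits alone (the baseline
#' whose predictive failure diagnoses higher-order interactions),
#' `"triplet_only"` uses 3-species fits alone (the phage-case default),
#' and `"average_pair_triplet"` averages over both (the no-phage
#' default).
#'
#' @param fits list of [fit_interactions] results jointly covering every
#'   ordered species pair of the target community under the strategy.
#' @param strategy one of `"average_pair_triplet"`, `"pairwise_only"`,
#'   `"triplet_only"`.
#' @param species target species order; defaults to the union over fits.
#' @return An object of class `glv_matrix`: `beta`, per-entry
#'   `provenance` (contexts and values), `strategy` and `species`.
#' @export
assemble_matrix <- function(fits,
                            strategy = c("average_pair_triplet",
                                         "pairwise_only", "triplet_only"),
                            species = NULL) {
  strategy <- match.arg(strategy)
  if (inherits(fits, "glv_fit")) fits <- list(fits)
  sizes <- vapply(fits, function(f) length(f$species), 1L)
  keep <- switch(strategy,
                 pairwise_only = sizes == 2,
                 triplet_only = sizes == 3,
                 average_pair_triplet = sizes %in% 2:3)
  fits <- fits[keep]
  if (!length(fits)) stop("no fits admitted by strategy ", strategy)
  if (is.null(species))
    species <- unique(unlist(lapply(fits, `[[`, "species")))
  n <- length(species)
  beta <- matrix(NA_real_, n, n, dimnames = list(species, species))
  prov <- list()
  missing <- character()
  for (i in species) for (j in species) {
    vals <- numeric(); ctxs <- character()
    for (f in fits) {
      if (i %in% f$species && j %in% f$species && !is.null(f$beta)) {
        vals <- c(vals, f$beta[i, j])
        ctxs <- c(ctxs, context_label(f$context))
      }
    }
    key <- paste(i, j, sep = "|")
    if (!length(vals)) { missing <- c(missing, key); next }
    beta[i, j] <- mean(vals)
    prov[[key]] <- data.frame(context = ctxs, value = vals,
                              stringsAsFactors = FALSE)
  }
  if (length(missing))
    stop("strategy ", strategy, " leaves entries uncovered: ",
         paste(missing, collapse = ", "))
  structure(list(species = species, beta = beta, provenance = prov,
                 strategy = strategy), class = "glv_matrix")
}

#' @export
print.glv_matrix <- function(x, ...) {
  cat(sprintf("assembled interaction matrix (%s), %d species:\n",
              x$strategy, length(x$species)))
  print(signif(x$beta, 4))
  invisible(x)
}

#' Turn an assembled matrix into a simulatable parameter set
#'
#' @param assembled a [assemble_matrix] result.
#' @param r named growth-rate vector covering the assembled species.
#' @return A [glv_params] object.
#' @export
as_glv_params <- function(assembled, r) {
  glv_params(r = r[assembled$species], beta = assembled$beta,
             species = assembled$species, signed = any(assembled$beta < 0))
}

#' Score full-community predictions against held-out data
#'
#' Simulates the community from the per-species means of the held-out
#' day-0 observations under the assembled matrix and fixed growth rates,
#' then reports root-mean-square error on log10 densities over all
#' uncensored held-out observations after day 0 (day 0 supplies the
#' initial condition and is not scored), overall and per species.
#'
#' @param assembled a [assemble_matrix] result (or a [glv_params]).
#' @param r named growth-rate vector.
#' @param heldout a [community_ts] of the held-out treatment.
#' @param mode,dilution,interval,transfer_sample culture regime of the
#'   held-out data; see [glv_simulate].
#' @return An object of class `glv_score` with `rmse` (overall, log10
#'   units), `rmse_species`, `n_obs` and the predicted trajectory.
#' @export
predict_and_score <- function(assembled, r, heldout,
                              mode = c("continuous", "serial_transfer"),
                              dilution = 0.01, interval = 1,
                              transfer_sample = c("pre", "post")) {
  mode <- match.arg(mode)
  transfer_sample <- match.arg(transfer_sample)
  df <- as.data.frame(heldout)
  sp_data <- unique(df$species)
  pool <- if (inherits(assembled, "glv_params")) assembled$species
          else assembled$species
  miss <- setdiff(sp_data, pool)
  if (length(miss))
    stop("held-out data contain species absent from the assembled matrix: ",
         paste(miss, collapse = ", "))
  sp <- pool[pool %in% sp_data]
  params <- if (inherits(assembled, "glv_params")) subset_params(assembled, sp)
            else subset_params(as_glv_params(assembled, r), sp)
  a <- ts_arrays(df, species = sp)
  init <- rowMeans(matrix(a$obs[1, , ], nrow = length(sp)))
  arr <- glv_integrate(params, matrix(init, ncol = 1), a$days, mode,
                       dilution, interval, transfer_sample)
  pred <- matrix(arr[, , 1], nrow = length(a$days),
                 dimnames = list(NULL, sp))
  mask <- !a$cens & a$obs > 0
  mask[1, , ] <- FALSE   # day 0 seeds the prediction; it is not scored
  logpred <- log10(pmax(pred, 1e-12))
  err2 <- array(NA_real_, dim = dim(a$obs))
  for (k in seq_len(dim(a$obs)[3]))
    err2[, , k] <- (logpred - log10(pmax(a$obs[, , k], 1e-12)))^2
  rmse_sp <- vapply(seq_along(sp), function(j) {
    m <- mask[, j, ]
    if (!any(m)) return(NA_real_)
    sqrt(mean(err2[, j, ][m]))
  }, numeric(1))
  names(rmse_sp) <- sp
  structure(list(rmse = sqrt(mean(err2[mask])), rmse_species = rmse_sp,
                 n_obs = sum(mask),
                 predicted = data.frame(day = rep(a$days, length(sp)),
                                        species = rep(sp, each = length(a$days)),
                                        density_cfu_ml = as.vector(pred))),
            class = "glv_score")
}

#' @export
print.glv_score <- function(x, ...) {
  cat(sprintf("held-out fit: overall RMSE %.3f log10 units over %d observations\n",
              x$rmse, x$n_obs))
  print(signif(x$rmse_species, 3))
  invisible(x)
}
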