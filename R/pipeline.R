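#' Default pipeline configuration
#'
#' Returns the configuration skeleton consumed by [run_pipeline]. Any
#' subset of fields may be overridden by the user's config (a nested
#' list or YAML file); unknown fields are rejected during validation.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    species = c("PA", "SA", "AB", "BC"),
    focal = "PA",
    genotypes = "WT",
    replicates = 6L,
    days = c(0, 1, 3, 7, 10),
    phage_rule = "all",
    sigma = 0.1,
    input = NULL,                      # tidy CSV path; NULL -> synthesize
    outdir = NULL,
    fit = list(mode = "serial_transfer", fitting_scale = "log10",
               n_starts = 16L, maxiter = 100L, bounds = c(0, 1e-5)),
    strategy = list(no_phage = "average_pair_triplet",
                    phage = "triplet_only"),
    analysis = list(horizon = 200, threshold = 100),
    verbose = TRUE)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

species_per_treatment <- function(data) {
  lapply(split(data$species, data$treatment_id), unique)
}

#' Run the bottom-up modelling pipeline
#'
#' Executes the full workflow on either a supplied tidy dataset or a
#' freshly synthesized one: (1) synthesize/load data, (2) fix growth
#' rates from no-phage monocultures, (3) fit interaction coefficients for
#' every 2- and 3-species treatment per (phage, genotype) context, (4)
#' assemble community interaction matrices (no-phage default: average of
#' pair and triplet fits; phage default: triplet fits only), (5) score
#' the 4-species predictions against the held-out full-community data,
#' (6) classify long-run outcomes, and (7) compute community metrics and
#' phage/no-phage fold changes. Every artifact is written under
#' `config$outdir` (when set) as it is produced, together with a manifest
#' recording the config hash and seed, so a run is regenerable from
#' config + seed alone.
#'
#' @param config nested list, or path to a YAML file, overriding
#'   [default_config].
#' @return Invisibly, a list with elements `config`, `data`, `growth`,
#'   `fits`, `matrices`, `scores`, `outcomes`, `metrics`, `fold_changes`
#'   and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("stage %-16s done in %.1f s", name,
        proc.time()[["elapsed"]] - t0)
    out
  }
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  persist <- function(obj, file, writer) {
    if (!is.null(outdir)) writer(obj, file.path(outdir, file))
  }

  # -- validation (fail fast, before any compute) -----------------------
  data <- stage("validate", {
    if (!cfg$focal %in% cfg$species)
      stop("focal species ", cfg$focal, " not in configured species")
    if (!is.null(cfg$input)) {
      d <- read_community_ts(cfg$input)
      extra <- setdiff(unique(d$species), cfg$species)
      if (length(extra))
        stop("data contain species absent from the config: ",
             paste(extra, collapse = ", "))
      d
    } else NULL
  })

  # -- synthesize -------------------------------------------------------
  truth <- NULL
  if (is.null(data)) {
    data <- stage("synth", {
      truth <- community_truth(sigma = cfg$sigma)
      miss <- setdiff(cfg$species, truth$params$species)
      if (length(miss))
        stop("default truth lacks species: ", paste(miss, collapse = ", "))
      design <- generate_design(cfg$species, focal = cfg$focal,
                                phage_rule = cfg$phage_rule,
                                genotypes = cfg$genotypes,
                                replicates = cfg$replicates,
                                days = cfg$days)
      generate_dataset(truth, design, seed = cfg$seed)
    })
  }
  persist(data, "dataset.csv", write_community_ts)

  spt <- species_per_treatment(data)
  fit_mode <- cfg$fit$mode
  trt_meta <- unique(as.data.frame(data)[c("treatment_id", "genotype", "phage")])

  # -- growth rates from no-phage monocultures --------------------------
  growth <- stage("growth_rates", {
    mono_ids <- names(spt)[vapply(spt, length, 1L) == 1]
    mono_ids <- intersect(mono_ids,
                          trt_meta$treatment_id[trt_meta$phage == 0])
    if (!length(mono_ids)) stop("no no-phage monoculture treatments found")
    fit_growth_rates(data[data$treatment_id %in% mono_ids, ],
                     mode = fit_mode)
  })
  if (!is.null(outdir))
    yaml::write_yaml(list(r = as.list(growth$r), K = as.list(growth$K),
                          beta_ii = as.list(growth$beta_ii)),
                     file.path(outdir, "growth_rates.yaml"))

  # -- interaction fits per (phage, genotype) context -------------------
  # fitting contexts: one per (phage, focal genotype) among polycultures;
  # non-focal subsets (genotype "none") are shared across genotypes
  contexts <- unique(trt_meta[vapply(spt[trt_meta$treatment_id],
                                     length, 1L) > 1, c("phage", "genotype")])
  contexts <- contexts[contexts$genotype != "none", , drop = FALSE]
  fits <- stage("fit_interactions", {
    res <- list()
    for (ci in seq_len(nrow(contexts))) {
      ph <- contexts$phage[ci]; gt <- contexts$genotype[ci]
      ids <- trt_meta$treatment_id[trt_meta$phage == ph &
                                     trt_meta$genotype %in% c(gt, "none")]
      ids <- ids[vapply(spt[ids], length, 1L) %in% 2:3]
      ctx_fits <- lapply(ids, function(id) {
        say("  fitting %s", id)
        fit_interactions(data[data$treatment_id == id, ],
                         r_fixed = growth$r, beta_diag = growth$beta_ii,
                         bounds = cfg$fit$bounds,
                         fitting_scale = cfg$fit$fitting_scale,
                         n_starts = cfg$fit$n_starts, seed = cfg$seed + ci,
                         mode = fit_mode, maxiter = cfg$fit$maxiter,
                         context = list(phage = ph > 0, genotype = gt))
      })
      names(ctx_fits) <- ids
      res[[paste0(if (ph > 0) "phage" else "nophage", "_", gt)]] <- ctx_fits
    }
    res
  })

  # -- assembly, prediction, outcome per context ------------------------
  matrices <- list(); scores <- list(); outcomes <- list()
  full <- names(spt)[vapply(spt, function(s)
    setequal(s, cfg$species), TRUE)]
  stage("assemble_predict", {
    for (ctx in names(fits)) {
      ph <- startsWith(ctx, "phage")
      strat <- if (ph) cfg$strategy$phage else cfg$strategy$no_phage
      m <- assemble_matrix(fits[[ctx]], strategy = strat,
                           species = cfg$species)
      matrices[[ctx]] <- m
      if (!is.null(outdir))
        write_glv_params(as_glv_params(m, growth$r),
                         file.path(outdir, paste0("matrix_", ctx, ".yaml")))
      gt <- sub("^(no)?phage_", "", ctx)
      held_ids <- intersect(full,
        trt_meta$treatment_id[(trt_meta$phage > 0) == ph &
                                trt_meta$genotype %in% c(gt, "none")])
      if (length(held_ids)) {
        held <- data[data$treatment_id %in% held_ids, ]
        scores[[ctx]] <- predict_and_score(m, growth$r, held,
                                            mode = fit_mode)
        a <- ts_arrays(held, species = cfg$species)
        init <- rowMeans(matrix(a$obs[1, , ], nrow = length(cfg$species)))
        names(init) <- cfg$species
        outcomes[[ctx]] <- classify_outcome(
          as_glv_params(m, growth$r), init,
          horizon = cfg$analysis$horizon,
          threshold = cfg$analysis$threshold)
      }
    }
    NULL
  })

  # -- metrics ----------------------------------------------------------
  metrics <- stage("metrics", community_metrics(data))
  persist(metrics, "metrics.csv",
          function(x, p) write.csv(x, p, row.names = FALSE))
  fold <- stage("fold_changes", {
    out <- list()
    subs <- vapply(spt, function(s) paste(sort(s), collapse = "+"), "")
    for (s in unique(subs)) {
      ids <- names(subs)[subs == s]
      d <- data[data$treatment_id %in% ids, ]
      if (length(unique(d$phage)) == 2) {
        for (gt in setdiff(unique(d$genotype), character(0))) {
          dg <- d[d$genotype %in% c(gt, "none"), ]
          if (length(unique(dg$phage)) == 2) {
            fc <- try(fold_change_report(dg), silent = TRUE)
            if (!inherits(fc, "try-error")) {
              fc$subset <- s; fc$genotype <- gt
              out[[paste(s, gt)]] <- fc
            }
          }
        }
      }
    }
    if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else NULL
  })
  if (!is.null(fold))
    persist(fold, "fold_changes.csv",
            function(x, p) write.csv(x, p, row.names = FALSE))

  # -- manifest ---------------------------------------------------------
  manifest <- stage("manifest", {
    cfg_file <- file.path(if (is.null(outdir)) tempdir() else outdir,
                          "config.yaml")
    cfg_store <- cfg; cfg_store$verbose <- NULL
    yaml::write_yaml(cfg_store, cfg_file)
    list(config_hash = unname(tools::md5sum(cfg_file)),
         seed = cfg$seed,
         package_version = as.character(utils::packageVersion("glvcomm")),
         contexts = names(fits),
         objectives = lapply(fits, function(fl)
           vapply(fl, `[[`, numeric(1), "objective")))
  })
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, data = data, truth = truth, growth = growth,
                 fits = fits, matrices = matrices, scores = scores,
                 outcomes = outcomes, metrics = metrics,
                 fold_changes = fold, manifest = manifest))
}
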