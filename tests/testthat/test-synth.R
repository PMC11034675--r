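test_that("the factorial design enumerates all subsets with the study's constants", {
  sp <- c("PA", "SA", "AB", "BC")
  d <- generate_design(sp, phage_rule = "none")
  expect_length(d, 15)                               # 2^4 - 1 subsets
  with_focal <- vapply(d, function(t) "PA" %in% t$species_subset, TRUE)
  expect_equal(sum(with_focal), 8)
  expect_true(all(vapply(d, `[[`, 1, "replicates") == 6))
  expect_equal(d[[1]]$days, c(0, 1, 3, 7, 10))

  # fully factorial phage rule doubles the arms
  d2 <- generate_design(sp, phage_rule = "all")
  expect_length(d2, 30)

  # inoculum split: focal 25%, competitors share the remainder equally
  t4 <- treatment_design(sp, focal = "PA")
  expect_equal(unname(t4$inoculum["PA"]), 0.25e6)
  expect_equal(unname(t4$inoculum[c("SA", "AB", "BC")]), rep(0.25e6, 3))
  t2 <- treatment_design(c("PA", "AB"), focal = "PA")
  expect_equal(unname(t2$inoculum), c(2.5e5, 7.5e5))
  # monocultures are density-matched; non-focal subsets share equally
  tm <- treatment_design("PA", focal = "PA")
  expect_equal(unname(tm$inoculum), 1e6)
  tn <- treatment_design(c("SA", "AB"), focal = "PA")
  expect_equal(unname(tn$inoculum), c(5e5, 5e5))

  expect_error(treatment_design(character(0)), "non-empty")
  expect_error(treatment_design("PA", dilution_factor = 0), "dilution")
  expect_error(treatment_design("PA", duration = 10, transfer_interval = 3),
               "multiple")
})

test_that("noise-free generation reproduces the simulated truth exactly", {
  truth <- synthetic_truth(params = benchmark_community_params(), sigma = 0)
  trt <- treatment_design(c("PA", "AB"), focal = "PA", replicates = 2)
  dat <- generate_dataset(truth, list(trt), seed = 1)
  ref <- glvcomm:::truth_trajectory(truth, trt)
  for (k in 1:2) {
    dk <- dat[dat$replicate == k, ]
    got <- matrix(dk$density_cfu_ml[order(dk$day, match(dk$species, c("PA", "AB")))],
                  nrow = 2)
    expect_equal(got, unname(ref), tolerance = 1e-12)
  }
})

test_that("identical seeds give identical datasets and different seeds differ", {
  truth <- community_truth(sigma = 0.1)
  design <- generate_design(truth$params$species, phage_rule = "none",
                            replicates = 2)[c(1, 5, 11)]
  d1 <- generate_dataset(truth, design, seed = 42)
  d2 <- generate_dataset(truth, design, seed = 42)
  d3 <- generate_dataset(truth, design, seed = 43)
  expect_identical(d1, d2)
  expect_false(identical(d1$density_cfu_ml, d3$density_cfu_ml))
})

test_that("observations at or below the detection floor are recorded at the floor and flagged", {
  truth <- community_truth(sigma = 0.1)
  design <- generate_design(truth$params$species, phage_rule = "none",
                            replicates = 3)
  dat <- generate_dataset(truth, design, seed = 3)
  expect_true(all(dat$density_cfu_ml >= truth$floor))
  expect_true(all(dat$density_cfu_ml[dat$censored == 1] == truth$floor))
  expect_true(all(dat$density_cfu_ml[dat$censored == 0] > truth$floor))
  # the dominant-competitor truth drives losers below detection
  expect_gt(sum(dat$censored), 0)
})

test_that("the phage model reduces to plain gLV without phage and conversion", {
  truth <- synthetic_truth(params = benchmark_community_params(),
                           genotypes = list(WT = list(conversion = 0,
                                                      cost = 0.05)),
                           sigma = 0, initial_phage = 0)
  trt <- treatment_design(c("PA", "SA", "AB"), phage = TRUE, focal = "PA")
  days <- c(0, 1, 3, 7, 10)
  ph <- generate_phage_truth(truth, trt, times = days)
  p <- effective_params(truth, trt$species_subset)
  arr <- glvcomm:::glv_integrate(p, matrix(trt$inoculum, ncol = 1), days,
                                 "serial_transfer", 0.01, 1, "pre")
  for (j in seq_along(trt$species_subset)) {
    sp <- trt$species_subset[j]
    expect_equal(ph[[sp]], arr[, j, 1], tolerance = 1e-6)
  }
})

test_that("with only resistant hosts the phage titre decays as a pure exponential", {
  truth <- synthetic_truth(params = benchmark_community_params(), sigma = 0)
  trt <- treatment_design("PA", phage = TRUE, focal = "PA")
  tt <- seq(0, 5, by = 0.5)
  ph <- generate_phage_truth(truth, trt, times = tt, mode = "continuous",
                             initial_resistant_fraction = 1)
  expected <- truth$initial_phage * exp(-truth$phage$decay * tt)
  expect_equal(ph$phage_pfu_ml, expected, tolerance = 1e-6)
  expect_true(all(ph$resistant_fraction == 1))
})

test_that("default phage dynamics rise above the inoculum then fall after resistance sweeps", {
  truth <- community_truth()
  trt <- treatment_design(truth$params$species, phage = TRUE, focal = "PA")
  ph <- generate_phage_truth(truth, trt)
  expect_gt(max(ph$phage_pfu_ml), truth$initial_phage)
  i99 <- which(ph$resistant_fraction > 0.99)[1]
  expect_false(is.na(i99))
  tail_titre <- ph$phage_pfu_ml[i99:nrow(ph)]
  expect_true(all(diff(tail_titre) <= 1e-9 * max(tail_titre)))
})

test_that("the full fitting chain recovers off-diagonal coefficients from generated data", {
  truth <- synthetic_truth(params = benchmark_community_params(),
                           sigma = 0.05)
  sp <- truth$params$species
  pairs <- combn(sp, 2, simplify = FALSE)
  design <- lapply(pairs, function(pp) treatment_design(pp, focal = "PA"))
  errs <- c()
  for (s in 1:2) {
    dat <- generate_dataset(truth, design, seed = s)
    for (pp in pairs) {
      id <- paste0(paste(pp, collapse = "+"), "_nophage_WT")
      tp <- effective_params(truth, pp)
      f <- fit_interactions(dat[dat$treatment_id == id, ], r_fixed = tp$r,
                            n_starts = 2, seed = s,
                            mode = "serial_transfer")
      errs <- c(errs, rel_err(offdiag(f$beta), offdiag(tp$beta)))
    }
  }
  expect_lt(median(errs), 0.25)
})
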