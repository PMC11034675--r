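test_that("growth rates and self-limitation are recovered from clean logistic data", {
  r <- 2; K <- 1e9; N0 <- 1e6
  p <- glv_params(r = setNames(r, "PA"), beta = matrix(r / K))
  mono <- make_dataset(p, N0, days = 0:10, id = "PA_mono")
  g <- fit_growth_rates(mono)
  expect_lt(rel_err(g$r[["PA"]], r), 0.01)
  expect_lt(rel_err(g$beta_ii[["PA"]], r / K), 0.01)
  expect_false(g$weak_K[["PA"]])
  expect_false(g$degenerate[["PA"]])
})

test_that("exponential-phase-only data identify r but flag beta_ii as weak", {
  r <- 1.2; K <- 1e12; N0 <- 1e4    # never approaches the plateau in 10 d
  p <- glv_params(r = setNames(r, "X"), beta = matrix(r / K))
  mono <- make_dataset(p, N0, days = 0:10, id = "X_mono")
  g <- fit_growth_rates(mono)
  expect_lt(rel_err(g$r[["X"]], r), 0.01)
  expect_true(g$weak_K[["X"]])
})

test_that("flat monoculture series yield r near zero with a degeneracy diagnostic", {
  flat <- community_ts(data.frame(
    treatment_id = "F_mono", genotype = "WT", phage = 0L, replicate = 1L,
    day = rep(c(0, 1, 3, 7, 10), 1), species = "F",
    density_cfu_ml = rep(5e6, 5), censored = 0L))
  expect_warning(g <- fit_growth_rates(flat), "unidentifiable")
  expect_lt(g$r[["F"]], 0.05)
  expect_true(g$degenerate[["F"]])
})

test_that("entirely censored monoculture series are rejected", {
  cens <- community_ts(data.frame(
    treatment_id = "C_mono", genotype = "WT", phage = 0L, replicate = 1L,
    day = c(0, 1, 3, 7, 10), species = "C",
    density_cfu_ml = 100, censored = 1L))
  expect_error(fit_growth_rates(cens), "censored")
})

test_that("noise-free coculture data return the generating coefficients", {
  # 2-species benchmark pair, informative initial conditions
  p2 <- benchmark_pair_params()
  d2 <- make_dataset(p2, c(A = 1e6, B = 3e6), id = "A+B")
  f2 <- fit_interactions(d2, r_fixed = p2$r, n_starts = 4, seed = 1)
  expect_true(f2$converged)
  expect_lt(max(rel_err(f2$beta, p2$beta)), 0.02)

  # randomized 2-species truths (recovery-consistency property)
  for (s in 4:6) {
    p <- random_params(2, seed = s, fac_range = c(0.3, 0.9))
    d <- make_dataset(p, setNames(c(2e6, 5e5), p$species), id = "rand")
    f <- fit_interactions(d, r_fixed = p$r, n_starts = 4, seed = s)
    expect_lt(max(rel_err(f$beta, p$beta)), 0.02)
  }
})

test_that("noise-free 3-species data return the generating coefficients", {
  sp <- c("A", "B", "C")
  p3 <- glv_params(
    r = c(A = 2, B = 1.6, C = 1.8),
    beta = matrix(c(2e-9, 1.2e-9, 8e-10,
                    1.8e-9, 3.2e-9, 9e-10,
                    1.0e-9, 1.5e-9, 2.5e-9), 3, 3, byrow = TRUE,
                  dimnames = list(sp, sp)))
  d3 <- make_dataset(p3, c(A = 1e6, B = 3e6, C = 5e5), id = "A+B+C")
  f3 <- fit_interactions(d3, r_fixed = p3$r, n_starts = 4, seed = 2)
  expect_lt(max(rel_err(f3$beta, p3$beta)), 0.02)
})

test_that("true null interactions stay pinned at the non-negative bound", {
  sp <- c("A", "B")
  p <- glv_params(r = c(A = 2, B = 1.6),
                  beta = diag(c(2e-9, 3.2e-9)))
  dimnames(p$beta) <- list(sp, sp)
  d <- make_dataset(p, c(A = 1e6, B = 3e6), id = "null")
  f <- fit_interactions(d, r_fixed = p$r, n_starts = 4, seed = 3)
  expect_lt(max(offdiag(f$beta)), 1e-3 * min(diag(f$beta)))
})

test_that("the fitted optimum is invariant to replicate order", {
  p <- benchmark_pair_params()
  d <- make_dataset(p, c(A = 1e6, B = 3e6), sigma = 0.1, nrep = 4,
                    seed = 9, id = "perm")
  d2 <- d
  d2$replicate <- 5 - d2$replicate   # reverse replicate labels
  d2 <- d2[order(d2$replicate, d2$day, d2$species), ]
  f1 <- fit_interactions(d, r_fixed = p$r, n_starts = 3, seed = 1)
  f2 <- fit_interactions(d2, r_fixed = p$r, n_starts = 3, seed = 1)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("species with no uncensored observations are flagged unidentifiable", {
  p <- benchmark_pair_params()
  d <- make_dataset(p, c(A = 1e6, B = 3e6), id = "cens")
  d$censored[d$species == "B"] <- 1L
  f <- fit_interactions(d, r_fixed = p$r, n_starts = 2, seed = 1)
  expect_true("B" %in% f$unidentifiable)
})

test_that("recovery error degrades monotonically with measurement noise", {
  p <- benchmark_pair_params()
  med <- vapply(c(0, 0.05, 0.1, 0.2), function(sg) {
    errs <- unlist(lapply(1:4, function(s) {
      d <- make_dataset(p, c(A = 1e6, B = 3e6), sigma = sg, nrep = 6,
                        seed = 200 + s, id = "mc")
      f <- fit_interactions(d, r_fixed = p$r, n_starts = 3, seed = s)
      rel_err(offdiag(f$beta), offdiag(p$beta))
    }))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("matrix assembly averages per entry and respects strategy provenance", {
  mkfit <- function(sp, beta, phage = FALSE) {
    structure(list(context = list(species = sp, phage = phage,
                                  genotype = "WT"),
                   species = sp, beta = beta, objective = 0,
                   converged = TRUE, unidentifiable = character(0)),
              class = "glv_fit")
  }
  spp <- c("A", "B", "C")
  bAB <- matrix(c(1, 2, 3, 4) * 1e-9, 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  bAC <- matrix(c(1, 5, 6, 7) * 1e-9, 2, 2, byrow = TRUE,
                dimnames = list(c("A", "C"), c("A", "C")))
  bBC <- matrix(c(4, 8, 9, 7) * 1e-9, 2, 2, byrow = TRUE,
                dimnames = list(c("B", "C"), c("B", "C")))
  bT <- matrix(c(3, 2, 5, 3, 4, 8, 6, 9, 7) * 1e-9, 3, 3, byrow = TRUE,
               dimnames = list(spp, spp))
  fits <- list(mkfit(c("A", "B"), bAB), mkfit(c("A", "C"), bAC),
               mkfit(c("B", "C"), bBC), mkfit(spp, bT))

  # identical values across contexts collapse to that value
  m_pair <- assemble_matrix(fits, "pairwise_only", species = spp)
  expect_equal(m_pair$beta["A", "B"], 2e-9)

  # two contexts average arithmetically: pair gives 1e-9, triplet 3e-9
  m_avg <- assemble_matrix(fits, "average_pair_triplet", species = spp)
  expect_equal(m_avg$beta["A", "A"], mean(c(1e-9, 1e-9, 3e-9)))
  expect_equal(m_avg$beta["A", "B"], mean(c(2e-9, 2e-9)))

  # triplet_only excludes every pair context from provenance
  m_tri <- assemble_matrix(fits, "triplet_only", species = spp)
  provs <- unlist(lapply(m_tri$provenance, `[[`, "context"))
  expect_true(all(provs == "A+B+C|WT"))
  expect_equal(m_tri$beta, bT)

  # every entry equals the mean of its recorded provenance values
  for (key in names(m_avg$provenance)) {
    ij <- strsplit(key, "|", fixed = TRUE)[[1]]
    expect_equal(m_avg$beta[ij[1], ij[2]],
                 mean(m_avg$provenance[[key]]$value))
  }

  # an uncovered pair is reported
  expect_error(assemble_matrix(fits[1:2], "pairwise_only", species = spp),
               "uncovered")
})

test_that("held-out scoring reports log10 RMSE with exact simple cases", {
  p <- benchmark_pair_params()
  d <- make_dataset(p, c(A = 1e6, B = 3e6), id = "held")
  s0 <- predict_and_score(p, p$r, d)
  expect_lt(s0$rmse, 1e-6)

  # constant-offset case: zero-dynamics system whose prediction is the
  # (constant) day-0 state while the data sit a factor of 10 lower
  pz <- glv_params(r = c(A = 0, B = 0), beta = diag(c(1e-300, 1e-300)))
  dimnames(pz$beta) <- list(c("A", "B"), c("A", "B"))
  dz <- make_dataset(pz, c(A = 1e6, B = 2e6), id = "const")
  dz$density_cfu_ml[dz$day > 0] <- dz$density_cfu_ml[dz$day > 0] / 10
  s1 <- predict_and_score(pz, pz$r, dz)
  expect_equal(s1$rmse, 1.0, tolerance = 1e-6)

  dX <- d
  dX$species <- sub("^A$", "Z", dX$species)
  expect_error(predict_and_score(p, p$r, community_ts(dX)), "absent")
})
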