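test_that("glv_derivative matches the formula, its limits, and vanishes at zero density", {
  # exponential limit: negligible self-limitation
  p <- glv_params(r = 0.5, beta = matrix(1e-300))
  expect_equal(unname(glv_derivative(100, p)), 50)

  # logistic equilibrium
  r <- 2; K <- 5e8
  p2 <- glv_params(r = r, beta = matrix(r / K))
  expect_equal(unname(glv_derivative(K, p2)), 0)

  # direct arithmetic evaluation for a coupled pair
  p3 <- glv_params(r = c(1, 1),
                   beta = matrix(c(1e-9, 2e-9, 1e-9, 1e-9), 2, 2,
                                 byrow = TRUE))
  expect_equal(unname(glv_derivative(c(1e8, 1e8), p3)), c(7e7, 8e7))

  # zero density gives exactly zero rate even with positive r
  p4 <- glv_params(r = c(3, 1), beta = diag(c(1e-9, 1e-9)))
  expect_identical(unname(glv_derivative(c(0, 1e5), p4))[1], 0)

  expect_error(glv_derivative(c(1, 2, 3), p3), "3 species")
  expect_error(glv_derivative(c(-1, 1), p3), ">= 0")
})

test_that("parameter container enforces its invariants and round-trips via YAML", {
  expect_error(glv_params(r = c(1, 2), beta = matrix(1e-9)), "dimension")
  expect_error(glv_params(r = 1, beta = matrix(0)), "beta\\[i,i\\]")
  expect_error(glv_params(r = c(1, 1),
                          beta = matrix(c(1e-9, -1e-10, 0, 1e-9), 2, 2)),
               "signed")
  p <- glv_params(r = c(A = 1, B = 2),
                  beta = matrix(c(1e-9, -1e-10, 2e-10, 3e-9), 2, 2,
                                byrow = TRUE), signed = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_glv_params(p, path)
  q <- read_glv_params(path)
  expect_equal(q$r, p$r)
  expect_equal(q$beta, p$beta, tolerance = 1e-12)
  expect_true(q$signed)
})

test_that("monoculture simulation matches the analytic logistic solution", {
  set.seed(11)
  tt <- seq(0, 10, by = 0.25)
  for (i in 1:5) {
    r <- runif(1, 0.5, 3); K <- 10^runif(1, 7, 10); N0 <- 10^runif(1, 4, 7)
    p <- glv_params(r = r, beta = matrix(r / K))
    sim <- glv_simulate(p, N0, tt)
    ana <- K / (1 + (K / N0 - 1) * exp(-r * tt))
    expect_lt(max(abs(sim$density_cfu_ml - ana) / ana), 1e-6)
  }
})

test_that("zero dynamics leave the state constant", {
  p <- glv_params(r = c(0, 0), beta = diag(c(1e-300, 1e-300)))
  sim <- glv_simulate(p, c(1e5, 2e5), times = c(0, 2, 7))
  expect_equal(sim$density_cfu_ml,
               rep(c(1e5, 2e5), each = 3), tolerance = 1e-9)
})

test_that("serial transfers dilute by construction, with both sampling conventions", {
  r <- 2; K <- 1e9
  p <- glv_params(r = r, beta = matrix(r / K))
  tt <- c(0, 0.5, 1, 1.5, 2)
  post <- glv_simulate(p, 1e6, tt, mode = "serial_transfer",
                       dilution = 0.01, interval = 1)
  pre <- glv_simulate(p, 1e6, tt, mode = "serial_transfer",
                      dilution = 0.01, interval = 1,
                      transfer_sample = "pre")
  d_post <- post$density_cfu_ml
  d_pre <- pre$density_cfu_ml
  # at the transfer instant: post-sample = dilution x pre-sample
  expect_equal(d_post[3] / d_pre[3], 0.01, tolerance = 1e-6)
  # off-transfer samples agree between conventions
  expect_equal(d_post[c(1, 2, 4)], d_pre[c(1, 2, 4)], tolerance = 1e-6)
  # trajectory resumes from the diluted state
  expect_lt(d_post[4], d_pre[3])
})

test_that("densities stay non-negative and bounded for valid parameter sets", {
  for (s in 1:15) {
    n <- sample(2:4, 1)
    p <- random_params(n, seed = s)
    set.seed(s + 100)
    init <- 10^runif(n, 3, 8)
    sim <- glv_simulate(p, init, times = seq(0, 15, by = 0.5),
                        mode = if (s %% 2) "continuous" else "serial_transfer")
    expect_true(all(sim$density_cfu_ml >= 0))
    bound <- max(c(init, carrying_capacity(p))) * (1 + 1e-6) + 1e-3
    expect_true(all(sim$density_cfu_ml <= bound))
  }
})

test_that("relabelling species permutes the trajectory identically", {
  p <- random_params(3, seed = 7)
  init <- c(1e5, 3e6, 4e4)
  perm <- c(3, 1, 2)
  pp <- glv_params(r = p$r[perm], beta = p$beta[perm, perm],
                   species = p$species[perm])
  s1 <- glv_simulate(p, init, times = c(0, 1, 4, 9))
  s2 <- glv_simulate(pp, init[perm], times = c(0, 1, 4, 9))
  m1 <- matrix(s1$density_cfu_ml, ncol = 3,
               dimnames = list(NULL, p$species))
  m2 <- matrix(s2$density_cfu_ml, ncol = 3,
               dimnames = list(NULL, pp$species))
  expect_equal(m2[, p$species], m1, tolerance = 1e-10)
})

test_that("interior equilibria solve beta N* = r and match simulation when stable", {
  r <- 1.5; K <- 2e8
  p <- glv_params(r = r, beta = matrix(r / K))
  expect_equal(unname(interior_equilibrium(p)), K)

  # decoupled pair: independent carrying capacities
  p2 <- glv_params(r = c(A = 2, B = 1),
                   beta = diag(c(2e-9, 1e-8)))
  expect_equal(unname(interior_equilibrium(p2)), c(1e9, 1e8))

  # coexisting random pairs: long-horizon simulation converges to N*
  found <- 0
  for (s in 1:30) {
    p3 <- random_params(2, seed = s, fac_range = c(0.2, 0.9))
    eq <- interior_equilibrium(p3)
    if (is.null(eq)) next
    found <- found + 1
    sim <- glv_simulate(p3, eq * c(0.1, 2), times = c(0, 400))
    term <- sim$density_cfu_ml[sim$day == 400]
    expect_equal(term, unname(eq), tolerance = 1e-4)
    if (found >= 5) break
  }
  expect_gte(found, 3)

  # singular restricted matrix is flagged degenerate
  b <- matrix(c(1e-9, 1e-9, 1e-9, 1e-9), 2, 2)
  diag(b) <- 1e-9
  p4 <- glv_params(r = c(1, 2), beta = b)
  det4 <- interior_equilibrium(p4, detail = TRUE)
  expect_null(det4$equilibrium)
  expect_true(det4$degenerate)
})

test_that("tidy time series round-trip through CSV and validate their schema", {
  p <- random_params(2, seed = 3)
  sim <- glv_simulate(p, c(1e5, 1e5), times = c(0, 1, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_community_ts(sim, path)
  back <- read_community_ts(path)
  expect_s3_class(back, "community_ts")
  expect_equal(back$density_cfu_ml, sim$density_cfu_ml)
  expect_error(community_ts(data.frame(day = 1, species = "A")),
               "missing columns")
})
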