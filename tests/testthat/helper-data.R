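# Build a tidy dataset from an arbitrary parameter set and initial state:
# simulate, replicate, add lognormal noise, censor at the floor. Used by
# the fitting and recovery tests, which need tighter control over the
# initial state than the factorial generator offers.
make_dataset <- function(params, init, days = c(0, 1, 3, 7, 10),
                         sigma = 0, nrep = 1, seed = 1,
                         mode = "continuous", dilution = 0.01,
                         interval = 1, floor = 100, id = "test") {
  sim <- glv_simulate(params, init, times = days, mode = mode,
                      dilution = dilution, interval = interval,
                      transfer_sample = "pre")
  sp <- params$species
  base <- matrix(sim$density_cfu_ml, ncol = length(sp))
  colnames(base) <- sp
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrep), function(k) {
    noisy <- base * 10^matrix(rnorm(length(base), 0, sigma), nrow(base))
    cens <- noisy <= floor
    noisy[cens] <- floor
    data.frame(treatment_id = id, genotype = "WT", phage = 0L,
               replicate = k, day = rep(days, length(sp)),
               species = rep(sp, each = length(days)),
               density_cfu_ml = as.vector(noisy),
               censored = as.integer(as.vector(cens)),
               stringsAsFactors = FALSE)
  }))
  community_ts(out)
}

# Random small gLV system with carrying capacities around 1e8-1e9 and
# off-diagonal competition scaled relative to r_i / K_j.
random_params <- function(n = 2, seed = 1, fac_range = c(0.2, 1.8)) {
  set.seed(seed)
  r <- runif(n, 1, 8)
  K <- 10^runif(n, 7.5, 9.5)
  beta <- diag(r / K)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    beta[i, j] <- runif(1, fac_range[1], fac_range[2]) * r[i] / K[j]
  glv_params(r = setNames(r, paste0("sp", 1:n)), beta = beta)
}

offdiag <- function(m) m[row(m) != col(m)]

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
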