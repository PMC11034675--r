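#' Tidy community time series
#'
#' The package-wide tabular form for density time series: one row per
#' (treatment, replicate, day, species) with columns `treatment_id`,
#' `genotype`, `phage` (0/1), `replicate`, `day`, `species`,
#' `density_cfu_ml` and `censored` (0/1). Censored observations are values
#' at or below the detection floor (10^2 cfu/ml by default) and carry the
#' floor as their recorded density.
#'
#' @param df a data.frame with the columns above (missing metadata columns
#'   are filled with defaults).
#' @return The validated data.frame with class `community_ts`.
#' @export
community_ts <- function(df) {
  defaults <- list(treatment_id = "treatment", genotype = "WT",
                   phage = 0L, replicate = 1L, censored = 0L)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  needed <- c("treatment_id", "genotype", "phage", "replicate", "day",
              "species", "density_cfu_ml", "censored")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("community time series is missing columns: ", paste(miss, collapse = ", "))
  df <- df[needed]
  if (any(df$density_cfu_ml < 0, na.rm = TRUE))
    stop("densities must be >= 0")
  if (any(df$day < 0)) stop("sampling days must be >= 0")
  class(df) <- c("community_ts", "data.frame")
  df
}

#' @export
print.community_ts <- function(x, ...) {
  cat(sprintf("community time series: %d rows, %d treatment(s), species: %s, days: %s\n",
              nrow(x), length(unique(x$treatment_id)),
              paste(sort(unique(x$species)), collapse = ", "),
              paste(sort(unique(x$day)), collapse = ", ")))
  NextMethod()
}

#' Read or write tidy community time-series CSV
#'
#' @param x a [community_ts] data.frame.
#' @param path CSV file path.
#' @return `read_community_ts` returns a [community_ts];
#'   `write_community_ts` returns `path` invisibly.
#' @export
write_community_ts <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_ts
#' @export
read_community_ts <- function(path) {
  community_ts(read.csv(path, stringsAsFactors = FALSE))
}

# Reshape one treatment's tidy rows into aligned arrays used by the
# fitting code: obs[day, species, replicate] plus a censoring mask.
# All replicates must share the sampling days (checked).
ts_arrays <- function(data, species = NULL) {
  data <- as.data.frame(data)
  if (is.null(species)) species <- sort(unique(data$species))
  reps <- sort(unique(data$replicate))
  days <- sort(unique(data$day))
  obs <- array(NA_real_, dim = c(length(days), length(species), length(reps)),
               dimnames = list(NULL, species, NULL))
  cens <- array(FALSE, dim = dim(obs))
  for (k in seq_along(reps)) {
    dk <- data[data$replicate == reps[k], , drop = FALSE]
    for (j in seq_along(species)) {
      dj <- dk[dk$species == species[j], , drop = FALSE]
      idx <- match(days, dj$day)
      if (anyNA(idx))
        stop(sprintf("replicate %s of species %s does not share the sampling days",
                     reps[k], species[j]))
      obs[, j, k] <- dj$density_cfu_ml[idx]
      cens[, j, k] <- dj$censored[idx] > 0
    }
  }
  list(days = days, species = species, replicates = reps, obs = obs, cens = cens)
}
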