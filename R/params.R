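#' gLV parameter set
#'
#' Container for the parameters of an n-species generalized Lotka-Volterra
#' (gLV) system
#' \deqn{dN_i/dt = r_i N_i - \sum_j \beta_{ij} N_i N_j,}
#' where `r` holds the per-species maximal growth rates (day^-1) and
#' `beta[i, j]` the per-capita inhibitory effect of species `j` on species
#' `i` (ml cfu^-1 day^-1). The diagonal `beta[i, i]` sets self-limitation,
#' so species `i` alone grows logistically towards the carrying capacity
#' `K_i = r_i / beta[i, i]`.
#'
#' By default the inhibition-only convention is enforced (`beta >= 0`
#' everywhere, `beta[i, i] > 0`); set `signed = TRUE` to allow negative
#' (facilitative) off-diagonal entries.
#'
#' @param r numeric vector of growth rates, day^-1; finite.
#' @param beta numeric n x n matrix of interaction coefficients,
#'   ml cfu^-1 day^-1.
#' @param species character vector of species labels; defaults to
#'   `names(r)`, then to `dimnames(beta)`, then to `"sp1"..."spn"`.
#' @param signed if `TRUE`, off-diagonal coefficients may be negative
#'   (facilitation); the diagonal must remain positive in either case.
#' @return An object of class `glv_params` with elements `species`, `r`,
#'   `beta` and `signed`.
#' @examples
#' p <- glv_params(r = c(A = 1, B = 0.8),
#'                 beta = matrix(c(1e-9, 2e-10, 5e-10, 2e-9), 2, 2, byrow = TRUE))
#' carrying_capacity(p)
#' @export
glv_params <- function(r, beta, species = NULL, signed = FALSE) {
  beta <- as.matrix(beta)
  n <- length(r)
  if (nrow(beta) != n || ncol(beta) != n)
    stop(sprintf("dimension mismatch: %d growth rates but a %d x %d interaction matrix",
                 n, nrow(beta), ncol(beta)))
  if (!all(is.finite(r)))
    stop("growth rates must be finite")
  if (!all(is.finite(beta)))
    stop("interaction coefficients must be finite")
  if (is.null(species)) {
    species <- names(r)
    if (is.null(species)) species <- rownames(beta)
    if (is.null(species)) species <- paste0("sp", seq_len(n))
  }
  if (length(species) != n || anyDuplicated(species))
    stop("species labels must be unique and match the number of growth rates")
  if (any(diag(beta) <= 0))
    stop("self-limitation beta[i,i] must be > 0 for every species (finite carrying capacity)")
  if (!signed && any(beta < 0))
    stop("negative interaction coefficients require signed = TRUE (inhibition-only convention)")
  r <- as.numeric(r)
  names(r) <- species
  dimnames(beta) <- list(species, species)
  structure(list(species = species, r = r, beta = beta, signed = signed),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  cat(sprintf("gLV parameter set: %d species (%s)\n",
              length(x$species), paste(x$species, collapse = ", ")))
  cat("growth rates r (day^-1):\n")
  print(signif(x$r, 4))
  cat("interaction matrix beta (ml cfu^-1 day^-1), beta[i,j] = effect of j on i:\n")
  print(signif(x$beta, 4))
  invisible(x)
}

#' @rdname glv_params
#' @param params a `glv_params` object.
#' @export
n_species <- function(params) length(params$species)

#' Carrying capacities implied by a gLV parameter set
#'
#' Returns `r_i / beta[i, i]` per species, the monoculture logistic
#' plateau in cfu/ml.
#'
#' @param params a [glv_params] object.
#' @return Named numeric vector of carrying capacities.
#' @export
carrying_capacity <- function(params) params$r / diag(params$beta)

#' Restrict a gLV parameter set to a species subset
#'
#' Drops all species outside `species` and reorders the retained rows and
#' columns to the requested order. Used to derive the model of a
#' subcommunity from the full-community parameters.
#'
#' @param params a [glv_params] object.
#' @param species character vector of retained species labels (order kept).
#' @return A [glv_params] object on the subset.
#' @export
subset_params <- function(params, species) {
  missing <- setdiff(species, params$species)
  if (length(missing))
    stop("species not in parameter set: ", paste(missing, collapse = ", "))
  glv_params(r = params$r[species],
             beta = params$beta[species, species, drop = FALSE],
             species = species, signed = params$signed)
}

#' Read or write a gLV parameter set as YAML
#'
#' The on-disk form records the species order, the growth-rate vector and
#' the interaction matrix row by row, in plain text.
#'
#' @param params a [glv_params] object.
#' @param path file path.
#' @return `read_glv_params` returns a [glv_params] object;
#'   `write_glv_params` returns `path` invisibly.
#' @export
write_glv_params <- function(params, path) {
  doc <- list(species = as.list(params$species),
              r = as.list(unname(params$r)),
              beta = lapply(seq_len(n_species(params)),
                            function(i) as.list(unname(params$beta[i, ]))),
              signed = params$signed)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_glv_params
#' @export
read_glv_params <- function(path) {
  doc <- yaml::read_yaml(path)
  species <- unlist(doc$species)
  beta <- do.call(rbind, lapply(doc$beta, unlist))
  glv_params(r = unlist(doc$r), beta = beta, species = species,
             signed = isTRUE(doc$signed))
}
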