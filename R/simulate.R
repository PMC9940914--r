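#' @useDynLib sweepstakes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# evaluate expr under a locally-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a genealogy under a coalescent model
#'
#' Draws a single genealogy of `n` sampled lineages. Kingman with growth uses
#' the closed-form time change of the pairwise merger intensity
#' `exp(growth * t)`; Lambda-Beta and Durrett-Schweinsberg draw waiting times
#' from the total merger rate and merger sizes from the rate table; the diploid
#' Xi-Beta model assigns merger participants uniformly at random to four
#' parental chromosomes, each group merging simultaneously, with null events
#' (no group of two) thinned.
#'
#' @param model a [coal_model] specification.
#' @param n sample size (>= 2).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return An object of class `"genealogy"`: `n`, `times` (strictly increasing
#'   event times), `events` (per event, a list of merging groups of block ids;
#'   leaves are 1..n, internal blocks n+1, ...), `new_ids`, `tmrca`, `model`,
#'   and `seed`.
#' @export
simulate_genealogy <- function(model, n, seed = NULL) {
  stopifnot(is_coal_model(model), n >= 2)
  a <- model_cpp_args(model)
  g <- with_seed(seed, sim_genealogy_cpp(model_code(model), as.integer(n),
                                         a$alpha, a$beta, a$cpar, a$f))
  structure(list(n = g$n, times = g$times, events = g$events,
                 new_ids = g$new_ids, tmrca = g$tmrca, model = model,
                 seed = seed),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Coalescent genealogy: n =", x$n, "leaves,", length(x$times),
      "merger events, TMRCA =", signif(x$tmrca, 4), "\n")
  invisible(x)
}

#' Branch-length family-size spectrum of a genealogy
#'
#' Replays the event list and accumulates \eqn{B_i}, the total branch length
#' subtending exactly i of the n leaves, for i = 1..n-1.
#'
#' @param genealogy a `"genealogy"` object.
#' @return Numeric vector of length n-1.
#' @export
branch_spectrum <- function(genealogy) {
  stopifnot(inherits(genealogy, "genealogy"))
  n <- genealogy$n
  # leaf counts per block id
  size <- c(rep(1L, n), rep(NA_integer_, length(unlist(genealogy$new_ids))))
  alive <- seq_len(n)
  B <- numeric(n - 1L)
  t_prev <- 0
  for (e in seq_along(genealogy$times)) {
    dt <- genealogy$times[e] - t_prev
    t_prev <- genealogy$times[e]
    tab <- size[alive]
    for (s in tab) B[s] <- B[s] + dt
    groups <- genealogy$events[[e]]
    nid <- genealogy$new_ids[[e]]
    for (z in seq_along(groups)) {
      ids <- groups[[z]]
      size[nid[z]] <- sum(size[ids])
      alive <- c(setdiff(alive, ids), nid[z])
    }
  }
  B
}

#' Monte Carlo branch-length spectra
#'
#' Simulates `reps` independent genealogies and returns their family-size
#' branch-length spectra, the workhorse behind Monte Carlo expected spectra
#' and the fragment-ensemble generators.
#'
#' @inheritParams simulate_genealogy
#' @param reps number of replicate genealogies.
#' @return A list with `B` (`reps` by `n-1` matrix of branch lengths) and
#'   `tmrca` (length-`reps` vector).
#' @export
sim_branch_spectra <- function(model, n, reps, seed = NULL) {
  stopifnot(is_coal_model(model), n >= 2, reps >= 1)
  a <- model_cpp_args(model)
  m <- with_seed(seed, sim_spectra_cpp(model_code(model), as.integer(n),
                                       as.integer(reps), a$alpha, a$beta,
                                       a$cpar, a$f))
  list(B = m[, seq_len(n - 1L), drop = FALSE], tmrca = m[, n])
}

#' Drop mutations on a genealogy (infinite-sites model)
#'
#' Mutations fall on branches as a Poisson process with rate `theta / 2` per
#' unit branch length, so a branch subtending i leaves contributes
#' derived-allele class i. In expected mode the deterministic mean
#' \eqn{\xi_i = (\theta/2) B_i} is returned instead of a Poisson draw.
#'
#' @param x a `"genealogy"` object or a numeric branch-length spectrum
#'   \eqn{B_i} (length n-1).
#' @param theta population-scaled mutation rate (> 0; `theta = 0` yields the
#'   degenerate all-zero SFS).
#' @param expected if `TRUE`, return the expected SFS deterministically.
#' @param seed optional integer seed for the Poisson draw.
#' @return An [sfs()] object.
#' @export
sfs_from_genealogy <- function(x, theta, expected = FALSE, seed = NULL) {
  if (inherits(x, "genealogy")) x <- branch_spectrum(x)
  stopifnot(is.numeric(x), is.numeric(theta), length(theta) == 1L)
  if (theta < 0) stop("domain error: theta must be >= 0")
  mean_counts <- theta / 2 * x
  counts <- if (expected) mean_counts else
    with_seed(seed, stats::rpois(length(x), mean_counts))
  out <- sfs(counts, meta = list(theta = theta,
                                 mode = if (expected) "expected" else "poisson"))
  if (theta == 0) out$meta$degenerate <- TRUE
  out
}

# Monte Carlo mean expected-mutation SFS of a model: mean over replicates of
# theta/2 * B, returned normalized. The fast path for exact Lambda models uses
# the recursion instead.
model_phi <- function(model, n, reps = 10000L, seed = NULL, exact = NULL) {
  if (is.null(exact)) {
    exact <- (model$family == "ds") ||
      (model$family == "kingman" && model$growth == 0) ||
      (model$family == "beta" && model$growth == 0 && model$ploidy == "lambda")
  }
  if (exact) {
    e <- expected_sfs(model, n)
    return(e$phi)
  }
  sp <- sim_branch_spectra(model, n, reps, seed = seed)
  mB <- colMeans(sp$B)
  mB / sum(mB)
}
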