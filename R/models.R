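#' Coalescent model specifications
#'
#' Constructors for the model families compared by the package. Each returns a
#' lightweight parameter object of class `"coal_model"` accepted by
#' [simulate_genealogy()], [sim_branch_spectra()], [expected_sfs()] and
#' [fit_coalescent()].
#'
#' * `kingman_model(growth)`: the Kingman coalescent (only pairwise mergers),
#'   the no-sweepstakes null, with population-size-rescaled exponential growth
#'   rate `growth` >= 0 (0 = constant size).
#' * `beta_model(alpha, growth, ploidy)`: the Beta(2-alpha, alpha) coalescent
#'   family of random sweepstakes. `alpha` in \[1, 2\] controls the skewness of
#'   the offspring distribution (smaller alpha = larger jackpots; alpha = 2 is
#'   Kingman, alpha = 1 the Bolthausen-Sznitman boundary). `ploidy` selects the
#'   haploid Lambda version (`"lambda"`) or the diploid Xi version (`"xi"`) in
#'   which merger participants are assigned to the four parental chromosomes of
#'   a large reproduction event. Growth enters as a deterministic time change
#'   with intensity factor `exp((alpha - 1) * growth * t)`, so its impact
#'   vanishes at maximal skew (alpha = 1) and the alpha = 2 limit recovers the
#'   standard Kingman exponential-growth model.
#' * `ds_model(c, f_genomewide)`: the Durrett-Schweinsberg coalescent of
#'   recurrent selective sweeps, with compound parameter `c >= 0` (the rate of
#'   sweeps times squared selection coefficient over recombination rate; the
#'   density of selection per map unit). `c = 0` recovers Kingman. A fraction
#'   `f_genomewide` of sweeps captures all lineages regardless of
#'   recombination (chromosome-wide sweeps or bottlenecks).
#'
#' @param growth exponential growth rate (>= 0, per coalescent time unit).
#' @param alpha reproductive-skew parameter in \[1, 2\].
#' @param ploidy `"lambda"` (haploid) or `"xi"` (diploid, four-way mergers).
#' @param c compound sweep parameter (>= 0).
#' @param f_genomewide fraction of sweeps in \[0, 1\] that capture lineages
#'   regardless of recombination.
#' @return A `"coal_model"` object.
#' @examples
#' kingman_model()
#' beta_model(alpha = 1.16, ploidy = "xi")
#' ds_model(c = 8.25)
#' @name coal_model
NULL

#' @rdname coal_model
#' @export
kingman_model <- function(growth = 0) {
  stopifnot(is.numeric(growth), length(growth) == 1L, growth >= 0)
  structure(list(family = "kingman", growth = growth),
            class = c("kingman_model", "coal_model"))
}

#' @rdname coal_model
#' @export
beta_model <- function(alpha, growth = 0, ploidy = c("lambda", "xi")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(growth), length(growth) == 1L, growth >= 0)
  if (alpha < 1 || alpha > 2)
    stop("domain error: alpha must lie in [1, 2]")
  structure(list(family = "beta", alpha = alpha, growth = growth,
                 ploidy = ploidy),
            class = c("beta_model", "coal_model"))
}

#' @rdname coal_model
#' @export
ds_model <- function(c = 0, f_genomewide = 0) {
  stopifnot(is.numeric(c), length(c) == 1L,
            is.numeric(f_genomewide), length(f_genomewide) == 1L)
  if (c < 0) stop("domain error: c must be >= 0")
  if (f_genomewide < 0 || f_genomewide > 1)
    stop("domain error: f_genomewide must lie in [0, 1]")
  structure(list(family = "ds", c = c, f_genomewide = f_genomewide),
            class = c("ds_model", "coal_model"))
}

is_coal_model <- function(x) inherits(x, "coal_model")

#' @export
print.coal_model <- function(x, ...) {
  desc <- switch(x$family,
    kingman = sprintf("Kingman coalescent (growth = %g)", x$growth),
    beta = sprintf("%s-Beta(2-a, a) coalescent (alpha = %g, growth = %g)",
                   if (x$ploidy == "xi") "diploid Xi" else "haploid Lambda",
                   x$alpha, x$growth),
    ds = sprintf("Durrett-Schweinsberg coalescent (c = %g, f_genomewide = %g)",
                 x$c, x$f_genomewide))
  cat(desc, "\n")
  invisible(x)
}

# integer model code shared with the C++ simulators
model_code <- function(model) {
  switch(model$family,
         kingman = 0L,
         beta = if (model$ploidy == "xi") 2L else 1L,
         ds = 3L)
}

model_cpp_args <- function(model) {
  list(alpha = if (model$family == "beta") model$alpha else 2.0,
       beta = if (model$family == "ds") 0.0 else model$growth,
       cpar = if (model$family == "ds") model$c else 0.0,
       f = if (model$family == "ds") model$f_genomewide else 0.0)
}
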