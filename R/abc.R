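#' Logit-normalized SFS summary statistic
#'
#' The summary statistic used for model fitting: the logit transform of the
#' normalized site-frequency spectrum over the unmasked, nonzero classes.
#' Invariant to scaling of the counts.
#'
#' @param x an [sfs()], `sfs_norm` or `expected_sfs` object.
#' @param support optional logical vector restricting the classes used (e.g.
#'   the common support of an observed spectrum); the spectrum is
#'   renormalized over it.
#' @return Named numeric vector of logit frequencies, with the class indices
#'   as names.
#' @export
summary_statistic <- function(x, support = NULL) {
  nz <- as_sfs_norm(x)
  supp <- nz$support
  if (!is.null(support)) supp <- supp & support
  if (sum(supp) < 2L)
    stop("summary statistic needs at least 2 unmasked classes")
  phi <- nz$phi[supp] / sum(nz$phi[supp])
  stats::setNames(logit(phi), which(supp))
}

#' Uniform prior box
#'
#' @param ... named length-2 numeric vectors `c(lo, hi)` with `lo < hi`, e.g.
#'   `prior_box(alpha = c(1, 2))`. Defaults used by [fit_coalescent()] are
#'   alpha in (1, 2), growth in (0, 50), c in (0, 50).
#' @return Object of class `"prior_box"`.
#' @export
prior_box <- function(...) {
  b <- list(...)
  if (length(b) == 0L || is.null(names(b)) || any(!nzchar(names(b))))
    stop("prior_box() needs named bounds, e.g. prior_box(alpha = c(1, 2))")
  for (nm in names(b)) {
    v <- b[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] >= v[2])
      stop("bounds for '", nm, "' must be c(lo, hi) with lo < hi")
  }
  structure(b, class = "prior_box")
}

prior_sample <- function(prior) {
  vapply(prior, function(v) stats::runif(1, v[1], v[2]), numeric(1))
}

prior_contains <- function(prior, theta) {
  all(mapply(function(v, x) x >= v[1] && x <= v[2], prior, theta))
}

#' ABC-MCMC configuration
#'
#' @param target_rate target acceptance rate of the adaptive proposal scaling
#'   (default 0.10).
#' @param tolerance absolute tolerance on the Euclidean summary distance; if
#'   `NULL` (default) it is set to the `pilot_quantile` quantile of distances
#'   from a `pilot`-draw prior-predictive pilot run and then held fixed.
#' @param chain_length total chain length including burn-in.
#' @param burn_in number of initial iterations discarded by summaries.
#' @param replicates simulation replicates per proposal for Monte Carlo
#'   simulators (default 10,000 single-locus replicates).
#' @param pilot number of prior draws in the pilot run.
#' @param pilot_quantile quantile of pilot distances used as tolerance.
#' @param adapt_decay adaptation weight decay exponent: iteration t uses
#'   weight t^(-adapt_decay) (default 2/3).
#' @param init_scale initial proposal standard deviations as a fraction of
#'   each prior range (default 0.1).
#' @param seed optional integer seed for the whole run.
#' @return List of class `"abc_config"`.
#' @export
abc_config <- function(target_rate = 0.10, tolerance = NULL,
                       chain_length = 6000L, burn_in = 1000L,
                       replicates = 10000L, pilot = 1000L,
                       pilot_quantile = 0.05, adapt_decay = 2 / 3,
                       init_scale = 0.1, seed = NULL) {
  stopifnot(target_rate > 0, target_rate < 1,
            chain_length > burn_in, burn_in >= 0)
  structure(list(target_rate = target_rate, tolerance = tolerance,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 replicates = as.integer(replicates),
                 pilot = as.integer(pilot), pilot_quantile = pilot_quantile,
                 adapt_decay = adapt_decay, init_scale = init_scale,
                 seed = seed),
            class = "abc_config")
}

#' Adaptive ABC-MCMC sampler
#'
#' Metropolis chain on the model parameters in which likelihood evaluation is
#' replaced by simulation: a proposal (Gaussian, symmetric) is accepted iff it
#' lies in the prior box and the Euclidean distance between the simulated and
#' observed summary statistics is within the tolerance. The global proposal
#' scale is adapted on the log scale towards the target acceptance rate with
#' decaying weight t^(-adapt_decay), so the realized post-burn-in acceptance
#' rate settles near the target (10% by default).
#'
#' The tolerance, unless supplied, is fixed to the `pilot_quantile` quantile
#' of summary distances from a prior-predictive pilot run; the chain starts
#' from the pilot draw with the smallest distance.
#'
#' @param observed_summary numeric summary vector of the observed data (see
#'   [summary_statistic()]).
#' @param simulator function mapping a named parameter vector to a summary
#'   vector of the same length (typically the mean of `replicates`
#'   simulations, or a deterministic expected-SFS summary).
#' @param prior a [prior_box()].
#' @param config an [abc_config()].
#' @return Object of class `"posterior_sample"`: `draws` (matrix, post
#'   burn-in states), `full_draws`, `accepted` (indicator trace),
#'   `distances`, `acceptance_rate` (post burn-in), `tolerance`,
#'   `pilot_quantiles`, `scale_trace`, `burn_in`, `prior`, `config`.
#' @export
abc_mcmc <- function(observed_summary, simulator, prior, config = abc_config()) {
  stopifnot(inherits(prior, "prior_box"), inherits(config, "abc_config"))
  with_seed(config$seed, {
    p <- length(prior)
    pnames <- names(prior)
    dist_fn <- function(sim) sqrt(sum((sim - observed_summary)^2))

    # prior-predictive pilot: tolerance and starting point
    pilot_theta <- matrix(NA_real_, config$pilot, p,
                          dimnames = list(NULL, pnames))
    pilot_dist <- numeric(config$pilot)
    for (i in seq_len(config$pilot)) {
      th <- prior_sample(prior)
      pilot_theta[i, ] <- th
      pilot_dist[i] <- dist_fn(simulator(th))
    }
    qs <- stats::quantile(pilot_dist, c(0.01, 0.05, 0.1, 0.25, 0.5))
    tol <- if (is.null(config$tolerance))
      stats::quantile(pilot_dist, config$pilot_quantile) else config$tolerance

    theta <- pilot_theta[which.min(pilot_dist), ]
    cur_dist <- min(pilot_dist)
    base_sd <- vapply(prior, function(v) config$init_scale * (v[2] - v[1]),
                      numeric(1))
    log_s <- 0

    L <- config$chain_length
    draws <- matrix(NA_real_, L, p, dimnames = list(NULL, pnames))
    accepted <- logical(L)
    distances <- rep(NA_real_, L)
    scale_trace <- numeric(L)
    n_acc_burn <- 0L

    for (t in seq_len(L)) {
      prop <- theta + exp(log_s) * base_sd * stats::rnorm(p)
      acc <- FALSE
      if (prior_contains(prior, prop)) {
        d <- dist_fn(simulator(prop))
        distances[t] <- d
        if (d <= tol) {
          theta <- prop
          cur_dist <- d
          acc <- TRUE
        }
      }
      accepted[t] <- acc
      if (t <= config$burn_in && acc) n_acc_burn <- n_acc_burn + 1L
      draws[t, ] <- theta
      log_s <- log_s + t^(-config$adapt_decay) *
        (as.numeric(acc) - config$target_rate)
      scale_trace[t] <- exp(log_s)
    }
    if (config$burn_in > 0L && n_acc_burn == 0L)
      stop("no acceptances during burn-in: the tolerance (", signif(tol, 4),
           ") may be too small; pilot distance quantiles (1/5/10/25/50%): ",
           paste(signif(qs, 4), collapse = ", "))

    post <- (config$burn_in + 1L):L
    structure(list(draws = draws[post, , drop = FALSE], full_draws = draws,
                   accepted = accepted, distances = distances,
                   acceptance_rate = mean(accepted[post]),
                   tolerance = unname(tol), pilot_quantiles = qs,
                   scale_trace = scale_trace, burn_in = config$burn_in,
                   prior = prior, config = config),
              class = "posterior_sample")
  })
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("ABC-MCMC posterior sample:", nrow(x$draws), "post burn-in draws,",
      sprintf("acceptance rate %.1f%%, tolerance %.4g\n",
              100 * x$acceptance_rate, x$tolerance))
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' Posterior location summaries
#'
#' Mean, median and mode of each marginal posterior. The mode is the argmax
#' of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) evaluated on a 512-point grid spanning the prior range,
#' restricted to the span of the draws. With fewer than 30 draws the mode is
#' omitted with a warning.
#'
#' @param sample a `"posterior_sample"`, or a numeric matrix/vector of draws.
#' @param prior optional [prior_box()] giving the grid range per parameter.
#' @param grid_n KDE grid size (default 512).
#' @return Data frame of class `"posterior_summary"` with one row per
#'   parameter: `mean`, `median`, `mode`, `bandwidth`.
#' @export
posterior_summaries <- function(sample, prior = NULL, grid_n = 512L) {
  if (inherits(sample, "posterior_sample")) {
    if (is.null(prior)) prior <- sample$prior
    draws <- sample$draws
  } else {
    draws <- as.matrix(sample)
  }
  out <- do.call(rbind, lapply(seq_len(ncol(draws)), function(j) {
    v <- draws[, j]
    nm <- colnames(draws)[j]
    if (is.null(nm)) nm <- paste0("param", j)
    rng <- if (!is.null(prior) && nm %in% names(prior)) prior[[nm]] else range(v)
    mode <- NA_real_
    bw <- NA_real_
    if (length(v) < 30L) {
      warning("fewer than 30 draws: mode omitted for ", nm)
    } else if (stats::sd(v) == 0) {
      mode <- v[1]
    } else {
      den <- stats::density(v, bw = "nrd0", n = grid_n,
                            from = rng[1], to = rng[2])
      keep <- den$x >= min(v) & den$x <= max(v)
      mode <- den$x[keep][which.max(den$y[keep])]
      bw <- den$bw
    }
    data.frame(parameter = nm, mean = mean(v), median = stats::median(v),
               mode = mode, bandwidth = bw)
  }))
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Export posterior draws as CSV
#'
#' Writes the full trace (iteration, parameters, accepted, distance).
#'
#' @param x a `"posterior_sample"`.
#' @param path output file.
#' @export
write_posterior <- function(x, path) {
  stopifnot(inherits(x, "posterior_sample"))
  df <- data.frame(iteration = seq_len(nrow(x$full_draws)), x$full_draws,
                   accepted = x$accepted, distance = x$distances)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
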