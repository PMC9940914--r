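#' Fit a coalescent model to an observed site-frequency spectrum
#'
#' The central fitting front end. The observed SFS is reduced to its
#' logit-normalized summary statistic and compared with candidate model
#' spectra, either by grid search (deterministic where the exact expected-SFS
#' recursion applies) or by adaptive ABC-MCMC ([abc_mcmc()]). Supported
#' families:
#'
#' * `"kingman"`: no sweepstakes; one parameter, the exponential growth rate
#'   (growth = 0 uses the exact recursion, growth > 0 a Monte Carlo mean of
#'   replicate genealogies).
#' * `"beta"`: random sweepstakes, Beta(2-alpha, alpha) coalescent; parameter
#'   alpha (optionally jointly with growth). The haploid Lambda version has an
#'   exact expected SFS; the diploid Xi version uses Monte Carlo means.
#' * `"ds"`: selective sweepstakes, Durrett-Schweinsberg coalescent;
#'   parameter c, exact expected SFS.
#'
#' The fit score is the squared Euclidean distance (residual sum of squares)
#' between logit-normalized spectra over the observed support, which is
#' invariant to scaling of the observed counts.
#'
#' @param observed an [sfs()] (or `sfs_norm`) object; masked classes are
#'   excluded from the fit.
#' @param family model family to fit.
#' @param method `"grid"` (default) or `"abc"`.
#' @param grid named list of parameter grids for the grid method (defaults:
#'   growth `seq(0, 10, 0.5)`; alpha `seq(1.01, 1.99, 0.01)`; c
#'   `seq(0.05, 20, 0.05)`).
#' @param prior a [prior_box()] for the ABC method (defaults: alpha (1, 2),
#'   growth (0, 50), c (0, 50)).
#' @param config an [abc_config()] for the ABC method.
#' @param ploidy for the beta family, `"lambda"` (haploid, default) or
#'   `"xi"` (diploid).
#' @param estimate_growth for the beta family, fit (alpha, growth) jointly.
#' @param simulator `"exact"` for the deterministic expected-SFS path (where
#'   available), `"mc"` for the Monte Carlo mean of `replicates` single-locus
#'   genealogies.
#' @param replicates Monte Carlo replicates per candidate spectrum.
#' @param seed optional integer seed controlling all randomness of the fit.
#' @return An object of class `"coal_fit"` with components `family`, `method`,
#'   `model` (best-fit [coal_model]), `coefficients`, `score`, `expected`
#'   (normalized expected SFS at the best fit), `observed`, `S`, `posterior`
#'   (for ABC: the sample and its [posterior_summaries()]), `grid` (for grid
#'   search: parameters and distances), `seed`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`, `simulate`.
#' @examples
#' obs <- sfs_from_genealogy(expected_sfs(ds_model(c = 5), 20)$branch_lengths,
#'                           theta = 2, expected = TRUE)
#' fit <- fit_coalescent(obs, "ds", grid = list(c = seq(0.5, 10, 0.5)))
#' coef(fit)
#' @export
fit_coalescent <- function(observed, family = c("kingman", "beta", "ds"),
                           method = c("grid", "abc"), grid = NULL,
                           prior = NULL, config = abc_config(),
                           ploidy = c("lambda", "xi"),
                           estimate_growth = FALSE,
                           simulator = c("exact", "mc"),
                           replicates = 10000L, seed = NULL) {
  family <- match.arg(family)
  method <- match.arg(method)
  ploidy <- match.arg(ploidy)
  simulator <- match.arg(simulator)
  obs_norm <- as_sfs_norm(observed)
  n <- obs_norm$n
  S <- if (is_sfs(observed)) sum(observed$counts[observed$mask]) else NULL
  supp <- obs_norm$support
  s_obs <- summary_statistic(obs_norm)

  make_model <- function(th) {
    switch(family,
           kingman = kingman_model(growth = unname(th[["growth"]])),
           beta = beta_model(alpha = unname(th[["alpha"]]),
                             growth = if ("growth" %in% names(th))
                               unname(th[["growth"]]) else 0,
                             ploidy = ploidy),
           ds = ds_model(c = unname(th[["c"]])))
  }
  needs_mc <- function(model) {
    model$family == "kingman" && model$growth > 0 ||
      model$family == "beta" && (model$growth > 0 || model$ploidy == "xi")
  }
  curve_seed <- if (is.null(seed)) NULL else seed + 1L
  model_summary <- function(th) {
    model <- make_model(th)
    use_mc <- needs_mc(model) || simulator == "mc"
    phi <- model_phi(model, n, reps = replicates, seed = curve_seed,
                     exact = !use_mc)
    ph <- phi[supp]
    if (any(ph <= 0)) return(rep(Inf, sum(supp)))
    logit(ph / sum(ph))
  }

  if (method == "grid") {
    if (is.null(grid)) {
      grid <- switch(family,
                     kingman = list(growth = seq(0, 10, by = 0.5)),
                     beta = list(alpha = seq(1.01, 1.99, by = 0.01)),
                     ds = list(c = seq(0.05, 20, by = 0.05)))
    }
    pts <- expand.grid(grid)
    dist2 <- vapply(seq_len(nrow(pts)), function(i) {
      s <- model_summary(unlist(pts[i, , drop = FALSE]))
      sum((s - s_obs)^2)
    }, numeric(1))
    best <- which.min(dist2)
    coefs <- unlist(pts[best, , drop = FALSE])
    names(coefs) <- names(grid)
    score <- dist2[best]
    posterior <- NULL
    grid_out <- cbind(pts, distance2 = dist2)
  } else {
    if (is.null(prior)) {
      prior <- switch(family,
                      kingman = prior_box(growth = c(0, 50)),
                      beta = if (estimate_growth)
                        prior_box(alpha = c(1, 2), growth = c(0, 50))
                      else prior_box(alpha = c(1, 2)),
                      ds = prior_box(c = c(0, 50)))
    }
    if (is.null(config$seed)) config$seed <- seed
    sim_fn <- function(th) model_summary(th)
    sample <- abc_mcmc(s_obs, sim_fn, prior, config)
    summ <- posterior_summaries(sample)
    coefs <- stats::setNames(ifelse(is.na(summ$mode), summ$median, summ$mode),
                             summ$parameter)
    score <- sum((model_summary(coefs) - s_obs)^2)
    posterior <- list(sample = sample, summary = summ)
    grid_out <- NULL
  }

  best_model <- make_model(coefs)
  phi_hat <- model_phi(best_model, n, reps = replicates, seed = curve_seed,
                       exact = !(needs_mc(best_model) || simulator == "mc"))
  expected <- structure(list(n = n, phi = phi_hat, support = phi_hat > 0,
                             meta = list(fitted = TRUE)),
                        class = "sfs_norm")
  structure(list(family = family, method = method, model = best_model,
                 coefficients = coefs, score = unname(score),
                 expected = expected, observed = observed, S = S,
                 posterior = posterior, grid = grid_out, seed = seed,
                 call = match.call()),
            class = "coal_fit")
}

#' @export
print.coal_fit <- function(x, ...) {
  cat("Coalescent model fit (", x$family, " family, ", x$method,
      " method)\n", sep = "")
  print(x$model)
  cat("Logit-scale residual sum of squares:", signif(x$score, 5), "\n")
  invisible(x)
}

#' @export
coef.coal_fit <- function(object, ...) object$coefficients

#' @export
summary.coal_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$posterior)) {
    cat("\nPosterior summaries:\n")
    print(object$posterior$summary)
    cat(sprintf("Realized acceptance rate: %.1f%% (tolerance %.4g)\n",
                100 * object$posterior$sample$acceptance_rate,
                object$posterior$sample$tolerance))
  }
  r <- stats::residuals(object)
  cat(sprintf("\nResiduals: %d classes, %d with 95%% band excluding zero\n",
              nrow(r), sum(r$lo95 > 0 | r$hi95 < 0)))
  invisible(object)
}

#' @export
residuals.coal_fit <- function(object, ...) {
  log_odds_residuals(object$observed, object$expected, S = object$S)
}

#' @export
predict.coal_fit <- function(object, type = c("phi", "counts"), S = NULL, ...) {
  type <- match.arg(type)
  if (type == "phi") return(object$expected)
  if (is.null(S)) S <- object$S
  if (is.null(S)) stop("S required to predict counts")
  sfs(object$expected$phi * S, n = object$expected$n,
      meta = list(fitted = TRUE))
}

#' @export
simulate.coal_fit <- function(object, nsim = 1, seed = NULL, theta = 1, ...) {
  generate_fragment_ensemble(object$model, n = object$expected$n,
                             theta = theta, n_fragments = nsim, seed = seed)
}

#' @export
plot.coal_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  obs <- as_sfs_norm(x$observed)
  supp <- obs$support & x$expected$support
  cls <- which(supp)
  graphics::plot(cls, obs$phi[supp], log = "y", pch = 16,
                 xlab = "derived-allele class", ylab = "normalized frequency",
                 main = paste(x$family, "fit"), ...)
  graphics::lines(cls, x$expected$phi[supp], col = 2, lwd = 2)
  r <- stats::residuals(x)
  graphics::plot(r$class, r$residual, type = "h",
                 xlab = "derived-allele class", ylab = "log-odds residual",
                 main = "residuals")
  graphics::polygon(c(r$class, rev(r$class)),
                    c(r$hi99 - r$residual, rev(r$residual - r$hi99)),
                    col = grDevices::grey(0.9), border = NA)
  graphics::polygon(c(r$class, rev(r$class)),
                    c(r$hi95 - r$residual, rev(r$residual - r$hi95)),
                    col = grDevices::grey(0.8), border = NA)
  graphics::segments(r$class, 0, r$class, r$residual, col = 4)
  graphics::abline(h = 0, col = 2, lty = 2)
  invisible(x)
}
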