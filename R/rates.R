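#' Lambda-coalescent merger rate tables
#'
#' For a Lambda-coalescent, `lambda[b, k]` is the rate at which a fixed
#' k-tuple out of b ancestral lineages merges. The families implemented here:
#'
#' * Beta(2-alpha, alpha): \eqn{\lambda_{b,k} = B(k-\alpha, b-k+\alpha) /
#'   B(2-\alpha, \alpha)} with `B` the Beta function; `alpha = 2` is treated as
#'   the Kingman limit (\eqn{\lambda_{b,2} = 1}, all larger mergers 0) and
#'   `alpha = 1` is the Bolthausen-Sznitman coalescent.
#' * Durrett-Schweinsberg: \eqn{\Lambda(dy) = \delta_0(dy) + c\,y\,dy}, i.e.
#'   \eqn{\lambda_{b,k} = 1\{k = 2\} + c\,(k-1)!\,(b-k)!/b!}; `c = 0` recovers
#'   the Kingman table.
#'
#' Computation is on the log-gamma scale for numerical stability. The tables
#' satisfy the Lambda-coalescent consistency recursion
#' \eqn{\lambda_{b,k} = \lambda_{b+1,k} + \lambda_{b+1,k+1}}, see
#' [check_rate_consistency()].
#'
#' @param alpha skew parameter in \[1, 2\].
#' @param c compound sweep parameter >= 0.
#' @param n maximum number of lineages.
#' @return An object of class `"merger_rates"`: a list with `n`, `lambda`
#'   (an n-by-n matrix, entry \[b, k\] valid for 2 <= k <= b, `NA` elsewhere),
#'   and `model` metadata.
#' @examples
#' r <- beta_merger_rates(1.5, 10)
#' r$lambda[3, 2:3]
#' @name merger_rates
NULL

new_merger_rates <- function(n, lambda, model) {
  structure(list(n = as.integer(n), lambda = lambda, model = model),
            class = "merger_rates")
}

#' @rdname merger_rates
#' @export
beta_merger_rates <- function(alpha, n) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, n >= 2)
  if (alpha < 1 || alpha > 2) stop("domain error: alpha must lie in [1, 2]")
  n <- as.integer(n)
  if (alpha == 2) return(kingman_merger_rates(n))
  lam <- matrix(NA_real_, n, n)
  lB0 <- lbeta(2 - alpha, alpha)
  for (b in 2:n) {
    k <- 2:b
    lam[b, k] <- exp(lbeta(k - alpha, b - k + alpha) - lB0)
  }
  new_merger_rates(n, lam, list(family = "beta", alpha = alpha))
}

#' @rdname merger_rates
#' @export
ds_merger_rates <- function(c, n) {
  stopifnot(is.numeric(c), length(c) == 1L, n >= 2)
  if (c < 0) stop("domain error: c must be >= 0")
  n <- as.integer(n)
  lam <- matrix(NA_real_, n, n)
  for (b in 2:n) {
    k <- 2:b
    lam[b, k] <- as.numeric(k == 2) + c * exp(lbeta(k, b - k + 1))
  }
  new_merger_rates(n, lam, list(family = "ds", c = c))
}

#' @rdname merger_rates
#' @export
kingman_merger_rates <- function(n) {
  stopifnot(n >= 2)
  n <- as.integer(n)
  lam <- matrix(NA_real_, n, n)
  for (b in 2:n) {
    lam[b, 2:b] <- c(1, rep(0, b - 2L))
  }
  new_merger_rates(n, lam, list(family = "kingman"))
}

#' @export
print.merger_rates <- function(x, ...) {
  cat("Lambda-coalescent merger rates (", x$model$family,
      "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Check the Lambda-coalescent consistency recursion
#'
#' Verifies \eqn{\lambda_{b,k} = \lambda_{b+1,k} + \lambda_{b+1,k+1}} for all
#' 2 <= k <= b <= n-1 and returns the maximum absolute violation.
#'
#' @param rates a `"merger_rates"` table.
#' @export
check_rate_consistency <- function(rates) {
  stopifnot(inherits(rates, "merger_rates"))
  lam <- rates$lambda
  worst <- 0
  for (b in 2:(rates$n - 1L)) {
    k <- 2:b
    worst <- max(worst, abs(lam[b, k] - lam[b + 1L, k] - lam[b + 1L, k + 1L]))
  }
  worst
}

# total merger rate q_b and weights w[b, k] = choose(b, k) * lambda_{b, k}
rate_weights <- function(rates) {
  n <- rates$n
  w <- matrix(0, n, n)
  for (b in 2:n) {
    k <- 2:b
    w[b, k] <- choose(b, k) * rates$lambda[b, k]
  }
  list(w = w, q = rowSums(w))
}

#' Exact expected site-frequency spectrum of a Lambda-coalescent
#'
#' Computes the expected branch lengths \eqn{E[B_i]} subtending
#' `i = 1, ..., n-1` of `n` leaves by a first-step recursion on the
#' block-counting chain: from `b` exchangeable blocks a k-merger occurs with
#' probability \eqn{\binom{b}{k}\lambda_{b,k}/q_b} after a mean holding time
#' \eqn{1/q_b} (with \eqn{q_b = \sum_k \binom{b}{k}\lambda_{b,k}}), and by
#' sampling consistency the post-merger process is a Lambda-coalescent on
#' `b - k + 1` exchangeable blocks whose branch classes map back to leaf
#' classes through the (k, 1, ..., 1) block sizes. Under the infinite-sites
#' model the expected SFS is \eqn{E[\xi_i] = (\theta/2) E[B_i]}, and the
#' normalized spectrum is \eqn{\phi_i = E[B_i] / \sum_j E[B_j]}.
#'
#' Deterministic, polynomial in n (n = 200 is feasible). For the Kingman
#' table this reproduces the closed form \eqn{E[B_i] = 2/i}.
#'
#' @param x a `"merger_rates"` table, or a [coal_model] for which exact rates
#'   exist (growth-free Kingman, haploid Lambda-Beta, or DS).
#' @param n sample size; defaults to the table size.
#' @return An object of class `"expected_sfs"`: list with `n`,
#'   `branch_lengths` (\eqn{E[B_i]}), and `phi` (normalized spectrum).
#' @examples
#' e <- expected_sfs(kingman_merger_rates(4))
#' e$phi  # (6/11, 3/11, 2/11)
#' @export
expected_sfs <- function(x, n = NULL) {
  if (is_coal_model(x)) {
    if (is.null(n)) stop("n must be given when x is a model specification")
    x <- exact_rates_for_model(x, n)
  }
  stopifnot(inherits(x, "merger_rates"))
  if (is.null(n)) n <- x$n
  n <- as.integer(n)
  if (n < 2L || n > x$n) stop("n must lie in 2..", x$n)
  rw <- rate_weights(x)
  E <- vector("list", n)
  E[[1L]] <- numeric(0)
  for (m in 2:n) {
    q <- rw$q[m]
    if (!is.finite(q) || q <= 0) stop("inconsistent rate table: q_", m, " <= 0")
    Em <- numeric(m - 1L)
    Em[1L] <- m / q
    for (k in 2:m) {
      pk <- rw$w[m, k] / q
      if (pk == 0) next
      mm <- m - k + 1L
      if (mm >= 2L) {
        Esub <- E[[mm]]
        j <- seq_len(mm - 1L)
        Em[j] <- Em[j] + pk * ((mm - j) / mm) * Esub
        Em[j + k - 1L] <- Em[j + k - 1L] + pk * (j / mm) * Esub
      }
    }
    E[[m]] <- Em
  }
  EB <- E[[n]]
  structure(list(n = n, branch_lengths = EB, phi = EB / sum(EB),
                 model = x$model),
            class = "expected_sfs")
}

exact_rates_for_model <- function(model, n) {
  if (model$family == "kingman") {
    if (model$growth != 0)
      stop("exact expected SFS is only available without growth; ",
           "use sim_branch_spectra() for growth models")
    return(kingman_merger_rates(n))
  }
  if (model$family == "beta") {
    if (model$growth != 0 || model$ploidy == "xi")
      stop("exact expected SFS is available for the haploid Lambda-Beta ",
           "model without growth; use sim_branch_spectra() otherwise")
    return(beta_merger_rates(model$alpha, n))
  }
  ds_merger_rates(model$c, n)
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat("Exact expected SFS (", x$model$family, "), n = ", x$n, "\n", sep = "")
  print(stats::setNames(round(x$phi, 4), seq_len(x$n - 1L)))
  invisible(x)
}
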