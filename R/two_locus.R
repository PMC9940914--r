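#' Two-locus extension of the Durrett-Schweinsberg model (two samples)
#'
#' Simulates paired coalescence times (T_A, T_B) of two loci for two sampled
#' sequences under recurrent selective sweeps, and summarizes the decay of
#' their correlation (a pairwise linkage-disequilibrium proxy) with map
#' distance. Background dynamics are the standard two-locus ancestral process:
#' pairwise coalescence at rate 1 and recombination at rate d/2 per lineage
#' carrying both loci, d the scaled map distance. Sweeps hit a uniform
#' position on a window around the loci; each locus copy is captured with
#' probability decaying exponentially in its distance from the sweep site
#' (one shared uniform per lineage per sweep, so at d = 0 both loci are
#' captured together and T_A = T_B exactly). A fraction `f_genomewide` of
#' sweeps captures everything regardless of recombination, which makes the
#' correlation plateau at a positive background level as d grows. The sweep
#' arrival rate is calibrated so the per-locus pairwise sweep coalescence rate
#' matches the single-locus DS rate c * B(2, 1) = c/2.
#'
#' @param params a [ds_model()] specification (`c`, `f_genomewide`).
#' @param distances nonnegative map distances (scaled recombination units).
#' @param n number of sampled sequences; only `n = 2` is supported.
#' @param replicates Monte Carlo replicates per distance.
#' @param margin half-width of the sweep-position window beyond the loci.
#' @param conf confidence level of the Monte Carlo interval on the
#'   correlation (Fisher z).
#' @param seed optional integer seed.
#' @return A data frame of class `"ld_curve"` with columns `distance`, `corr`,
#'   `lo`, `hi`, `mean_TA`, `mean_TB`.
#' @examples
#' \donttest{
#' two_locus_ds(ds_model(c = 8, f_genomewide = 0.1),
#'              distances = c(0, 1, 5), replicates = 2000, seed = 1)
#' }
#' @export
two_locus_ds <- function(params, distances, n = 2L, replicates = 10000L,
                         margin = 10, conf = 0.95, seed = NULL) {
  stopifnot(inherits(params, "ds_model"))
  if (n != 2L)
    stop("unsupported configuration: the two-locus extension is restricted ",
         "to n = 2 sampled sequences")
  if (any(distances < 0)) stop("domain error: distances must be >= 0")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  with_seed(seed, {
    rows <- lapply(distances, function(d) {
      sim <- sim_two_locus_cpp(params$c, params$f_genomewide, d,
                               as.integer(replicates), margin)
      if (stats::sd(sim$TA) == 0 || stats::sd(sim$TB) == 0 ||
          all(sim$TA == sim$TB)) {
        rho <- if (all(sim$TA == sim$TB)) 1 else NA_real_
        lo <- hi <- rho
      } else {
        rho <- stats::cor(sim$TA, sim$TB)
        # Fisher z interval
        zeta <- atanh(min(rho, 1 - 1e-12))
        sez <- 1 / sqrt(replicates - 3)
        lo <- tanh(zeta - z * sez)
        hi <- tanh(zeta + z * sez)
      }
      data.frame(distance = d, corr = rho, lo = lo, hi = hi,
                 mean_TA = mean(sim$TA), mean_TB = mean(sim$TB))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("ld_curve", "data.frame")
    out
  })
}

#' Export an LD-decay curve as CSV
#'
#' @param x an `"ld_curve"` data frame from [two_locus_ds()].
#' @param path output file.
#' @export
write_ld_curve <- function(x, path) {
  stopifnot(inherits(x, "ld_curve"))
  utils::write.csv(x[, c("distance", "corr", "lo", "hi")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Sweep-timescale arithmetic
#'
#' In a population of size N, a selective sweep starting from one individual
#' whose fit descendants number k per generation fixes after log(N)
#' generations once k^(log N) = N, i.e. the required per-generation
#' reproductive excess is k = N^(1/log N) = e, regardless of N.
#'
#' @param N population size (> 1).
#' @return List with `N`, `duration_generations` (= log N) and
#'   `reproductive_excess` (= e).
#' @examples
#' sweep_arithmetic(1e9)  # duration 20.7 generations, excess 2.71
#' @export
sweep_arithmetic <- function(N) {
  stopifnot(is.numeric(N))
  if (any(N <= 1)) stop("domain error: N must be > 1")
  list(N = N, duration_generations = log(N),
       reproductive_excess = N^(1 / log(N)))
}
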