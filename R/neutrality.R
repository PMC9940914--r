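#' Theta estimators from an unfolded site-frequency spectrum
#'
#' Classical moment estimators of the population-scaled mutation rate:
#' Watterson's \eqn{\theta_W = S / a_1} with \eqn{a_1 = \sum_{i<n} 1/i},
#' pairwise diversity \eqn{\theta_\pi = \sum i(n-i)\xi_i / \binom{n}{2}},
#' \eqn{\theta_H = \sum i^2 \xi_i / \binom{n}{2}}, and
#' \eqn{\theta_L = \sum i \xi_i / (n-1)}.
#'
#' @param x an [sfs()] object.
#' @return List with `n`, `S`, `theta_W`, `theta_pi`, `theta_H`, `theta_L`,
#'   and `singletons`.
#' @export
theta_estimators <- function(x) {
  stopifnot(is_sfs(x))
  n <- x$n
  xi <- x$counts
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  S <- sum(xi)
  list(n = n, S = S,
       theta_W = S / a1,
       theta_pi = sum(i * (n - i) * xi) / choose(n, 2),
       theta_H = sum(i^2 * xi) / choose(n, 2),
       theta_L = sum(i * xi) / (n - 1),
       singletons = xi[1L])
}

#' SFS-based neutrality test statistics
#'
#' Computes Tajima's D, Fu and Li's D, the variance-normalized Fay and Wu's H,
#' and Zeng's E from an unfolded SFS, using the variance estimators of the
#' original publications (Watterson-based plug-ins for theta and theta^2).
#' Under Kingman-coalescent neutrality at equilibrium each statistic has
#' expectation approximately 0; selective sweeps drive Tajima's D and Fay and
#' Wu's H negative.
#'
#' * Tajima's D = (theta_pi - theta_W) / sqrt(e1 S + e2 S(S-1))
#' * Fu & Li's D = (S - a1 xi_1) / sqrt(uD S + vD S^2), xi_1 the derived
#'   singleton count
#' * Fay & Wu's H (normalized) = (theta_pi - theta_L) / sqrt(Var), with the
#'   unnormalized variant theta_pi - theta_H available via
#'   `normalized = FALSE`
#' * Zeng's E = (theta_L - theta_W) / sqrt(Var)
#'
#' @param x an [sfs()] object with n >= 4.
#' @param normalized report Fay and Wu's H in variance-normalized form
#'   (default); otherwise the unnormalized theta_pi - theta_H.
#' @return List of class `"neutrality_stats"` with `Tajima_D`, `FuLi_D`,
#'   `FayWu_H`, `Zeng_E`, `S`, `n`, and `defined` (FALSE with all statistics
#'   `NA` when S = 0 or a variance estimate is non-positive).
#' @export
neutrality_suite <- function(x, normalized = TRUE) {
  stopifnot(is_sfs(x))
  n <- x$n
  if (n < 4L) stop("neutrality statistics require n >= 4")
  th <- theta_estimators(x)
  S <- th$S
  out <- list(Tajima_D = NA_real_, FuLi_D = NA_real_, FayWu_H = NA_real_,
              Zeng_E = NA_real_, S = S, n = n, defined = FALSE)
  class(out) <- "neutrality_stats"
  if (S <= 0) return(out)

  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  # Tajima (1989)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  varD <- e1 * S + e2 * S * (S - 1)
  # Fu & Li (1993)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  varFL <- uD * S + vD * S^2
  # Zeng, Fu, Shi & Wu (2006): theta and theta^2 plug-ins
  th1 <- S / a1
  th2 <- S * (S - 1) / (a1^2 + a2)
  bn1 <- a2 + 1 / n^2  # sum_{i=1}^{n} 1/i^2
  varH <- (n - 2) / (6 * (n - 1)) * th1 +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th2
  varE <- (n / (2 * (n - 1)) - 1 / a1) * th1 +
    (a2 / a1^2 + 2 * (n / (n - 1))^2 * a2 -
       2 * (n * a2 - n + 1) / ((n - 1) * a1) - (3 * n + 1) / (n - 1)) * th2

  if (varD > 0) out$Tajima_D <- (th$theta_pi - th$theta_W) / sqrt(varD)
  if (varFL > 0) out$FuLi_D <- (S - a1 * th$singletons) / sqrt(varFL)
  if (normalized) {
    if (varH > 0) out$FayWu_H <- (th$theta_pi - th$theta_L) / sqrt(varH)
  } else {
    out$FayWu_H <- th$theta_pi - th$theta_H
  }
  if (varE > 0) out$Zeng_E <- (th$theta_L - th$theta_W) / sqrt(varE)
  out$defined <- !anyNA(out[c("Tajima_D", "FuLi_D", "FayWu_H", "Zeng_E")])
  out
}

#' @export
print.neutrality_stats <- function(x, ...) {
  cat(sprintf(
    "Neutrality statistics (n = %d, S = %g):\n  Tajima's D = %.4f  Fu & Li's D = %.4f\n  Fay & Wu's H = %.4f  Zeng's E = %.4f\n",
    x$n, x$S, x$Tajima_D, x$FuLi_D, x$FayWu_H, x$Zeng_E))
  invisible(x)
}

#' Sliding-window neutrality scan
#'
#' Assembles a per-window SFS from a per-site table of derived-allele counts
#' and evaluates the neutrality suite in each window. Windows are half-open
#' `[start, start + window_bp)`, tile `[min(position), max(position)]`, and
#' advance by `step_bp`; empty windows are retained as undefined rows.
#'
#' @param site_table data frame with columns `position` (sorted, 0-based) and
#'   `derived_count` (in 1..n-1).
#' @param n sample size (number of lineages).
#' @param window_bp window size in bp (default 100 kb).
#' @param step_bp step size in bp (default 20 kb).
#' @return Data frame with one row per window: `start`, `end`, `S`,
#'   `Tajima_D`, `FuLi_D`, `FayWu_H`, `Zeng_E`.
#' @export
windowed_scan <- function(site_table, n, window_bp = 100000, step_bp = 20000) {
  stopifnot(is.data.frame(site_table),
            all(c("position", "derived_count") %in% names(site_table)))
  if (is.unsorted(site_table$position))
    stop("site table must be sorted by position")
  dc <- site_table$derived_count
  if (any(dc < 1 | dc > n - 1))
    stop("derived counts must lie in 1..n-1")
  starts <- seq(min(site_table$position), max(site_table$position),
                by = step_bp)
  rows <- lapply(starts, function(s) {
    in_win <- site_table$position >= s & site_table$position < s + window_bp
    cnt <- tabulate(dc[in_win], nbins = n - 1L)
    if (sum(cnt) == 0) {
      data.frame(start = s, end = s + window_bp, S = 0, Tajima_D = NA_real_,
                 FuLi_D = NA_real_, FayWu_H = NA_real_, Zeng_E = NA_real_)
    } else {
      st <- neutrality_suite(sfs(cnt, n = n))
      data.frame(start = s, end = s + window_bp, S = st$S,
                 Tajima_D = st$Tajima_D, FuLi_D = st$FuLi_D,
                 FayWu_H = st$FayWu_H, Zeng_E = st$Zeng_E)
    }
  })
  do.call(rbind, rows)
}

#' McDonald-Kreitman test and neutrality index
#'
#' For counts of non-synonymous and synonymous polymorphic (Pn, Ps) and fixed
#' (Dn, Ds) sites, computes the neutrality index NI = (Pn/Ps)/(Dn/Ds), its
#' negative natural log (positive under positive selection, negative under
#' purifying/background selection), the adaptive-substitution proportion
#' alpha = 1 - NI, and the two-sided p-value of Fisher's exact test on the
#' 2x2 table. Tables with a zero in Ps, Dn, or Ds have an undefined NI and
#' are flagged rather than silently corrected; `haldane = TRUE` applies the
#' +0.5 correction to every cell first.
#'
#' @param Pn,Ps,Dn,Ds nonnegative integer counts (vectorized), or `Pn` may be
#'   a data frame with columns `Pn`, `Ps`, `Dn`, `Ds` (and optionally `gene`).
#' @param haldane apply the +0.5 correction to all cells (default off).
#' @return Data frame of class `"mk_result"` with columns `Pn`, `Ps`, `Dn`,
#'   `Ds`, `NI`, `neg_log_NI`, `alpha`, `p`, `defined`.
#' @examples
#' mk_test(2, 4, 4, 4)  # NI = 0.5, -log NI = 0.693, alpha = 0.5
#' @export
mk_test <- function(Pn, Ps = NULL, Dn = NULL, Ds = NULL, haldane = FALSE) {
  if (is.data.frame(Pn)) {
    df <- Pn
    stopifnot(all(c("Pn", "Ps", "Dn", "Ds") %in% names(df)))
    gene <- if ("gene" %in% names(df)) df$gene else seq_len(nrow(df))
    Pn <- df$Pn; Ps <- df$Ps; Dn <- df$Dn; Ds <- df$Ds
  } else {
    gene <- seq_along(Pn)
  }
  if (any(c(Pn, Ps, Dn, Ds) < 0)) stop("MK counts must be nonnegative")
  p <- mapply(function(pn, ps, dn, ds) {
    stats::fisher.test(matrix(c(pn, ps, dn, ds), 2, byrow = TRUE))$p.value
  }, Pn, Ps, Dn, Ds)
  defined <- Ps > 0 & Dn > 0 & Ds > 0 & Pn > 0
  aPn <- Pn + 0.5 * haldane; aPs <- Ps + 0.5 * haldane
  aDn <- Dn + 0.5 * haldane; aDs <- Ds + 0.5 * haldane
  NI <- ifelse(defined | haldane, (aPn / aPs) / (aDn / aDs), NA_real_)
  out <- data.frame(gene = gene, Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds,
                    NI = NI, neg_log_NI = -log(NI), alpha = 1 - NI,
                    p = p, defined = defined | haldane)
  class(out) <- c("mk_result", "data.frame")
  out
}

#' Genome-wide summary of McDonald-Kreitman results
#'
#' Mean and median of -log NI over the defined tables, with the implied
#' adaptive-substitution proportions alpha = 1 - exp(-m).
#'
#' @param x an `"mk_result"` data frame from [mk_test()].
#' @return List with `mean_neg_log_NI`, `median_neg_log_NI`, `alpha_mean`,
#'   `alpha_median`, `n_defined`, `n_total`.
#' @export
mk_summary <- function(x) {
  stopifnot(inherits(x, "mk_result"))
  v <- x$neg_log_NI[x$defined & is.finite(x$neg_log_NI)]
  m <- mean(v)
  md <- stats::median(v)
  list(mean_neg_log_NI = m, median_neg_log_NI = md,
       alpha_mean = 1 - exp(-m), alpha_median = 1 - exp(-md),
       n_defined = length(v), n_total = nrow(x))
}

#' Expected sequence divergence between taxa
#'
#' Converts a p-distance (nucleotide substitutions per site) and a genome
#' length into the implied number of differing sites, reported in mega-sites.
#' `divergence_from_rate()` gives the same quantity from a substitution rate
#' per year and a divergence time.
#'
#' @param p_distance proportion of nucleotide differences per site, in
#'   \[0, 1\].
#' @param genome_length_bp genome length in bp (> 0).
#' @return List with `site_difference` and `megasites`
#'   (= site_difference / 1e6).
#' @examples
#' expected_divergence(0.005, 685e6)$megasites  # 3.4 M sites
#' @export
expected_divergence <- function(p_distance, genome_length_bp) {
  if (any(p_distance < 0 | p_distance > 1))
    stop("domain error: p_distance must lie in [0, 1]")
  if (any(genome_length_bp <= 0))
    stop("domain error: genome length must be > 0")
  d <- p_distance * genome_length_bp
  list(site_difference = d, megasites = d / 1e6)
}

#' @rdname expected_divergence
#' @param rate_per_year substitutions per year across the genome.
#' @param years divergence time in years.
#' @export
divergence_from_rate <- function(rate_per_year, years) {
  if (any(rate_per_year < 0) || any(years < 0))
    stop("domain error: rate and time must be >= 0")
  d <- rate_per_year * years
  list(site_difference = d, megasites = d / 1e6)
}
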