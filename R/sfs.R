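#' Site-frequency spectrum objects
#'
#' An `sfs` object holds the unfolded site-frequency spectrum of a sample of
#' `n` lineages: counts \eqn{\xi_i} of polymorphic sites at which exactly
#' `i = 1, ..., n-1` of the sampled lineages carry the derived allele
#' (ancestral state known, e.g. outgroup-polarized). Classes can be masked
#' (e.g. by [truncate_sfs()]); masked classes are excluded from all downstream
#' statistics and normalization renormalizes over the retained support.
#'
#' @param counts numeric vector of n-1 nonnegative class counts.
#' @param n sample size (number of lineages); defaults to `length(counts) + 1`.
#' @param mask logical vector of length n-1, `TRUE` for retained classes.
#' @param meta free-form provenance list (source file, model, seed, ...).
#' @return An object of class `"sfs"` with fields `n`, `counts`, `mask`, `meta`.
#' @examples
#' x <- sfs(c(10, 5, 2, 1))
#' normalize_sfs(x)$phi
#' @export
sfs <- function(counts, n = length(counts) + 1L, mask = NULL, meta = list()) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("sample size n must be an integer >= 2")
  counts <- as.numeric(counts)
  if (length(counts) != n - 1L)
    stop("length of counts (", length(counts), ") must equal n - 1 = ", n - 1L)
  if (anyNA(counts) || any(counts < 0))
    stop("all SFS counts must be nonnegative and non-missing")
  if (is.null(mask)) mask <- rep(TRUE, n - 1L)
  if (!is.logical(mask) || length(mask) != n - 1L)
    stop("mask must be a logical vector of length n - 1")
  structure(list(n = n, counts = counts, mask = mask, meta = meta),
            class = "sfs")
}

is_sfs <- function(x) inherits(x, "sfs")

#' @export
print.sfs <- function(x, ...) {
  cat("Unfolded site-frequency spectrum: n =", x$n, "lineages,",
      sum(x$counts[x$mask]), "segregating sites")
  if (!all(x$mask)) cat(" (", sum(!x$mask), " classes masked)", sep = "")
  cat("\n")
  print(stats::setNames(x$counts, seq_len(x$n - 1L)))
  invisible(x)
}

#' Read a site-frequency spectrum from disk
#'
#' Supports the flat whitespace-separated dialect written by ANGSD's realSFS
#' (a single data line of n+1 reals for allele-count classes 0..n; the
#' monomorphic classes 0 and n are read but dropped) and a two-column CSV
#' `class,count` with classes 1..n-1.
#'
#' @param path file to read.
#' @param dialect `"realSFS"` (flat, default) or `"csv"`.
#' @return An [sfs()] object.
#' @export
read_sfs <- function(path, dialect = c("realSFS", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "realSFS") {
    lines <- readLines(path, warn = FALSE)
    nonempty <- which(nzchar(trimws(lines)))
    if (length(nonempty) == 0L) stop("malformed SFS file (no data line): ", path)
    ln <- nonempty[1L]
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("parse error in '%s': non-numeric token '%s' at line %d, field %d",
                   path, tok[bad], ln, bad))
    }
    if (length(vals) < 3L)
      stop("malformed SFS: flat dialect needs at least 3 values (classes 0..n), got ",
           length(vals))
    n <- length(vals) - 1L
    sfs(vals[2:n], n = n, meta = list(source = path, dialect = "realSFS"))
  } else {
    df <- utils::read.csv(path)
    if (!all(c("class", "count") %in% names(df)))
      stop("csv dialect requires columns 'class' and 'count' in ", path)
    if (!is.numeric(df$class) || !is.numeric(df$count))
      stop(sprintf("parse error in '%s': non-numeric 'class' or 'count' column", path))
    n <- as.integer(max(df$class)) + 1L
    if (!setequal(df$class, seq_len(n - 1L)))
      stop("csv dialect requires one row per class 1..n-1 in ", path)
    counts <- df$count[order(df$class)]
    sfs(counts, n = n, meta = list(source = path, dialect = "csv"))
  }
}

#' Write a site-frequency spectrum to disk
#'
#' The realSFS flat dialect writes one line of n+1 values with zeros in the
#' monomorphic classes 0 and n, so `read_sfs(write_sfs(x))` round-trips.
#'
#' @param x an [sfs()] object.
#' @param path output file.
#' @param dialect `"realSFS"` or `"csv"`.
#' @export
write_sfs <- function(x, path, dialect = c("realSFS", "csv")) {
  stopifnot(is_sfs(x))
  dialect <- match.arg(dialect)
  if (dialect == "realSFS") {
    writeLines(paste(c(0, x$counts, 0), collapse = " "), path)
  } else {
    utils::write.csv(data.frame(class = seq_len(x$n - 1L), count = x$counts),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Normalize a site-frequency spectrum
#'
#' Returns the normalized spectrum \eqn{\phi_i = \xi_i / \sum_j \xi_j}, where
#' the sum runs over the unmasked classes. The result carries a support mask
#' that additionally excludes zero classes (so logit transforms stay finite).
#' Normalizing an already-normalized spectrum is the identity.
#'
#' @param x an [sfs()] or `sfs_norm` object.
#' @return An object of class `"sfs_norm"` with fields `n`, `phi` (NA at
#'   masked classes, summing to 1 over the retained support), and `support`.
#' @export
normalize_sfs <- function(x) {
  if (inherits(x, "sfs_norm")) return(x)
  stopifnot(is_sfs(x))
  tot <- sum(x$counts[x$mask])
  if (tot <= 0) stop("degenerate input: all-zero SFS cannot be normalized")
  phi <- ifelse(x$mask, x$counts / tot, NA_real_)
  structure(list(n = x$n, phi = phi,
                 support = x$mask & x$counts > 0, meta = x$meta),
            class = "sfs_norm")
}

#' @export
print.sfs_norm <- function(x, ...) {
  cat("Normalized SFS: n =", x$n, "lineages,", sum(x$support),
      "supported classes\n")
  print(stats::setNames(round(x$phi, 4), seq_len(x$n - 1L)))
  invisible(x)
}

#' Logit (log-odds) transform
#'
#' `log(p / (1 - p))` with natural logarithm, the transform applied to both
#' normalized site frequencies and derived-allele frequencies i/n. Values of
#' exactly 0 or 1 are returned as `NA` (such classes are masked rather than
#' propagating infinities into summaries).
#'
#' @param p numeric vector in `[0, 1]`.
#' @export
logit <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("logit requires p in [0, 1]")
  out <- log(p / (1 - p))
  out[!is.na(p) & (p == 0 | p == 1)] <- NA_real_
  out
}

#' Truncate a site-frequency spectrum
#'
#' Masks the classes most sensitive to SNP misorientation and low-level
#' ancestral introgression: singletons, doubletons, and the n-1 and n-2
#' classes. Counts are unchanged; downstream normalization renormalizes over
#' the retained support. Idempotent.
#'
#' @param x an [sfs()] object with n >= 6.
#' @export
truncate_sfs <- function(x) {
  stopifnot(is_sfs(x))
  if (x$n < 6L)
    stop("empty support: truncation requires n >= 6 (got n = ", x$n, ")")
  mask <- x$mask
  mask[c(1L, 2L, x$n - 2L, x$n - 1L)] <- FALSE
  sfs(x$counts, n = x$n, mask = mask, meta = x$meta)
}

#' Classwise mean of an ensemble of spectra
#'
#' The mean of a fragment ensemble is used as the observed SFS for
#' model fitting (single-locus coalescent replicates average the same way).
#'
#' @param ensemble a list of [sfs()] objects sharing the same n.
#' @export
ensemble_mean_sfs <- function(ensemble) {
  stopifnot(is.list(ensemble), length(ensemble) >= 1L)
  ns <- vapply(ensemble, function(s) s$n, integer(1))
  if (length(unique(ns)) != 1L)
    stop("shape error: ensemble members have mixed sample sizes")
  cts <- vapply(ensemble, function(s) s$counts, numeric(ns[1] - 1L))
  cts <- if (is.matrix(cts)) rowMeans(cts) else mean(cts)
  masks <- vapply(ensemble, function(s) s$mask, logical(ns[1] - 1L))
  mask <- if (is.matrix(masks)) apply(masks, 1, all) else all(masks)
  sfs(cts, n = ns[1], mask = mask,
      meta = list(ensemble_size = length(ensemble)))
}

#' Bootstrap error bands for an ensemble-mean spectrum
#'
#' Resamples the fragment ensemble with replacement `B` times, takes the
#' classwise mean of each resample, and reports the per-class standard
#' deviation of the resampled means together with mean +/- 2 SD bands.
#'
#' @param ensemble list of [sfs()] objects sharing n (size >= 2 for nonzero
#'   bands; a singleton ensemble warns and yields zero-width bands).
#' @param B number of bootstrap replicates (default 100).
#' @return A list of class `"sfs_boot"`: `mean` (an [sfs()]), `sd`, `lower`,
#'   `upper` (per-class numeric vectors), `B`.
#' @export
bootstrap_sfs <- function(ensemble, B = 100L) {
  stopifnot(is.list(ensemble), length(ensemble) >= 1L, B >= 1L)
  if (length(ensemble) == 1L)
    warning("singleton ensemble: bootstrap bands have zero width")
  m <- ensemble_mean_sfs(ensemble)
  K <- length(ensemble)
  cts <- vapply(ensemble, function(s) s$counts, numeric(m$n - 1L))
  cts <- matrix(cts, nrow = m$n - 1L)
  boot_means <- vapply(seq_len(B), function(b) {
    idx <- sample.int(K, K, replace = TRUE)
    rowMeans(cts[, idx, drop = FALSE])
  }, numeric(m$n - 1L))
  boot_means <- matrix(boot_means, nrow = m$n - 1L)
  sd_b <- apply(boot_means, 1, stats::sd)
  if (K == 1L) sd_b[] <- 0
  structure(list(mean = m, sd = sd_b,
                 lower = m$counts - 2 * sd_b, upper = m$counts + 2 * sd_b,
                 B = as.integer(B)),
            class = "sfs_boot")
}

#' Log-odds residual profile of an observed against an expected spectrum
#'
#' Per-class residuals \eqn{r_i = \mathrm{logit}(\phi_{obs,i}) -
#' \mathrm{logit}(\phi_{exp,i})}, the difference of observed and expected
#' logit site frequencies. The standard error uses the binomial-proportion
#' delta method on the observed proportion with `S` segregating sites,
#' \eqn{SE_i = \sqrt{1/(S\phi_i) + 1/(S(1-\phi_i))}}, and 95%/99% bands are
#' \eqn{\pm 1.96\,SE} and \eqn{\pm 2.576\,SE}. Classes outside the common
#' support (masked or zero in either spectrum) are excluded; both spectra are
#' renormalized over the common support before the transform.
#'
#' @param obs observed spectrum ([sfs()] or `sfs_norm`).
#' @param expected expected spectrum ([sfs()], `sfs_norm`, or `expected_sfs`).
#' @param S total number of segregating sites; defaults to the observed total
#'   count when `obs` carries counts.
#' @return A data frame of class `"residual_profile"` with columns `class`,
#'   `freq` (i/n), `phi_obs`, `phi_exp`, `residual`, `se`, `lo95`, `hi95`,
#'   `lo99`, `hi99`.
#' @export
log_odds_residuals <- function(obs, expected, S = NULL) {
  if (is.null(S) && is_sfs(obs)) S <- sum(obs$counts[obs$mask])
  obs_n <- as_sfs_norm(obs)
  exp_n <- as_sfs_norm(expected)
  if (obs_n$n != exp_n$n) stop("observed and expected spectra differ in n")
  if (is.null(S) || S <= 0) stop("S (total segregating sites) must be > 0")
  supp <- obs_n$support & exp_n$support
  if (sum(supp) < 2L) stop("fewer than 2 classes in the common support")
  po <- obs_n$phi[supp] / sum(obs_n$phi[supp])
  pe <- exp_n$phi[supp] / sum(exp_n$phi[supp])
  r <- logit(po) - logit(pe)
  se <- sqrt(1 / (S * po) + 1 / (S * (1 - po)))
  cls <- which(supp)
  out <- data.frame(class = cls, freq = cls / obs_n$n,
                    phi_obs = po, phi_exp = pe, residual = r, se = se,
                    lo95 = r - 1.96 * se, hi95 = r + 1.96 * se,
                    lo99 = r - 2.576 * se, hi99 = r + 2.576 * se)
  class(out) <- c("residual_profile", "data.frame")
  out
}

as_sfs_norm <- function(x) {
  if (inherits(x, "sfs_norm")) return(x)
  if (inherits(x, "expected_sfs")) {
    return(structure(list(n = x$n, phi = x$phi, support = x$phi > 0,
                          meta = list()), class = "sfs_norm"))
  }
  if (is_sfs(x)) return(normalize_sfs(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a normalized SFS")
}

#' Export a residual profile as CSV
#'
#' @param x a `"residual_profile"` data frame from [log_odds_residuals()].
#' @param path output file.
#' @export
write_residual_profile <- function(x, path) {
  stopifnot(inherits(x, "residual_profile"))
  utils::write.csv(x[, c("class", "freq", "residual", "se",
                         "lo95", "hi95", "lo99", "hi99")],
                   path, row.names = FALSE)
  invisible(path)
}
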