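#' Simulate a fragment-ensemble of site-frequency spectra
#'
#' Emulates the construction of an observed SFS from many short, effectively
#' unlinked genomic fragments (25 kb fragments separated by 500 kb gaps by
#' default): each fragment is an independent single-locus genealogy from the
#' requested model, with Poisson infinite-sites mutations at rate theta/2 per
#' unit branch length. The classwise mean of the ensemble
#' ([ensemble_mean_sfs()]) is the observed SFS for model fitting.
#'
#' @param model a [coal_model] specification.
#' @param n sample size.
#' @param theta population-scaled mutation rate per fragment.
#' @param n_fragments number of fragments (>= 1).
#' @param seed optional integer seed; the same seed replays the ensemble
#'   bit-identically.
#' @param fragment_bp,gap_bp fragment layout metadata recorded per fragment.
#' @return List of [sfs()] objects, one per fragment, each carrying its
#'   genomic start coordinate in `meta`.
#' @export
generate_fragment_ensemble <- function(model, n, theta, n_fragments,
                                       seed = NULL, fragment_bp = 25000,
                                       gap_bp = 500000) {
  stopifnot(is_coal_model(model), n_fragments >= 1)
  with_seed(seed, {
    sp <- sim_branch_spectra(model, n, n_fragments)
    lapply(seq_len(n_fragments), function(i) {
      counts <- stats::rpois(n - 1L, theta / 2 * sp$B[i, ])
      sfs(counts, n = n,
          meta = list(model = model$family, theta = theta, fragment = i,
                      start = (i - 1) * (fragment_bp + gap_bp),
                      length_bp = fragment_bp, seed = seed))
    })
  })
}

#' Perturb an SFS by SNP misorientation
#'
#' Mis-assignment of ancestral/derived states (parallel mutation in the
#' outgroup or low-level ancestral introgression) transfers mass between
#' complementary classes: \eqn{\xi'_i = (1-\epsilon)\xi_i + \epsilon\,
#' \xi_{n-i}}. The total count is conserved exactly; epsilon = 0.5 yields a
#' symmetric (folded-looking) spectrum, and two applications compose into a
#' single one with mixture weight \eqn{\epsilon_1(1-\epsilon_2) +
#' \epsilon_2(1-\epsilon_1)}.
#'
#' @param x an [sfs()] object.
#' @param epsilon misorientation probability in \[0, 1\].
#' @export
misorient_sfs <- function(x, epsilon) {
  stopifnot(is_sfs(x))
  if (epsilon < 0 || epsilon > 1)
    stop("domain error: epsilon must lie in [0, 1]")
  counts <- (1 - epsilon) * x$counts + epsilon * rev(x$counts)
  sfs(counts, n = x$n, mask = x$mask,
      meta = c(x$meta, list(misorientation = epsilon)))
}

#' Simulate per-gene McDonald-Kreitman tables
#'
#' Generates independent Poisson 2x2 tables whose cell means satisfy
#' (E\[Pn\]/E\[Ps\]) / (E\[Dn\]/E\[Ds\]) = `true_NI`: Ps, Dn and Ds have mean
#' `depth` and Pn mean `depth * true_NI`. With shallow depth many tables
#' contain zero cells and are flagged undefined by [mk_test()].
#'
#' @param n_genes number of genes.
#' @param true_NI generative neutrality index (> 0).
#' @param depth expected count per cell (> 0).
#' @param seed optional integer seed.
#' @return Data frame with columns `gene`, `Pn`, `Ps`, `Dn`, `Ds`.
#' @export
generate_mk_tables <- function(n_genes, true_NI, depth, seed = NULL) {
  stopifnot(n_genes >= 1)
  if (true_NI <= 0) stop("domain error: true_NI must be > 0")
  if (depth <= 0) stop("domain error: depth must be > 0")
  with_seed(seed, data.frame(
    gene = paste0("gene", seq_len(n_genes)),
    Pn = stats::rpois(n_genes, depth * true_NI),
    Ps = stats::rpois(n_genes, depth),
    Dn = stats::rpois(n_genes, depth),
    Ds = stats::rpois(n_genes, depth)))
}

#' Assemble a full synthetic study bundle
#'
#' An end-to-end synthetic stand-in for a population-genomic study: a
#' fragment-ensemble SFS with its ensemble mean and 100-replicate bootstrap
#' bands, a per-site table for windowed scans, per-gene McDonald-Kreitman
#' tables, and the generating record (model family, parameters, theta, seed)
#' sufficient to replay the bundle bit-identically.
#'
#' @param config list with elements `model` (a [coal_model]; default Kingman),
#'   `n` (sample size, default 20), `theta` (default 5), `n_fragments`
#'   (default 100), `n_sites` (default 2000), `span_bp` (default 1e6),
#'   `n_genes` (default 200), `true_NI` (default 1), `depth` (default 50),
#'   `bootstrap_B` (default 100).
#' @param seed integer seed (required for replay; default 1).
#' @return Object of class `"study_bundle"`: `fragments`, `observed`,
#'   `bootstrap`, `sites`, `mk`, `record`.
#' @export
generate_study_bundle <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(
    list(model = kingman_model(), n = 20L, theta = 5, n_fragments = 100L,
         n_sites = 2000L, span_bp = 1e6, n_genes = 200L, true_NI = 1,
         depth = 50, bootstrap_B = 100L),
    config)
  stopifnot(is_coal_model(cfg$model))
  with_seed(seed, {
    fragments <- generate_fragment_ensemble(cfg$model, cfg$n, cfg$theta,
                                            cfg$n_fragments)
    observed <- ensemble_mean_sfs(fragments)
    boot <- bootstrap_sfs(fragments, B = cfg$bootstrap_B)
    phi <- normalize_sfs(observed)$phi
    phi[is.na(phi)] <- 0
    sites <- data.frame(
      position = sort(sample.int(cfg$span_bp, cfg$n_sites, replace = TRUE)),
      derived_count = sample.int(cfg$n - 1L, cfg$n_sites, replace = TRUE,
                                 prob = phi))
    mk <- generate_mk_tables(cfg$n_genes, cfg$true_NI, cfg$depth)
    record <- list(family = cfg$model$family,
                   params = unclass(cfg$model), theta = cfg$theta,
                   n = cfg$n, n_fragments = cfg$n_fragments,
                   n_sites = cfg$n_sites, span_bp = cfg$span_bp,
                   n_genes = cfg$n_genes, true_NI = cfg$true_NI,
                   depth = cfg$depth, bootstrap_B = cfg$bootstrap_B,
                   seed = seed)
    structure(list(fragments = fragments, observed = observed,
                   bootstrap = boot, sites = sites, mk = mk, record = record),
              class = "study_bundle")
  })
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle:", x$record$family, "model,",
      length(x$fragments), "fragments, n =", x$observed$n,
      ", seed =", x$record$seed, "\n")
  invisible(x)
}

#' Write / read a study bundle as a plain-text directory
#'
#' Layout: `observed.sfs` (realSFS flat), `fragments.csv` (long format:
#' fragment, start, class, count), `sites.csv`, `mk.csv`, `bundle.json`
#' (the generating record).
#'
#' @param bundle a `"study_bundle"`.
#' @param dir target directory (created if missing).
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sfs(bundle$observed, file.path(dir, "observed.sfs"))
  frag <- do.call(rbind, lapply(seq_along(bundle$fragments), function(i) {
    f <- bundle$fragments[[i]]
    data.frame(fragment = i, start = f$meta$start,
               class = seq_len(f$n - 1L), count = f$counts)
  }))
  utils::write.csv(frag, file.path(dir, "fragments.csv"), row.names = FALSE)
  utils::write.csv(bundle$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$mk, file.path(dir, "mk.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$record, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study_bundle
#' @export
read_study_bundle <- function(dir) {
  record <- jsonlite::read_json(file.path(dir, "bundle.json"),
                                simplifyVector = TRUE)
  frag <- utils::read.csv(file.path(dir, "fragments.csv"))
  n <- max(frag$class) + 1L
  fragments <- lapply(split(frag, frag$fragment), function(d) {
    sfs(d$count[order(d$class)], n = n, meta = list(start = d$start[1]))
  })
  names(fragments) <- NULL
  structure(list(fragments = fragments,
                 observed = read_sfs(file.path(dir, "observed.sfs")),
                 bootstrap = NULL,
                 sites = utils::read.csv(file.path(dir, "sites.csv")),
                 mk = utils::read.csv(file.path(dir, "mk.csv")),
                 record = record),
            class = "study_bundle")
}
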