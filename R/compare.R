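#' Full coalescent model comparison for an observed SFS
#'
#' Fits each requested model family to the observed spectrum (grid search by
#' default; see [fit_coalescent()]), computes log-odds residual profiles, and
#' ranks the families by the logit-scale residual sum of squares. When an
#' ensemble of fragment spectra is supplied, its classwise mean is the
#' observed SFS and bootstrap error bands are attached to the report.
#'
#' @param observed an [sfs()] object or a list of them (a fragment ensemble).
#' @param families character vector among `"kingman"`, `"beta"`, `"ds"`.
#' @param control named list of per-family argument lists passed on to
#'   [fit_coalescent()] (e.g. `control = list(ds = list(grid = list(c =
#'   seq(1, 12, 0.25))))`).
#' @param seed integer seed; family fits use `seed + 1, seed + 2, ...` so the
#'   whole report replays bit-identically.
#' @return Object of class `"model_comparison"`: `fits` (named list of
#'   `coal_fit` objects or error messages), `ranking` (data frame with
#'   family, parameters, score, sorted by score), `observed`, `bootstrap`
#'   (or `NULL`), `seed`.
#' @export
run_model_comparison <- function(observed,
                                 families = c("kingman", "beta", "ds"),
                                 control = list(), seed = 1L) {
  families <- match.arg(families, several.ok = TRUE)
  bootstrap <- NULL
  if (is.list(observed) && !is_sfs(observed) &&
      !inherits(observed, "sfs_norm")) {
    bootstrap <- bootstrap_sfs(observed)
    observed <- ensemble_mean_sfs(observed)
  }
  fits <- list()
  for (i in seq_along(families)) {
    fam <- families[i]
    args <- c(list(observed = observed, family = fam, seed = seed + i),
              control[[fam]])
    fits[[fam]] <- tryCatch(do.call(fit_coalescent, args),
                            error = function(e) conditionMessage(e))
  }
  ok <- vapply(fits, inherits, logical(1), what = "coal_fit")
  ranking <- do.call(rbind, lapply(names(fits)[ok], function(fam) {
    f <- fits[[fam]]
    data.frame(family = fam,
               parameters = paste(names(coef(f)), signif(coef(f), 4),
                                  sep = "=", collapse = ", "),
               score = f$score)
  }))
  if (!is.null(ranking)) ranking <- ranking[order(ranking$score), ]
  structure(list(fits = fits, ranking = ranking, observed = observed,
                 bootstrap = bootstrap, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Coalescent model comparison (n =", x$observed$n, "lineages)\n\n")
  if (is.null(x$ranking)) {
    cat("no successful fits\n")
  } else {
    print(x$ranking, row.names = FALSE)
  }
  failed <- names(x$fits)[!vapply(x$fits, inherits, logical(1), "coal_fit")]
  if (length(failed))
    cat("\nfailed families:", paste(failed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.model_comparison <- function(object, ...) {
  print(object)
  for (fam in names(object$fits)) {
    f <- object$fits[[fam]]
    if (inherits(f, "coal_fit")) {
      cat("\n--", fam, "--\n")
      print(f)
    }
  }
  invisible(object)
}

#' Write a model-comparison report to disk
#'
#' Emits `report.json` (ranking, best-fit parameters, scores, seed) plus
#' per-family CSVs of the expected spectrum and the residual profile.
#'
#' @param x a `"model_comparison"`.
#' @param dir target directory (created if missing).
#' @export
write_comparison_report <- function(x, dir) {
  stopifnot(inherits(x, "model_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- vapply(x$fits, inherits, logical(1), "coal_fit")
  report <- list(
    n = x$observed$n,
    seed = x$seed,
    ranking = x$ranking,
    models = lapply(x$fits[ok], function(f)
      list(family = f$family, method = f$method,
           coefficients = as.list(coef(f)), score = f$score)),
    failed = as.list(x$fits[!ok]))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (fam in names(x$fits)[ok]) {
    f <- x$fits[[fam]]
    utils::write.csv(data.frame(class = seq_len(f$expected$n - 1L),
                                phi = f$expected$phi),
                     file.path(dir, paste0("expected_", fam, ".csv")),
                     row.names = FALSE)
    write_residual_profile(stats::residuals(f),
                           file.path(dir, paste0("residuals_", fam, ".csv")))
  }
  invisible(dir)
}
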