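test_that("fragment ensembles replay from their seed and match closed-form means", {
  e1 <- generate_fragment_ensemble(kingman_model(), 10, theta = 5,
                                   n_fragments = 20, seed = 1)
  e2 <- generate_fragment_ensemble(kingman_model(), 10, theta = 5,
                                   n_fragments = 20, seed = 1)
  expect_identical(lapply(e1, function(f) f$counts),
                   lapply(e2, function(f) f$counts))
  expect_equal(e1[[3]]$meta$start, 2 * (25000 + 500000))

  # ensemble-mean normalized SFS near the Kingman closed form
  big <- generate_fragment_ensemble(kingman_model(), 10, theta = 5,
                                    n_fragments = 10000, seed = 2)
  m <- ensemble_mean_sfs(big)
  phi <- m$counts / sum(m$counts)
  cts <- vapply(big, function(f) f$counts, numeric(9))
  se <- apply(cts / sum(m$counts), 1, stats::sd) / sqrt(ncol(cts))
  expect_lt(max(abs(phi - kingman_phi(10)) / se), 3.5)
})

test_that("10,000 DS replicates leave no zero class in the mean SFS (n = 20, c = 10, theta = 5)", {
  ens <- generate_fragment_ensemble(ds_model(c = 10), 20, theta = 5,
                                    n_fragments = 10000, seed = 3)
  m <- ensemble_mean_sfs(ens)
  expect_true(all(m$counts > 0))
  # and the DS ensemble is more U-shaped than a Kingman ensemble at matched theta
  ek <- generate_fragment_ensemble(kingman_model(), 20, theta = 5,
                                   n_fragments = 10000, seed = 4)
  mk <- ensemble_mean_sfs(ek)
  ratio <- function(x) x$counts[19] / x$counts[10]
  expect_gt(ratio(m), ratio(mk))
})

test_that("misorientation mixes complementary classes and conserves the total", {
  x <- sfs(c(10, 0, 0, 0, 2), n = 6)
  expect_equal(misorient_sfs(x, 0)$counts, x$counts)
  expect_equal(misorient_sfs(x, 0.1)$counts, c(9.2, 0, 0, 0, 2.8))
  sym <- misorient_sfs(x, 0.5)$counts
  expect_equal(sym, rev(sym))
  for (eps in c(0.05, 0.3, 0.9)) {
    y <- misorient_sfs(x, eps)
    expect_equal(sum(y$counts), sum(x$counts))
  }
  # composition: eps1 then eps2 equals one application at the composed weight
  e1 <- 0.1; e2 <- 0.25
  comp <- e1 * (1 - e2) + e2 * (1 - e1)
  expect_equal(misorient_sfs(misorient_sfs(x, e1), e2)$counts,
               misorient_sfs(x, comp)$counts)
  expect_error(misorient_sfs(x, 1.2), "domain")
})

test_that("MK table generator recovers its generative neutrality index", {
  null <- mk_test(generate_mk_tables(500, true_NI = 1, depth = 50, seed = 5))
  v <- null$neg_log_NI[null$defined]
  expect_lt(abs(mean(v)) / (stats::sd(v) / sqrt(length(v))), 3)

  # the study-scale signal: true -log NI = 0.27
  strong <- mk_test(generate_mk_tables(2000, true_NI = exp(-0.27),
                                       depth = 100, seed = 6))
  v2 <- strong$neg_log_NI[strong$defined]
  expect_lt(abs(mean(v2) - 0.27), 3 * stats::sd(v2) / sqrt(length(v2)) + 0.01)

  # shallow depth: most tables flagged undefined (zero cells dominate)
  shallow <- mk_test(generate_mk_tables(400, true_NI = 1, depth = 0.1,
                                        seed = 7))
  expect_gt(mean(!shallow$defined), 0.5)
})

test_that("study bundles replay bit-identically and are internally consistent", {
  cfg <- list(model = ds_model(c = 10), n = 20, n_fragments = 60,
              n_genes = 50, n_sites = 500)
  b1 <- generate_study_bundle(cfg, seed = 11)
  b2 <- generate_study_bundle(cfg, seed = 11)
  expect_identical(b1$observed$counts, b2$observed$counts)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$mk, b2$mk)
  expect_equal(b1$observed$counts, ensemble_mean_sfs(b1$fragments)$counts)
  expect_equal(b1$record$seed, 11)
  expect_equal(b1$bootstrap$B, 100L)

  # directory round trip
  d <- withr::local_tempdir()
  write_study_bundle(b1, d)
  b3 <- read_study_bundle(d)
  expect_equal(vapply(b3$fragments, function(f) f$counts, numeric(19)),
               vapply(b1$fragments, function(f) f$counts, numeric(19)))
  expect_equal(b3$observed$counts, b1$observed$counts)
  expect_equal(b3$record$family, "ds")
})

test_that("pipeline fits rank the bundle's own generating family best across seeds", {
  ctl <- list(kingman = list(grid = list(growth = 0)),
              ds = list(grid = list(c = seq(1, 16, 1))))
  wins <- 0L
  n_trials <- 10L
  for (s in seq_len(n_trials)) {
    b <- generate_study_bundle(list(model = ds_model(c = 10), n = 20,
                                    n_fragments = 100), seed = 100 + s)
    cmp <- run_model_comparison(b$observed, families = c("kingman", "ds"),
                                control = ctl, seed = s)
    if (cmp$ranking$family[1] == "ds") wins <- wins + 1L
  }
  expect_gte(wins / n_trials, 0.9)
})
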