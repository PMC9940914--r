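test_that("grid fit recovers generative parameters from exact spectra", {
  obs <- sfs(expected_sfs(ds_model(c = 5), 20)$phi * 1e5)
  fit <- fit_coalescent(obs, "ds", grid = list(c = seq(0.5, 10, 0.5)))
  expect_equal(unname(coef(fit)), 5)
  expect_lt(fit$score, 1e-12)
  expect_s3_class(fit$expected, "sfs_norm")

  obsb <- sfs(expected_sfs(beta_model(1.4), 20)$phi * 1e5)
  fb <- fit_coalescent(obsb, "beta", grid = list(alpha = seq(1.05, 1.95, 0.05)))
  expect_equal(unname(coef(fb)), 1.4)
})

test_that("fit methods: coef, predict, residuals, simulate, print", {
  obs <- sfs(round(expected_sfs(ds_model(c = 8), 20)$phi * 1e4))
  fit <- fit_coalescent(obs, "ds", grid = list(c = seq(1, 12, 0.5)))
  expect_named(coef(fit), "c")
  p <- predict(fit)
  expect_s3_class(p, "sfs_norm")
  expect_equal(sum(p$phi), 1)
  pc <- predict(fit, type = "counts")
  expect_equal(sum(pc$counts), fit$S)
  r <- residuals(fit)
  expect_s3_class(r, "residual_profile")
  expect_lt(max(abs(r$residual)), 0.5)
  sim <- simulate(fit, nsim = 3, seed = 1, theta = 2)
  expect_length(sim, 3)
  expect_true(all(vapply(sim, inherits, logical(1), "sfs")))
  expect_output(print(fit), "Durrett-Schweinsberg")
})

test_that("score is invariant to scaling of the observed counts", {
  obs <- sfs(c(50, 22, 13, 9, 7, 5, 4, 4, 6))
  f1 <- fit_coalescent(obs, "ds", grid = list(c = seq(1, 10, 1)))
  f2 <- fit_coalescent(sfs(10 * obs$counts), "ds",
                       grid = list(c = seq(1, 10, 1)))
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$score, f2$score)
})

test_that("ABC fit wires the sampler and emits posterior summaries", {
  obs <- sfs(expected_sfs(beta_model(1.5), 15)$phi * 1000)
  fit <- fit_coalescent(obs, "beta", method = "abc",
                        config = abc_config(chain_length = 1500,
                                            burn_in = 300, pilot = 300),
                        seed = 4)
  expect_s3_class(fit$posterior$sample, "posterior_sample")
  expect_s3_class(fit$posterior$summary, "posterior_summary")
  expect_lt(abs(coef(fit)[["alpha"]] - 1.5), 0.1)
  # replay from the same seed
  fit2 <- fit_coalescent(obs, "beta", method = "abc",
                         config = abc_config(chain_length = 1500,
                                             burn_in = 300, pilot = 300),
                         seed = 4)
  expect_identical(fit$posterior$sample$draws, fit2$posterior$sample$draws)
  # default Monte Carlo replicates follow the study design
  expect_equal(abc_config()$replicates, 10000L)
})

test_that("model comparison ranks the generative family first on clean data", {
  obs <- sfs(expected_sfs(kingman_model(), 20)$phi * 1e5)
  cmp <- run_model_comparison(
    obs, control = list(kingman = list(grid = list(growth = 0)),
                        beta = list(grid = list(alpha = seq(1.1, 1.99, 0.01))),
                        ds = list(grid = list(c = seq(0.05, 20, 0.05)))),
    seed = 1)
  expect_equal(cmp$ranking$family[1], "kingman")
  expect_lt(cmp$fits$kingman$score, 1e-6)
  # DS pulled towards its Kingman limit
  expect_lt(coef(cmp$fits$ds)[["c"]], 0.5)
  # Beta pulled towards alpha = 2
  expect_gt(coef(cmp$fits$beta)[["alpha"]], 1.9)
})

test_that("comparison on a DS ensemble ranks DS first, replays, and writes a report", {
  ens <- generate_fragment_ensemble(ds_model(c = 10), 20, theta = 5,
                                    n_fragments = 100, seed = 9)
  ctl <- list(kingman = list(grid = list(growth = c(0, 1, 2))),
              beta = list(grid = list(alpha = seq(1.05, 1.95, 0.05))),
              ds = list(grid = list(c = seq(0.5, 16, 0.5))))
  cmp <- run_model_comparison(ens, control = ctl, seed = 2)
  expect_equal(cmp$ranking$family[1], "ds")
  expect_s3_class(cmp$bootstrap, "sfs_boot")
  cmp2 <- run_model_comparison(ens, control = ctl, seed = 2)
  expect_identical(cmp$ranking, cmp2$ranking)
  expect_identical(coef(cmp$fits$ds), coef(cmp2$fits$ds))

  d <- withr::local_tempdir()
  write_comparison_report(cmp, d)
  rep <- jsonlite::read_json(file.path(d, "report.json"), simplifyVector = TRUE)
  expect_equal(rep$seed, 2)
  expect_true(file.exists(file.path(d, "residuals_ds.csv")))
  expect_true(file.exists(file.path(d, "expected_kingman.csv")))
})

test_that("a failing family is recorded without sinking the report", {
  obs <- sfs(expected_sfs(kingman_model(), 4)$phi * 100)  # n too small to truncate
  cmp <- run_model_comparison(
    obs, families = c("kingman", "ds"),
    control = list(kingman = list(grid = list(growth = "bad")),
                   ds = list(grid = list(c = c(1, 2)))),
    seed = 3)
  expect_false(inherits(cmp$fits$kingman, "coal_fit"))
  expect_s3_class(cmp$fits$ds, "coal_fit")
})
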