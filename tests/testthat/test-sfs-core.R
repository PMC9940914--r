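test_that("realSFS flat dialect parses, drops monomorphic classes, and round-trips", {
  f <- withr::local_tempfile()
  writeLines("0 10 5 2 1 0", f)
  x <- read_sfs(f)
  expect_equal(x$n, 5L)
  expect_equal(x$counts, c(10, 5, 2, 1))

  # round trip
  g <- withr::local_tempfile()
  write_sfs(x, g)
  y <- read_sfs(g)
  expect_equal(y$counts, x$counts)
  expect_equal(y$n, x$n)

  # csv dialect equivalence (and its round trip)
  h <- withr::local_tempfile(fileext = ".csv")
  write_sfs(x, h, dialect = "csv")
  z <- read_sfs(h, dialect = "csv")
  expect_equal(z$counts, x$counts)
  expect_equal(z$n, x$n)

  # extra whitespace tolerated
  writeLines("  0\t10  5 2 1 0  ", f)
  expect_equal(read_sfs(f)$counts, c(10, 5, 2, 1))
})

test_that("malformed SFS files raise informative parse errors", {
  f <- withr::local_tempfile()
  writeLines("0 10 x 2 1 0", f)
  expect_error(read_sfs(f), "non-numeric token 'x' at line 1, field 3")
  writeLines("0 5", f)
  expect_error(read_sfs(f), "malformed")
  writeLines(c("", "0 1 x"), f)
  expect_error(read_sfs(f), "line 2")
})

test_that("normalization divides by the unmasked total and is idempotent", {
  x <- sfs(c(10, 5, 2, 1))
  nz <- normalize_sfs(x)
  expect_equal(nz$phi, c(10, 5, 2, 1) / 18)
  expect_equal(sum(nz$phi[nz$support]), 1)
  expect_identical(normalize_sfs(nz), nz)

  # uniform counts -> uniform phi
  u <- normalize_sfs(sfs(rep(3, 7), n = 8))
  expect_equal(u$phi, rep(1 / 7, 7))

  # Kingman expectation for n = 4
  k <- normalize_sfs(sfs(c(1, 1 / 2, 1 / 3)))
  expect_equal(k$phi, c(6, 3, 2) / 11)

  expect_error(normalize_sfs(sfs(c(0, 0, 0))), "degenerate")
})

test_that("logit is the natural-log odds, odd about 1/2, and masks the endpoints", {
  expect_equal(logit(0.5), 0)
  expect_equal(round(logit(0.88), 2), 1.99)
  expect_equal(round(logit(0.12), 2), -1.99)
  p <- seq(0.02, 0.98, by = 0.02)
  expect_equal(logit(p), -logit(1 - p))
  expect_true(all(diff(logit(p)) > 0))
  expect_true(is.na(logit(0)) && is.na(logit(1)))
  expect_error(logit(1.2), "requires p in")
})

test_that("truncation masks classes 1, 2, n-2, n-1 and is idempotent", {
  x <- sfs(c(5, 4, 3, 2, 1), n = 6)
  tr <- truncate_sfs(x)
  expect_equal(which(tr$mask), 3L)
  expect_equal(tr$counts, x$counts)  # counts unchanged, only masked
  expect_equal(normalize_sfs(tr)$phi[3], 1)

  # renormalization over retained support sums to 1
  y <- truncate_sfs(sfs(c(9, 7, 5, 4, 3, 2, 1, 1, 2), n = 10))
  nz <- normalize_sfs(y)
  expect_equal(sum(nz$phi[nz$support]), 1)

  expect_identical(truncate_sfs(truncate_sfs(y))$mask, truncate_sfs(y)$mask)
  expect_error(truncate_sfs(sfs(c(1, 2, 3, 4))), "empty support")
})

test_that("ensemble mean is the classwise mean and commutes with scaling", {
  e <- list(sfs(c(2, 0)), sfs(c(0, 2)))
  expect_equal(ensemble_mean_sfs(e)$counts, c(1, 1))
  one <- sfs(c(3, 2, 1))
  expect_equal(ensemble_mean_sfs(rep(list(one), 7))$counts, one$counts)
  expect_error(ensemble_mean_sfs(list(sfs(c(1, 2)), sfs(c(1, 2, 3)))),
               "mixed sample sizes")
  # commutes with classwise scaling
  sc <- lapply(e, function(s) sfs(5 * s$counts))
  expect_equal(ensemble_mean_sfs(sc)$counts, 5 * ensemble_mean_sfs(e)$counts)
})

test_that("bootstrap bands match exact resample enumeration and degenerate cases", {
  # identical fragments: zero SD
  e <- rep(list(sfs(c(4, 2, 1))), 5)
  b <- bootstrap_sfs(e, B = 50)
  expect_equal(b$sd, c(0, 0, 0))
  expect_equal(b$lower, b$upper)

  # two-fragment ensemble: the 4 equiprobable resamples give class SD
  # sqrt(0.5) exactly (resample means 2, 1, 1, 0 per class)
  set.seed(1)
  b2 <- bootstrap_sfs(list(sfs(c(2, 0)), sfs(c(0, 2))), B = 4000)
  expect_lt(max(abs(b2$sd - sqrt(0.5))), 0.05)

  expect_warning(bootstrap_sfs(list(sfs(c(1, 2)))), "singleton ensemble")
  expect_equal(formals(bootstrap_sfs)$B, 100L)
})

test_that("log-odds residuals vanish for a model against itself with nested bands", {
  e <- expected_sfs(kingman_merger_rates(10))
  r <- log_odds_residuals(e, e, S = 500)
  expect_equal(r$residual, rep(0, 9))
  expect_true(all(r$lo99 <= r$lo95 & r$hi95 <= r$hi99))
})

test_that("log-odds residuals and delta-method SE match hand arithmetic", {
  obs <- sfs(c(500, 250, 250))
  exp_ <- sfs(c(250, 250, 500))
  r <- log_odds_residuals(obs, exp_, S = 1000)
  # phi_obs = 0.5 vs phi_exp = 0.25 at class 1
  expect_equal(r$residual[1], log(1) - log(1 / 3))
  expect_equal(r$se[1], sqrt(2 / 500))
  expect_equal(r$hi95[1] - r$residual[1], 1.96 * sqrt(2 / 500))
  # S defaults to the observed total
  r2 <- log_odds_residuals(obs, exp_)
  expect_equal(r2$se, r$se)
  # csv export keeps the documented columns
  f <- withr::local_tempfile(fileext = ".csv")
  write_residual_profile(r, f)
  expect_named(utils::read.csv(f),
               c("class", "freq", "residual", "se",
                 "lo95", "hi95", "lo99", "hi99"))
})

test_that("zero expected classes are masked out of the residual support", {
  obs <- sfs(c(5, 5, 5, 5))
  exp_ <- normalize_sfs(sfs(c(1, 0, 1, 2)))
  r <- log_odds_residuals(obs, exp_, S = 20)
  expect_equal(r$class, c(1L, 3L, 4L))
})
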