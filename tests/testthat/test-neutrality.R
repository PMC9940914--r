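test_that("theta estimators match their definitions and the pairwise enumeration", {
  x <- sfs(c(6, 3, 2, 1, 1, 1, 1, 0, 1), n = 10)
  th <- theta_estimators(x)
  expect_equal(th$S, 16)
  expect_equal(th$theta_W, 16 / sum(1 / (1:9)))
  # independent route: explicit haplotype pairwise differences
  derived <- list(c(1), c(2), c(1, 2), c(1, 2, 3), c(1, 2, 3, 4, 5))
  cnt <- tabulate(vapply(derived, length, integer(1)), nbins = 5)
  expect_equal(theta_estimators(sfs(cnt, n = 6))$theta_pi,
               theta_pi_enum(derived, 6))
  # n = 2: Watterson and pairwise estimators coincide
  th2 <- theta_estimators(sfs(7, n = 2))
  expect_equal(th2$theta_W, th2$theta_pi)
})

test_that("neutrality suite reproduces the independently computed reference values", {
  # frozen values from a step-by-step evaluation of the published formulas
  st <- neutrality_suite(sfs(c(6, 3, 2, 1, 1, 1, 1, 0, 1), n = 10))
  expect_equal(st$Tajima_D, -0.1365919190, tolerance = 1e-8)
  expect_equal(st$FuLi_D, -0.1083416815, tolerance = 1e-8)
  expect_equal(st$FayWu_H, 0.0279392946, tolerance = 1e-8)
  expect_equal(st$Zeng_E, -0.1383760571, tolerance = 1e-8)
  expect_true(st$defined)
})

test_that("suite edge cases: D = 0 when theta_pi = theta_W, sign of H, S = 0 flag", {
  # constructed so that theta_pi = theta_W exactly
  st <- neutrality_suite(sfs(c(8, 3, 0), n = 4))
  expect_equal(st$Tajima_D, 0)
  # mass on class n-1: high-frequency derived excess, H < 0
  hi <- neutrality_suite(sfs(c(1, 0, 0, 0, 0, 0, 0, 0, 30), n = 10))
  expect_lt(hi$FayWu_H, 0)
  # unnormalized variant is theta_pi - theta_H
  th <- theta_estimators(sfs(c(1, 0, 0, 0, 0, 0, 0, 0, 30), n = 10))
  expect_equal(neutrality_suite(sfs(c(1, 0, 0, 0, 0, 0, 0, 0, 30), n = 10),
                                normalized = FALSE)$FayWu_H,
               th$theta_pi - th$theta_H)
  # S = 0: undefined result, not an exception
  z <- neutrality_suite(sfs(c(0, 0, 0, 0)))
  expect_false(z$defined)
  expect_true(is.na(z$Tajima_D))
  expect_error(neutrality_suite(sfs(c(1, 1))), "n >= 4")
})

test_that("under Kingman the statistics are near zero; sweeps drive D negative", {
  # the normalized statistics carry a small negative finite-theta bias, so
  # "near zero" is judged against the +/- 1 scale at which they are read
  set.seed(21)
  sp <- sim_branch_spectra(kingman_model(), 20, 2000)
  vals <- t(vapply(seq_len(2000), function(r) {
    st <- neutrality_suite(sfs(stats::rpois(19, 5 * sp$B[r, ])))
    c(st$Tajima_D, st$FuLi_D, st$FayWu_H, st$Zeng_E)
  }, numeric(4)))
  expect_lt(max(abs(colMeans(vals, na.rm = TRUE))), 0.25)

  set.seed(22)
  spd <- sim_branch_spectra(ds_model(c = 10), 20, 1000)
  D <- vapply(seq_len(1000), function(r)
    neutrality_suite(sfs(stats::rpois(19, 5 * spd$B[r, ])))$Tajima_D,
    numeric(1))
  expect_lt(mean(D, na.rm = TRUE), -0.5)

  # the high-frequency excess picked up by H needs the study-scale sample
  # size: the exact expected numerator is negative at n = 68
  n <- 68; i <- seq_len(n - 1)
  EB <- expected_sfs(ds_merger_rates(10, n))$branch_lengths
  expect_lt(sum((i * (n - i) / choose(n, 2) - i / (n - 1)) * EB), 0)
})

test_that("windowed scan tiles half-open windows and is translation invariant", {
  set.seed(23)
  sites <- data.frame(position = sort(sample.int(3e5, 400)),
                      derived_count = sample.int(9, 400, replace = TRUE))
  scan <- windowed_scan(sites, n = 10)
  expect_equal(scan$end - scan$start, rep(1e5, nrow(scan)))
  expect_equal(unique(diff(scan$start)), 2e4)
  # defaults are 100 kb windows with 20 kb steps
  expect_identical(scan, windowed_scan(sites, n = 10, window_bp = 100000,
                                       step_bp = 20000))
  # translation: coordinates shift, statistics do not
  shifted <- windowed_scan(transform(sites, position = position + 77777),
                           n = 10)
  expect_equal(shifted$start, scan$start + 77777)
  expect_equal(shifted$Tajima_D, scan$Tajima_D)
  # all sites in one window: one defined row, empty rows retained undefined
  one <- windowed_scan(data.frame(position = c(10, 20, 30),
                                  derived_count = c(1, 2, 3)), n = 10)
  expect_true(any(one$S > 0))
  expect_error(windowed_scan(data.frame(position = c(5, 1),
                                        derived_count = c(1, 1)), n = 10),
               "sorted")
})

test_that("MK test arithmetic, flags, and exact-test p-values", {
  null <- mk_test(10, 10, 10, 10)
  expect_equal(null$NI, 1)
  expect_equal(null$neg_log_NI, 0)
  expect_equal(null$alpha, 0)
  expect_equal(null$p, 1)

  r <- mk_test(2, 4, 4, 4)
  expect_equal(r$NI, 0.5)
  expect_equal(r$neg_log_NI, log(2))
  expect_equal(r$alpha, 0.5)
  expect_equal(r$p, fisher_p_enum(2, 4, 4, 4))

  # p matches fixed-margin enumeration on a grid of tables
  for (tab in list(c(1, 9, 8, 2), c(5, 5, 1, 9), c(3, 0, 2, 7))) {
    expect_equal(mk_test(tab[1], tab[2], tab[3], tab[4])$p,
                 do.call(fisher_p_enum, as.list(tab)),
                 tolerance = 1e-8, label = paste(tab, collapse = ","))
  }

  # zero cells flag NI as undefined unless the Haldane correction is on
  z <- mk_test(3, 0, 2, 7)
  expect_false(z$defined)
  expect_true(is.na(z$NI))
  zh <- mk_test(3, 0, 2, 7, haldane = TRUE)
  expect_true(zh$defined)
  expect_equal(zh$NI, (3.5 / 0.5) / (2.5 / 7.5))

  # -log NI antisymmetric under swapping the rows' roles
  a <- mk_test(6, 3, 2, 5)
  b <- mk_test(2, 5, 6, 3)
  expect_equal(a$neg_log_NI, -b$neg_log_NI)

  # paper-scale arithmetic: mean -log NI of 0.27 implies alpha ~ 24%
  expect_equal(round(100 * (1 - exp(-0.27))), 24)
})

test_that("divergence arithmetic converts p-distance and rate to mega-sites", {
  expect_equal(round(expected_divergence(0.005, 685e6)$megasites, 1), 3.4)
  expect_equal(expected_divergence(0, 685e6)$megasites, 0)
  expect_equal(divergence_from_rate(1, 3.5e6)$megasites, 3.5)
  expect_error(expected_divergence(1.5, 1e6), "domain")
})
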