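test_that("incidence arithmetic reproduces the published rates and counts", {
  assum <- incidence_assumptions()
  expect_equal(incidence_per_impact(assum), 3.88)
  expect_equal(incidence_per_impact(assum, apply_underreporting = TRUE), 38.8)
  # multiplier of 1 is the identity
  one <- incidence_assumptions(underreporting_multiplier = 1)
  expect_equal(incidence_per_impact(one, apply_underreporting = TRUE),
               incidence_per_impact(one))
  # exact arithmetic is linear in the multiplier
  for (m in c(2, 5, 10)) {
    am <- incidence_assumptions(underreporting_multiplier = m)
    expect_equal(incidence_per_impact(am, TRUE, exact = TRUE),
                 m * incidence_per_impact(am, FALSE, exact = TRUE))
  }
  expect_equal(incidence_per_impact(assum, exact = TRUE),
               5.56 / (1000 * 14.3) * 1e4)
  expect_error(incidence_assumptions(concussions_per_1000_games = 0),
               "positive")

  expect_identical(expected_concussions(38.8, 63011), 244L)
  expect_identical(expected_concussions(10, 10000), 10L)
  expect_identical(expected_concussions(38.8, 0), 0L)

  expect_identical(additional_concussions(244, 37), 207L)
  expect_identical(additional_concussions(244, 244), 0L)
  expect_identical(additional_concussions(5, 2), 3L)
  expect_error(additional_concussions(5, 7), "below")
})

test_that("ranking orders sub-concussive impacts by mean percentile rank", {
  d <- make_impacts(c(100, 50, 100), c(5000, 2000, 1000),
                    id = c("i1", "i2", "i3"))
  expect_identical(rank_impacts(d), c("i1", "i3", "i2"))
  # full tie: stable input order
  dt <- make_impacts(rep(30, 4), rep(1500, 4), id = paste0("t", 1:4))
  expect_identical(rank_impacts(dt), paste0("t", 1:4))
  # an impact maximal on both axes ranks first
  dm <- make_impacts(c(10, 90, 40), c(800, 9000, 3000),
                     id = c("a", "b", "c"))
  expect_identical(rank_impacts(dm)[1], "b")
  # concussive rows are excluded from the ranking
  dl <- make_impacts(c(10, 200, 40), c(800, 9000, 3000),
                     label = c(0L, 1L, 0L), id = c("a", "b", "c"))
  expect_identical(rank_impacts(dl), c("c", "a"))
})

test_that("ranking is a deterministic total order", {
  set.seed(8)
  d <- make_impacts(round(rlnorm(60, 3, 0.5)), round(rlnorm(60, 7, 0.5)),
                    id = sprintf("x%02d", 1:60))
  r1 <- rank_impacts(d)
  r2 <- rank_impacts(d)
  expect_identical(r1, r2)
  expect_identical(sort(r1), sort(d$impact_id))  # permutation, no loss
})

test_that("lognormal marginal fit is the maximum-likelihood estimate", {
  set.seed(101)
  x <- rlnorm(1e4, meanlog = 4.6, sdlog = 0.3)
  m <- fit_concussive_marginal(x)
  expect_equal(m$meanlog, 4.6, tolerance = 0.01)
  expect_equal(m$sdlog, 0.3, tolerance = 0.01)
  # agrees with the fitdistrplus MLE route
  ref <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(m$meanlog, unname(ref$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(m$sdlog, unname(ref$estimate["sdlog"]), tolerance = 1e-3)
  # quantile/CDF inverse round trip
  grid <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95))
  expect_equal(unname(marginal_quantile(m, marginal_cdf(m, grid))),
               unname(grid), tolerance = 1e-10)
  expect_error(fit_concussive_marginal(rep(5, 10)), "variance")
  expect_error(fit_concussive_marginal(c(-1, 2, 3, 4, 5)), "positive")
  expect_error(fit_concussive_marginal(c(1, 2, 3)), "at least 5")
})

test_that("copula correlation is recovered by Kendall-tau inversion", {
  # comonotone sample: tau = 1, rho -> 1^-
  d <- make_impacts(1:20, 2 * (1:20))
  cop <- fit_gaussian_copula(d)
  expect_gt(cop$rho, 0.999)
  expect_lt(cop$rho, 1)
  # independent axes: |rho| < 0.05 at n = 1e4
  set.seed(31)
  di <- make_impacts(rlnorm(1e4, 4, 0.5), rlnorm(1e4, 8, 0.4))
  expect_lt(abs(fit_gaussian_copula(di)$rho), 0.05)
  # true rho = 0.6 recovered within 0.03 at n = 1e4
  set.seed(32)
  z1 <- rnorm(1e4)
  z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(1e4)
  dg <- make_impacts(qlnorm(pnorm(z1), 4, 0.5), qlnorm(pnorm(z2), 8, 0.4))
  expect_lt(abs(fit_gaussian_copula(dg)$rho - 0.6), 0.03)
  expect_error(fit_gaussian_copula(make_impacts(rep(2, 6), 1:6)),
               "degenerate")
})

test_that("copula samples respect the fitted marginals and dependence", {
  set.seed(55)
  spec <- population_preset("hits")$concussive
  train <- generate_class(class_spec(spec$mean_linear, spec$sd_linear,
                                     spec$mean_rotational,
                                     spec$sd_rotational, 0.35, 500),
                          seed = 91)
  cop <- fit_gaussian_copula(train)
  draws <- withr::with_seed(77, sample_gaussian_copula(cop, 1e4))
  # uniform marginals after the probability-integral transform
  u1 <- marginal_cdf(cop$marginal_linear, draws$linear_acc)
  u2 <- marginal_cdf(cop$marginal_rotational, draws$rotational_acc)
  expect_gt(ks.test(u1, "punif")$p.value, 0.01)
  expect_gt(ks.test(u2, "punif")$p.value, 0.01)
  # rank correlation consistent with rho (tau = 2/pi asin(rho))
  tau_expected <- 2 / pi * asin(cop$rho)
  expect_lt(abs(cor(draws$linear_acc, draws$rotational_acc,
                    method = "kendall") - tau_expected), 0.03)
})

test_that("reassignment conserves counts and flips exactly n_additional", {
  set.seed(9)
  d <- generate_hits_like(seed = 40, scale = 0.01)
  d$label[1:8] <- 1L   # ensure a usable concussive class
  cop <- fit_gaussian_copula(d[d$label == 1L, ])

  adj0 <- reassign_and_generate(d, 0, cop, seed = 1)
  expect_equal(adj0$records[names(d)], d)
  expect_identical(adj0$n_reassigned, 0L)

  adj <- reassign_and_generate(d, 25, cop, seed = 2)
  expect_identical(nrow(adj$records), nrow(d))
  expect_identical(sum(adj$records$label == 1L), sum(d$label == 1L) + 25L)
  expect_identical(sum(adj$records$reassigned), 25L)
  expect_setequal(adj$records$impact_id[adj$records$reassigned == 1L],
                  adj$reassigned_ids)
  # untouched rows keep their kinematics
  same <- adj$records$reassigned == 0L
  expect_identical(adj$records$linear_acc[same],
                   d$linear_acc[match(adj$records$impact_id[same],
                                      d$impact_id)])
  # deterministic under seed
  adj2 <- reassign_and_generate(d, 25, cop, seed = 2)
  expect_identical(adj$records, adj2$records)
  expect_error(reassign_and_generate(d, nrow(d) + 1, cop, seed = 1),
               "exceeds")
})

test_that("reassigned impacts are the top-ranked sub-concussive ones", {
  set.seed(44)
  d <- make_impacts(c(5, 80, 60, 10, 90), c(500, 4000, 3500, 800, 100),
                    label = c(0L, 0L, 0L, 0L, 1L),
                    id = c("lo1", "hi1", "hi2", "lo2", "con"))
  cop <- fit_gaussian_copula(make_impacts(rlnorm(10, 4.6, 0.3),
                                          rlnorm(10, 8.4, 0.4)))
  adj <- reassign_and_generate(d, 2, cop, seed = 3)
  expect_setequal(adj$reassigned_ids, c("hi1", "hi2"))
})
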