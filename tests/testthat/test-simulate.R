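test_that("same config and seed give identical output", {
  cfg <- sim_config(n_sires = 10, n_dams = 30, parities = 1,
                    kits_per_litter = 5, n_batches = 4, seed = 3)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$true_values, s2$true_values)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("zero-variance intercept-only liability gives a constant trait", {
  blk <- disease_trait("resist", c(S = 0, Ch = 0), c(S = 0, Ch = 0),
                       intercept = c(S = 8, Ch = 8), batch_sd = 0,
                       farm_sd = 0, sex_diff = 0)
  cfg <- sim_config(n_sires = 5, n_dams = 10, parities = 1,
                    kits_per_litter = 6, n_batches = 2, seed = 4,
                    composite_resist = FALSE, production = NULL,
                    diseases = list(resist = blk), fostering_rate = 0)
  sim <- simulate_population(cfg)
  # logistic residual with intercept +8: P(1) = plogis(8) = 0.99966
  expect_gt(mean(sim$phenotypes$animals$resist), 0.99)
})

test_that("inverse-link identities of expected_prevalence hold", {
  b0 <- disease_trait("t", c(S = 0, Ch = 0), c(S = 0, Ch = 0),
                      intercept = c(S = 0, Ch = 0), batch_sd = 0,
                      farm_sd = 0, sex_diff = 0)
  expect_equal(expected_prevalence(b0, "S"), 0.5)
  b1 <- disease_trait("t", c(S = 0, Ch = 0), c(S = 0, Ch = 0),
                      intercept = c(S = log(0.26 / 0.74), Ch = 0),
                      batch_sd = 0, farm_sd = 0, sex_diff = 0)
  expect_equal(expected_prevalence(b1, "S"), 0.26, tolerance = 1e-8)
})

test_that("quadrature prevalence matches a large Monte-Carlo draw", {
  # challenging-environment configuration: additive 0.29, litter 0.01
  blk <- disease_trait("t", c(S = 0.29, Ch = 0.29), c(S = 0.01, Ch = 0.01),
                       prevalence = c(S = 0.41, Ch = 0.41), batch_sd = 0,
                       farm_sd = 0, sex_diff = 0)
  mu <- solve_liability_intercept(blk, "Ch", male_fraction = 0.5)
  pq <- expected_prevalence(blk, "Ch")
  expect_equal(pq, 0.41, tolerance = 1e-6)
  set.seed(99)
  n <- 1e6
  z <- stats::rnorm(n, 0, sqrt(0.29 + 0.01))
  pmc <- mean(stats::plogis(mu + z) )
  expect_lt(abs(pq - pmc), 0.003)
})

test_that("realized prevalence tracks the quadrature expectation", {
  cfg <- sim_config(n_sires = 60, n_dams = 250, parities = 3,
                    kits_per_litter = 7, n_batches = 12, seed = 11,
                    composite_resist = FALSE, production = NULL,
                    diseases = default_disease_params()["dig"])
  sim <- simulate_population(cfg)
  an <- sim$phenotypes$animals
  for (e in c("S", "Ch")) {
    sub <- an[an$environment == e, ]
    p_exp <- expected_prevalence(cfg$diseases$dig, e,
                                 cuniqg:::.env_male_fraction(cfg, e))
    se <- sqrt(p_exp * (1 - p_exp) / nrow(sub))
    # allow for between-batch sampling of the finite batch effects as well
    se_batch <- cfg$diseases$dig$batch_sd / sqrt(cfg$n_batches) * 0.25
    expect_lt(abs(mean(sub[[ "dig" ]]) - p_exp), 3 * sqrt(se^2 + se_batch^2))
  }
})

test_that("composite resistance is 1 whenever a component disorder is 1", {
  cfg <- sim_config(n_sires = 20, n_dams = 60, parities = 1,
                    kits_per_litter = 6, n_batches = 6, seed = 12,
                    production = NULL)
  sim <- simulate_population(cfg)
  an <- sim$phenotypes$animals
  expect_true(all(an$resist[an$dig == 1] == 1))
  expect_true(all(an$resist[an$resp == 1] == 1))
  expect_true(all(an$resist[an$other == 1] == 1))
  expect_true(all(an$resist %in% c(0, 1)))
})

test_that("breeding values transmit additively (midparent regression near 1)", {
  cfg <- sim_config(n_sires = 40, n_dams = 150, parities = 2,
                    kits_per_litter = 7, n_batches = 8, seed = 13,
                    composite_resist = FALSE)
  sim <- simulate_population(cfg)
  ped <- sim$pedigree
  tv <- sim$true_values
  ok <- ped$sire_idx > 0 & ped$dam_idx > 0
  for (col in c("ww_direct", "nba")) {
    mp <- 0.5 * (tv[[col]][ped$sire_idx[ok]] + tv[[col]][ped$dam_idx[ok]])
    sl <- stats::coef(stats::lm(tv[[col]][ok] ~ mp))[2]
    expect_lt(abs(sl - 1), 0.12)
  }
  # Mendelian sampling variance about half the additive variance
  res <- tv$ww_direct[ok] -
    0.5 * (tv$ww_direct[ped$sire_idx[ok]] + tv$ww_direct[ped$dam_idx[ok]])
  expect_lt(abs(stats::var(res) / 2986 - 0.5), 0.1)
})

test_that("paternal half-sib means recover the configured G x E correlation", {
  blk <- disease_trait("resist", c(S = 1, Ch = 1), c(S = 0, Ch = 0),
                       prevalence = c(S = 0.3, Ch = 0.45), r_env = 0.7)
  cfg <- sim_config(n_sires = 400, n_dams = 800, parities = 1,
                    kits_per_litter = 4, n_batches = 8, seed = 14,
                    composite_resist = FALSE, production = NULL,
                    fostering_rate = 0, diseases = list(resist = blk))
  sim <- simulate_population(cfg)
  tv <- sim$true_values
  ped <- sim$pedigree
  kits <- ped$sire_idx > 0
  sires <- ped$sire[kits]
  bs <- tapply(tv$resist_S[kits], sires, mean)
  bc <- tapply(tv$resist_Ch[kits], sires, mean)
  # sire-mean true breeding values across environments: correlation
  # approaches r_env as family count grows
  expect_lt(abs(stats::cor(bs, bc) - 0.7), 0.08)
})

test_that("non-PSD trait configurations are rejected before sampling", {
  blk <- disease_trait("bad", c(S = 0.1, Ch = 0.1), c(S = 0, Ch = 0),
                       prevalence = c(S = 0.3, Ch = 0.3), r_env = 1.0)
  blk$r_env <- 1.5  # force an invalid correlation past the constructor
  cfg <- sim_config(n_sires = 5, n_dams = 10, parities = 1,
                    kits_per_litter = 4, n_batches = 2, seed = 1,
                    composite_resist = FALSE, production = NULL,
                    diseases = list(bad = blk))
  expect_error(simulate_population(cfg), "positive semi-definite")
})
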