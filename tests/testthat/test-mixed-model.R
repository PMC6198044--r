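balanced_sire_data <- function(s = 25, n = 16, sigma2_s = 2, sigma2_e = 5,
                               seed = 42) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(s)), each = n)
  y <- rep(stats::rnorm(s, 0, sqrt(sigma2_s)), each = n) +
    stats::rnorm(s * n, 0, sqrt(sigma2_e))
  ped <- as_pedigree(data.frame(animal = sprintf("a%03d", seq_len(s * n)),
                                sire = 0, dam = 0))
  pheno <- list(animals = data.frame(
    animal = sprintf("a%03d", seq_len(s * n)), rearing_litter = g, y = y,
    stringsAsFactors = FALSE))
  list(ped = ped, pheno = pheno, y = y, g = g, s = s, n = n)
}

test_that("REML on a balanced one-way design equals the ANOVA estimator", {
  d <- balanced_sire_data()
  des <- build_design(model_spec("y", random = "litter"), d$ped, d$pheno)
  fit <- reml_fit(des, vcov = FALSE)
  m <- tapply(d$y, d$g, mean)
  MSB <- d$n * stats::var(m)
  MSW <- sum((d$y - stats::ave(d$y, d$g))^2) / (d$s * (d$n - 1))
  expect_lt(abs(fit$varcomp$litter[1, 1] - (MSB - MSW) / d$n), 1e-6)
  expect_lt(abs(fit$varcomp$residual[1, 1] - MSW), 1e-6)
})

test_that("REML matches lme4 on an identity-structure random effect", {
  skip_if_not_installed("lme4")
  d <- balanced_sire_data(s = 18, n = 9, seed = 7)
  des <- build_design(model_spec("y", random = "litter"), d$ped, d$pheno)
  fit <- reml_fit(des, vcov = FALSE)
  lf <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = d$y, g = d$g),
                   REML = TRUE)
  expect_equal(fit$varcomp$litter[1, 1],
               as.numeric(lme4::VarCorr(lf)$g), tolerance = 1e-5)
  expect_equal(fit$varcomp$residual[1, 1],
               attr(lme4::VarCorr(lf), "sc")^2, tolerance = 1e-5)
  expect_equal(fit$neg2, lme4::REMLcrit(lf), tolerance = 1e-6)
})

test_that("solutions satisfy the mixed-model equations", {
  cfg <- small_disease_config(seed = 21, n_sires = 15, n_dams = 45, kits = 5)
  cfg$production <- default_production_params()
  sim <- simulate_population(cfg)
  des <- build_design(model_spec("ww", fixed = c("batch", "sex"),
                                 random = c("animal", "litter")),
                      sim$pedigree, sim$phenotypes)
  fit <- reml_fit(des, vcov = FALSE)
  expect_lt(mme_residual(fit), 1e-8)
})

test_that("a constant response drives the additive variance to the boundary", {
  ped <- random_mating_ped(8, 30, gens = 2, seed = 3)
  pheno <- list(animals = data.frame(animal = ped$animal,
                                     y = 5, stringsAsFactors = FALSE))
  des <- build_design(model_spec("y", random = "animal"), ped, pheno)
  fit <- reml_fit(des, vcov = FALSE)
  expect_lt(fit$varcomp$genetic[1, 1], 1e-6)
  expect_true(length(fit$boundary) > 0)
})

test_that("the reported optimum beats random parameter perturbations", {
  d <- balanced_sire_data(s = 15, n = 8, seed = 9)
  des <- build_design(model_spec("y", random = "litter"), d$ped, d$pheno)
  fit <- reml_fit(des, vcov = FALSE)
  set.seed(1)
  for (k in 1:50) {
    vc <- fit$varcomp
    vc$litter[1, 1] <- vc$litter[1, 1] * exp(stats::rnorm(1, 0, 0.4)) + 1e-6
    vc$residual[1, 1] <- vc$residual[1, 1] * exp(stats::rnorm(1, 0, 0.4))
    ll <- reml_loglik_at(fit, vc)
    expect_lte(ll, fit$loglik + 1e-6)
  }
})

test_that("bivariate REML recovers a zero genetic correlation on average", {
  # two traits measured on the same animals, zero genetic correlation
  rgs <- replicate(8, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    ns <- 30; nk <- 5
    sire <- sprintf("s%02d", seq_len(ns))
    kid <- sprintf("k%03d", seq_len(ns * nk))
    ped <- as_pedigree(data.frame(
      animal = c(sire, kid), sire = c(rep(0, ns), rep(sire, each = nk)),
      dam = 0, stringsAsFactors = FALSE))
    a1 <- stats::rnorm(ns, 0, 1); a2 <- stats::rnorm(ns, 0, 1)
    idx <- rep(seq_len(ns), each = nk)
    y1 <- 0.5 * a1[idx] + stats::rnorm(ns * nk, 0, sqrt(1 - 0.25))
    y2 <- 0.5 * a2[idx] + stats::rnorm(ns * nk, 0, sqrt(1 - 0.25))
    pheno <- list(animals = data.frame(animal = kid, y1 = y1, y2 = y2,
                                       stringsAsFactors = FALSE))
    des <- build_design(list(model_spec("y1", random = "animal"),
                             model_spec("y2", random = "animal")),
                        ped, pheno)
    fit <- reml_fit(des, vcov = FALSE,
                    control = list(maxit = 500, polish = FALSE))
    G <- fit$varcomp$genetic
    G[1, 2] / sqrt(max(G[1, 1] * G[2, 2], 1e-12))
  })
  se <- stats::sd(rgs) / sqrt(length(rgs))
  expect_lt(abs(mean(rgs)), 2 * se + 0.05)
})

test_that("cross-environment traits have residual covariance fixed at zero", {
  cfg <- small_disease_config(seed = 31, n_sires = 20, n_dams = 60)
  cfg$fraction_batches_ch <- 0.5
  cfg$male_fraction_ch <- 0.5
  sim <- simulate_population(cfg)
  des <- build_design(list(
    model_spec("resist", random = "animal", environment = "S"),
    model_spec("resist", random = "animal", environment = "Ch")),
    sim$pedigree, sim$phenotypes)
  # no animal is recorded in both environments
  expect_false(any(duplicated(des$units)))
  fit <- reml_fit(des, vcov = FALSE, control = list(maxit = 400))
  expect_identical(fit$residual_cov, FALSE)
  expect_equal(fit$varcomp$residual[1, 2], 0)
})
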