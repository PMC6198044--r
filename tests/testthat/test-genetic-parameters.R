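test_that("variance ratios reproduce the reference liability and production cells", {
  # liability convention: sigma2_p = sigma2_a + sigma2_litter + pi^2/3
  expect_equal(round(variance_ratio(0.15, liability_sigma2_p(0.15, 0.14)), 2),
               0.04)
  expect_equal(round(variance_ratio(0.42, liability_sigma2_p(0.42, 0.04)), 2),
               0.11)
  # production traits: repeatability (1.71 + 0.32) / 10.49 and NBA h2
  expect_equal(round(variance_ratio(c(1.71, 0.32), 10.49), 2), 0.19)
  expect_equal(round(variance_ratio(1.71, 10.49), 2), 0.16)
  expect_equal(variance_ratio(0, 3), 0)
  expect_error(variance_ratio(1, 0), "positive")
})

test_that("mixture LRT p-values follow the 50:50 chi-square mixture", {
  expect_equal(mixture_lrt_pvalue(0, 0), 0.5)
  expect_equal(mixture_lrt_pvalue(2.706, 0), 0.05, tolerance = 1e-3)
  # quadrature oracle for q = 1
  T <- 10
  p_num <- 0.5 * stats::integrate(function(x) stats::dchisq(x, 1), T, Inf,
                                  rel.tol = 1e-12)$value +
    0.5 * stats::integrate(function(x) stats::dchisq(x, 2), T, Inf,
                           rel.tol = 1e-12)$value
  expect_equal(mixture_lrt_pvalue(T, 1), p_num, tolerance = 1e-9)
  expect_error(mixture_lrt_pvalue(-1, 0), "non-negative")
})

test_that("mixture LRT p-value is monotone in T and bracketed by plain chi-squares", {
  Ts <- seq(0.01, 15, length.out = 40)
  for (q in 0:2) {
    ps <- vapply(Ts, mixture_lrt_pvalue, 0, q = q)
    expect_true(all(diff(ps) < 0))
    # the 50:50 mixture lies between the two plain chi-square tails
    lower <- if (q == 0) rep(0, length(Ts)) else
      stats::pchisq(Ts, q, lower.tail = FALSE)
    upper <- stats::pchisq(Ts, q + 1, lower.tail = FALSE)
    expect_true(all(ps >= lower - 1e-12))
    expect_true(all(ps <= upper + 1e-12))
  }
})

test_that("heritability comparison t-test matches hand arithmetic", {
  r <- compare_h2(0.5, 0.1, 0.2, 0.1)
  expect_equal(r$t, 0.3 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(r$t, 2.1213, tolerance = 1e-4)
  r0 <- compare_h2(0.3, 0.05, 0.3, 0.07)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # S vs Ch disease heritabilities: not significantly different
  rsc <- compare_h2(0.04, 0.01, 0.08, 0.02)
  expect_lt(abs(rsc$t), 2)
  expect_gt(rsc$p, 0.05)
})

fit_for_se <- function(seed = 33) {
  d <- local({
    set.seed(seed)
    s <- 40; n <- 10
    g <- rep(sprintf("g%02d", seq_len(s)), each = n)
    y <- rep(stats::rnorm(s, 0, sqrt(2)), each = n) +
      stats::rnorm(s * n, 0, sqrt(4))
    ped <- as_pedigree(data.frame(animal = sprintf("a%03d", seq_len(s * n)),
                                  sire = 0, dam = 0))
    pheno <- list(animals = data.frame(
      animal = sprintf("a%03d", seq_len(s * n)), rearing_litter = g, y = y,
      stringsAsFactors = FALSE))
    build_design(model_spec("y", random = "litter"), ped, pheno)
  })
  reml_fit(d)
}

test_that("sampling SE of a ratio agrees with the delta method and is reproducible", {
  fit <- fit_for_se()
  h2ish <- function(v) v[["litter:var(y:litter)"]] /
    (v[["litter:var(y:litter)"]] + v[["residual:y"]])
  s1 <- sample_parameter_se(fit, h2ish, n_draws = 10000, seed = 7)
  s2 <- sample_parameter_se(fit, h2ish, n_draws = 10000, seed = 7)
  expect_identical(s1$se, s2$se)
  dm <- delta_method_se(fit, h2ish)
  expect_lt(abs(s1$se - dm) / dm, 0.10)
  expect_true(is.finite(s1$normal_p))

  # zero sampling covariance -> SE exactly 0
  fit0 <- fit
  fit0$vcov_varcomp <- fit$vcov_varcomp * 0
  expect_equal(sample_parameter_se(fit0, h2ish, n_draws = 100, seed = 1)$se, 0)
})

test_that("sampling SE converges to the delta-method SE as covariance shrinks", {
  fit <- fit_for_se()
  h2ish <- function(v) v[["litter:var(y:litter)"]] /
    (v[["litter:var(y:litter)"]] + v[["residual:y"]])
  dm_full <- delta_method_se(fit, h2ish)
  rel_err <- vapply(c(1, 0.25, 0.01), function(sc) {
    f <- fit
    f$vcov_varcomp <- fit$vcov_varcomp * sc
    se <- sample_parameter_se(f, h2ish, n_draws = 20000, seed = 11)$se
    abs(se - dm_full * sqrt(sc)) / (dm_full * sqrt(sc))
  }, 0)
  expect_true(all(diff(rel_err) < 0.05))  # shrinking covariance: closer to delta
  expect_lt(rel_err[3], 0.03)
})

test_that("assembled reports are internally consistent with variance_ratio", {
  cfg <- small_disease_config(seed = 41, n_sires = 25, n_dams = 75)
  sim <- simulate_population(cfg)
  fit <- fit_threshold_trait(build_design(
    model_spec("resist", random = c("animal", "litter"), link = "logit",
               environment = "S"), sim$pedigree, sim$phenotypes),
    vcov = FALSE)
  rep <- assemble_report(list(resist_S = fit), n_draws = 0)
  row <- rep$components[1, ]
  expect_equal(row$h2,
               variance_ratio(row$sigma2_a,
                              liability_sigma2_p(row$sigma2_a,
                                                 row$sigma2_litter)))
  expect_equal(row$sigma2_e, pi^2 / 3)

  # single-trait report has a trivial 1x1 correlation structure
  expect_null(rep$correlations)
})

test_that("h2 + litter ratio never exceeds 1 under the declared convention", {
  for (seed in c(51, 52)) {
    cfg <- small_disease_config(seed = seed, n_sires = 20, n_dams = 60)
    sim <- simulate_population(cfg)
    fit <- fit_threshold_trait(build_design(
      model_spec("resist", random = c("animal", "litter"), link = "logit",
                 environment = "S"), sim$pedigree, sim$phenotypes),
      vcov = FALSE)
    l <- liability_h2(fit)
    expect_lte(l$h2 + l$c2, 1)
    expect_gte(l$h2, 0)
  }
})
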