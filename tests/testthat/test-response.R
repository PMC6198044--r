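test_that("selection intensity matches truncated-normal quadrature", {
  expect_equal(selection_intensity(1), 0)
  # oracle: E[z | z > q] by numerical integration
  for (p in c(0.15, 0.25, 0.5)) {
    q <- stats::qnorm(1 - p)
    oracle <- stats::integrate(function(z) z * stats::dnorm(z), q, Inf,
                               rel.tol = 1e-12)$value / p
    expect_equal(selection_intensity(p), oracle, tolerance = 1e-9)
  }
  # finite candidate numbers reduce the intensity
  expect_lt(selection_intensity(0.25, N = 490), selection_intensity(0.25))
  expect_lt(selection_intensity(0.15, N = 50),
            selection_intensity(0.15, N = 5000))
  # correlated candidates reduce it further
  expect_lt(selection_intensity(0.25, N = 490, rho = 0.3),
            selection_intensity(0.25, N = 490))
  expect_error(selection_intensity(0), "fraction")
})

mass_selection_setup <- function() {
  p <- default_scheme_params()
  G <- p$G * 0
  G["WW_direct", "WW_direct"] <- 2986
  p$G <- G
  p$env$WW$sigma2_litter <- 0
  p$env$WW$sigma2_matenv <- 0
  sc <- scheme_config(use_sib_records = FALSE, use_dam_nba = FALSE,
                      parent_index = FALSE, bulmer = FALSE,
                      selected_fraction_males = 0.15,
                      selected_fraction_females = 0.15)
  list(p = p, sc = sc, obj = breeding_objective("WW", c(WW_direct = 1)))
}

test_that("mass selection on one trait matches a 50,000-animal stochastic oracle", {
  ms <- mass_selection_setup()
  r <- predict_response(ms$sc, ms$p, ms$obj)
  pred <- r$response[["WW_direct"]]
  set.seed(9)
  n <- 50000
  a <- stats::rnorm(n, 0, sqrt(2986))
  ph <- a + stats::rnorm(n, 0, sqrt(ms$p$env$WW$sigma2_e))
  sel <- ph >= stats::quantile(ph, 1 - 0.15)
  obs <- mean(a[sel])
  mc_se <- stats::sd(a[sel]) / sqrt(sum(sel))
  expect_lt(abs(pred - obs), 4 * mc_se + 0.015 * obs)
  # and the closed form i h2 sigma_p
  s2p <- 2986 + ms$p$env$WW$sigma2_e
  i <- selection_intensity(0.15, 35 / 0.15)
  expect_equal(pred, i * 2986 / sqrt(s2p), tolerance = 1e-2)
})

test_that("zero genetic variance gives zero response everywhere", {
  p <- default_scheme_params()
  p$G <- p$G * 0
  r <- predict_response(scheme_config(), p,
                        default_breeding_objectives()$HProduction)
  expect_true(all(r$response == 0))
  expect_equal(r$accuracy, 0)
})

test_that("responses are invariant to rescaling the objective weights", {
  p <- default_scheme_params()
  o1 <- default_breeding_objectives()$HResist_S_Ch
  o2 <- breeding_objective("x", 3.7 * o1$weights)
  sc <- scheme_config(record_resist_s = TRUE, record_resist_ch = TRUE)
  r1 <- predict_response(sc, p, o1)
  r2 <- predict_response(sc, p, o2)
  expect_equal(r1$response, r2$response, tolerance = 1e-10)
})

test_that("the Bulmer recursion shrinks genetic variance and converges", {
  p <- default_scheme_params()
  sc <- scheme_config()
  r <- predict_response(sc, p, default_breeding_objectives()$HProduction)
  expect_lt(r$iterations, 60)
  # equilibrium genetic variance of the trait under direct pressure is
  # below its base value
  expect_lt(r$G_eq["WW_direct", "WW_direct"], p$G["WW_direct", "WW_direct"])
  # without Bulmer the response is larger
  sc0 <- scheme_config(bulmer = FALSE)
  r0 <- predict_response(sc0, p, default_breeding_objectives()$HProduction)
  expect_gt(r0$response[["WW_direct"]], r$response[["WW_direct"]])
})

test_that("adding information sources never decreases index accuracy", {
  p <- default_scheme_params()
  obj <- default_breeding_objectives()$HResist_S_Ch
  acc <- function(...) {
    sc <- scheme_config(record_resist_s = TRUE, ...)
    predict_response(sc, p, obj)$accuracy
  }
  a_own <- acc(use_sib_records = FALSE, parent_index = FALSE)
  a_sib <- acc(use_sib_records = TRUE, parent_index = FALSE)
  a_par <- acc(use_sib_records = TRUE, parent_index = TRUE)
  a_ch <- acc(use_sib_records = TRUE, parent_index = TRUE,
              record_resist_ch = TRUE)
  expect_gte(a_sib, a_own - 1e-10)
  expect_gte(a_par, a_sib - 1e-10)
  expect_gte(a_ch, a_par - 1e-10)
})

test_that("recording the challenging environment raises its response", {
  p <- default_scheme_params()
  for (nm in c("HResist_S", "HResist_Ch", "HResist_S_Ch")) {
    obj <- default_breeding_objectives()[[nm]]
    r_yes <- predict_response(scheme_config(record_resist_s = TRUE,
                                            record_resist_ch = TRUE), p, obj)
    r_no <- predict_response(scheme_config(record_resist_s = TRUE,
                                           record_resist_ch = FALSE), p, obj)
    expect_gt(abs(r_yes$response[["Resist_Ch"]]),
              abs(r_no$response[["Resist_Ch"]]))
  }
})

test_that("production-only selection gives no disease response without correlation", {
  p <- default_scheme_params()
  G <- p$G
  for (tr in c("Resist_S", "Resist_Ch")) {
    G[tr, setdiff(colnames(G), tr)] <- 0
    G[setdiff(colnames(G), tr), tr] <- 0
  }
  p$G <- G
  r <- predict_response(scheme_config(), p,
                        default_breeding_objectives()$HProduction)
  expect_equal(unname(r$response["Resist_S"]), 0, tolerance = 1e-10)
  expect_equal(unname(r$response["Resist_Ch"]), 0, tolerance = 1e-10)
  # with the reference (negative) correlation signs the correlated disease
  # response is favourable
  r2 <- predict_response(scheme_config(), default_scheme_params(),
                         default_breeding_objectives()$HProduction)
  expect_lt(r2$response[["Resist_S"]], 0)
  expect_lt(r2$response[["Resist_Ch"]], 0)
})

test_that("a redundant information source raises a singularity error", {
  p <- default_scheme_params()
  sc <- scheme_config()
  # duplicate the own-WW source by zeroing all variances -> P singular
  p$G <- p$G * 0
  p$env$WW$sigma2_litter <- 0
  p$env$WW$sigma2_matenv <- 0
  p$env$WW$sigma2_e <- 0
  p$env$Resist_S$sigma2_e <- 0
  p$env$Resist_Ch$sigma2_e <- 0
  p$env$NBA$sigma2_e <- 0
  p$env$NBA$sigma2_pe <- 0
  expect_error(predict_response(sc, p,
                                default_breeding_objectives()$HProduction),
               "singular")
})
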