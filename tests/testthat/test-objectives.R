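test_that("objective covariance is the printed bilinear form", {
  G1 <- matrix(4, 1, 1, dimnames = list("t1", "t1"))
  w <- breeding_objective("w", c(t1 = 1))
  expect_equal(objective_covariance(w, w, G1), 4)

  # disjoint single-trait objectives on uncorrelated traits
  G2 <- diag(c(4, 9)); dimnames(G2) <- list(c("a", "b"), c("a", "b"))
  wa <- breeding_objective("wa", c(a = 1))
  wb <- breeding_objective("wb", c(b = 1))
  expect_equal(objective_covariance(wa, wb, G2), 0)

  # hand-expanded 2-trait case: v1=4, v2=9, cov=3, Wi=(1,1), Wj=(2,0)
  G3 <- matrix(c(4, 3, 3, 9), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  wi <- breeding_objective("wi", c(a = 1, b = 1))
  wj <- breeding_objective("wj", c(a = 2, b = 0))
  expect_equal(objective_covariance(wi, wj, G3), 14)
  expect_equal(objective_covariance(wj, wi, G3), 14)  # symmetry

  expect_error(objective_covariance(
    breeding_objective("bad", c(zzz = 1)), wj, G3), "absent")
})

test_that("objective correlation has unit diagonal, sign symmetry and scale invariance", {
  G <- default_scheme_params()$G
  objs <- default_breeding_objectives()
  expect_equal(objective_correlation(objs$HProduction, objs$HProduction, G), 1)
  neg <- breeding_objective("neg", -objs$HProduction$weights)
  expect_equal(objective_correlation(objs$HProduction, neg, G), -1)
  scaled <- breeding_objective("s", 17.3 * objs$HResist_S$weights)
  expect_equal(objective_correlation(objs$HProduction, scaled, G),
               objective_correlation(objs$HProduction, objs$HResist_S, G),
               tolerance = 1e-12)
  expect_error(objective_correlation(
    breeding_objective("zero", c(NBA = 0)), objs$HProduction, G),
    "zero-variance")
})

test_that("|correlation| <= 1 on random PSD genetic matrices", {
  set.seed(55)
  for (k in seq_len(1000)) {
    t <- sample(2:5, 1)
    L <- matrix(stats::rnorm(t * t), t, t)
    G <- crossprod(L) + diag(1e-8, t)
    dimnames(G) <- list(paste0("t", 1:t), paste0("t", 1:t))
    wi <- breeding_objective("wi", stats::setNames(stats::rnorm(t), paste0("t", 1:t)))
    wj <- breeding_objective("wj", stats::setNames(stats::rnorm(t), paste0("t", 1:t)))
    r <- objective_correlation(wi, wj, G)
    expect_lte(abs(r), 1)
  }
})

test_that("the four reference objectives are mutually positively correlated", {
  # configured G in which the weighted disease terms contribute about as
  # much objective variance as the production block (the scale consistent
  # with the reported objective-correlation table): all pairwise
  # correlations are at least 0.7
  p <- default_scheme_params()
  G <- p$G
  for (tr in c("Resist_S", "Resist_Ch")) {
    f <- 0.05 / sqrt(p$G[tr, tr])
    G[tr, ] <- G[tr, ] * f
    G[, tr] <- G[, tr] * f
    G[tr, tr] <- 0.05^2
  }
  M <- objective_correlation_table(default_breeding_objectives(), G)
  expect_true(all(M >= 0.7))
  expect_true(all(diag(M) == 1))
  # the combined objective correlates most strongly with its two parents
  expect_gt(M["HResist_S_Ch", "HResist_S"], M["HProduction", "HResist_S"])
  expect_gt(M["HResist_S_Ch", "HResist_Ch"], M["HProduction", "HResist_Ch"])
})

test_that("desired-gains search is a fixed point at the base objective's own gains", {
  p <- default_scheme_params()
  sc <- scheme_config()
  base <- default_breeding_objectives()$HProduction
  own <- predict_response(sc, p, base)$response[c("NBA", "WW_direct")]
  out <- desired_gains_search(base, own, sc, p)
  expect_true(attr(out, "converged"))
  expect_equal(out$weights, base$weights, tolerance = 1e-8)
})

test_that("raising a desired gain does not shrink the trait's weight", {
  p <- default_scheme_params()
  sc <- scheme_config(record_resist_s = TRUE)
  base <- default_breeding_objectives()$HResist_S
  r0 <- predict_response(sc, p, base)$response
  # ask for progressively more Resist_S improvement (more negative gain)
  w_resist <- vapply(c(1, 1.15, 1.3), function(f) {
    targ <- c(Resist_S = unname(r0["Resist_S"]) * f,
              WW_direct = unname(r0["WW_direct"]))
    out <- desired_gains_search(base, targ, sc, p, tol = 0.05)
    abs(out$weights[["Resist_S"]])
  }, 0)
  expect_true(all(diff(w_resist) > -1e-6))
})

test_that("the sign pattern of the combined-improvement objective is recovered", {
  # target: improve Resist in both environments, increase WW, stable NBA
  p <- default_scheme_params()
  sc <- scheme_config(record_resist_s = TRUE, record_resist_ch = TRUE)
  start <- default_breeding_objectives()$HResist_S_Ch
  r0 <- predict_response(sc, p, start)$response
  # feasible nearby targets: stable NBA, a bit more weaning weight, disease
  # responses held at their achieved values
  targ <- c(NBA = 0, WW_direct = unname(r0[["WW_direct"]]) * 1.1,
            Resist_S = unname(r0[["Resist_S"]]),
            Resist_Ch = unname(r0[["Resist_Ch"]]))
  out <- desired_gains_search(start, targ, sc, p, tol = 0.1, max_iter = 25)
  w <- out$weights
  expect_gt(w[["NBA"]], 0)
  expect_gt(w[["WW_direct"]], 0)
  expect_lt(w[["Resist_S"]], 0)
  expect_lt(w[["Resist_Ch"]], 0)
})
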