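#' Threshold (liability) model for a binary trait
#'
#' Fits a generalized linear animal model with a logit link by penalized
#' quasi-likelihood: the binary response is repeatedly linearized to a
#' working variable `z = eta + (y - mu) / (mu (1 - mu))` with working
#' weights `w = mu (1 - mu)`, and the variance components of the liability
#' are re-estimated by [reml_fit()] on the working model (residual dispersion
#' fixed at 1) until the joint fit stabilizes. Estimated additive and litter
#' variances are on the logit-liability scale, on which the residual
#' variance is pi^2/3 and the phenotypic variance convention is
#' `sigma2_p = sigma2_a + sigma2_litter + pi^2/3`.
#'
#' @param design A [build_design()] bundle for a single binary trait.
#' @param max_outer Maximum PQL (re-linearization) iterations.
#' @param tol Convergence tolerance on the linear predictor.
#' @param vcov Compute the sampling covariance of the variance components at
#'   the final working model.
#' @param control Passed to [reml_fit()] for the final inner fit.
#' @return A `cuni_fit` with additional fields `link = "logit"`, `mu`
#'   (fitted probabilities) and `outer_iter`.
#' @export
fit_threshold_trait <- function(design, max_outer = 25, tol = 1e-5,
                                vcov = TRUE, control = list()) {
  stopifnot(inherits(design, "cuni_design"))
  y <- design$y
  if (length(design$traits) != 1)
    stop("threshold fits are single-trait")
  if (!all(y %in% c(0, 1))) stop("threshold models require a 0/1 response")
  if (all(y == 0) || all(y == 1))
    stop("response is constant (all ", y[1], "); liability model undefined")
  # complete separation check per fixed factor
  X <- design$X
  for (fac in unique(design$assign)) {
    if (grepl("(Intercept)", fac, fixed = TRUE)) next
    cols <- which(design$assign == fac)
    for (cc in cols) {
      lv <- X[, cc] > 0
      if (sum(lv) > 0 && (all(y[lv] == 0) || all(y[lv] == 1))) {
        # a level with constant response in the corner parameterization is
        # only separated if the response is constant at 0 or 1 there AND
        # differs from the remainder; flag the factor
        if (length(unique(y[!lv])) == 1 && unique(y[lv]) != unique(y[!lv]))
          stop("complete separation by fixed factor '", fac, "'")
      }
    }
  }

  # start from the fixed-effects-only logistic regression
  g0 <- stats::glm.fit(X, y, family = stats::binomial())
  eta <- g0$linear.predictors
  fit <- NULL
  start <- NULL
  for (it in seq_len(max_outer)) {
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    dwork <- design
    dwork$y <- z
    last <- it == max_outer
    fit <- reml_fit(dwork, start = start, fix_residual = 1, weights = w,
                    vcov = FALSE,
                    control = utils::modifyList(list(maxit = 400,
                                                     polish = FALSE), control))
    start <- fit$varcomp
    eta_new <- .fitted_eta(fit, dwork)
    delta <- max(abs(eta_new - eta)) / max(1, max(abs(eta_new)))
    eta <- eta_new
    if (delta < tol) break
  }
  # final high-precision inner fit at the converged linearization
  mu <- pmin(pmax(stats::plogis(eta), 1e-6), 1 - 1e-6)
  w <- mu * (1 - mu)
  z <- eta + (y - mu) / w
  dwork <- design
  dwork$y <- z
  fit <- reml_fit(dwork, start = start, fix_residual = 1, weights = w,
                  vcov = vcov, control = control)
  fit$link <- "logit"
  fit$mu <- stats::plogis(.fitted_eta(fit, dwork))
  fit$outer_iter <- it
  fit
}

.fitted_eta <- function(fit, design) {
  eta <- as.vector(design$X %*% fit$fixef)
  for (g in names(design$terms)) {
    tm <- design$terms[[g]]
    eta <- eta + as.vector(tm$Z %*% as.vector(fit$ranef[[g]]))
  }
  eta
}

#' Liability-scale heritability of a threshold fit
#'
#' @param fit A [fit_threshold_trait()] result.
#' @return List with `h2`, `c2` (common litter) and `sigma2_p` under the
#'   logistic-residual convention.
#' @export
liability_h2 <- function(fit) {
  stopifnot(identical(fit$link, "logit"))
  s2a <- if (!is.null(fit$varcomp$genetic)) fit$varcomp$genetic[1, 1] else 0
  s2c <- if (!is.null(fit$varcomp$litter)) fit$varcomp$litter[1, 1] else 0
  s2p <- s2a + s2c + pi^2 / 3
  list(h2 = s2a / s2p, c2 = s2c / s2p, sigma2_p = s2p)
}
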