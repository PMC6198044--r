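#' Wald F test for dropping a fixed factor
#'
#' Tests the joint nullity of all estimable coefficients of a fixed factor
#' in a fitted model, using the fixed-effect covariance from the inverse
#' mixed-model-equation coefficient matrix. The denominator degrees of
#' freedom use a containment-style approximation, `n - rank(X)`.
#'
#' @param fit A [reml_fit()] or [fit_threshold_trait()] result.
#' @param factor Name of the fixed factor (as given in the model spec; for
#'   multi-trait fits use the `"label:factor"` form).
#' @return List with `F`, `ndf`, `ddf` and `p`.
#' @export
wald_f_test <- function(fit, factor) {
  asg <- fit$design$assign
  hit <- asg == factor
  if (!any(hit)) {
    short <- sub("^[^:]*:", "", asg)
    hit <- short == factor
  }
  if (!any(hit))
    stop("factor '", factor, "' is not in the fitted model (it may have ",
         "been absorbed by identifiability constraints)")
  b <- fit$fixef[hit]
  V <- fit$vcov_fixef[hit, hit, drop = FALSE]
  q <- length(b)
  Fstat <- as.numeric(crossprod(b, solve(V, b))) / q
  ddf <- fit$n - fit$p
  list(F = Fstat, ndf = q, ddf = ddf,
       p = stats::pf(Fstat, q, ddf, lower.tail = FALSE))
}

#' Backward stepwise selection of fixed effects by Wald F
#'
#' Starting from the full candidate set, repeatedly refits the model and
#' drops the factor with the largest Wald-F p-value until every retained
#' factor is significant at `alpha`.
#'
#' @param spec A single-trait [model_spec()] whose `fixed` lists the
#'   candidate factors.
#' @param ped,pheno Passed to [build_design()].
#' @param alpha Retention threshold (default 0.05).
#' @param ... Passed to the fitting function ([reml_fit()] for identity
#'   link, [fit_threshold_trait()] for logit).
#' @return The spec with `fixed` reduced to the retained factors; attribute
#'   `"trace"` records the drop sequence and p-values.
#' @export
stepwise_select <- function(spec, ped, pheno, alpha = 0.05, ...) {
  stopifnot(inherits(spec, "cuni_model_spec"))
  trace <- list()
  repeat {
    if (!length(spec$fixed)) break
    design <- build_design(spec, ped, pheno)
    fit <- if (spec$link == "logit")
      fit_threshold_trait(design, vcov = FALSE, ...)
    else reml_fit(design, vcov = FALSE, ...)
    pv <- vapply(spec$fixed, function(f) wald_f_test(fit, f)$p, 0)
    worst <- which.max(pv)
    if (pv[worst] < alpha) break
    trace[[length(trace) + 1L]] <- list(dropped = spec$fixed[worst],
                                        p = unname(pv[worst]))
    spec$fixed <- spec$fixed[-worst]
  }
  attr(spec, "trace") <- trace
  spec
}
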