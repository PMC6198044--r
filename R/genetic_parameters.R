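#' Variance ratio (heritability, common-litter, repeatability, ...)
#'
#' Computes `sum(numerator) / sigma2_p`. For threshold (logit) traits the
#' phenotypic-variance convention is
#' `sigma2_p = sigma2_a + sigma2_litter + pi^2/3`.
#'
#' @param numerator Variance component(s) to sum in the numerator.
#' @param sigma2_p Phenotypic variance (must be positive).
#' @return The ratio.
#' @export
variance_ratio <- function(numerator, sigma2_p) {
  if (!is.numeric(sigma2_p) || length(sigma2_p) != 1 || sigma2_p <= 0)
    stop("sigma2_p must be a single positive number")
  sum(numerator) / sigma2_p
}

#' Liability-scale phenotypic variance under the logistic-residual convention
#'
#' @param sigma2_a Additive liability variance.
#' @param sigma2_litter Common-litter liability variance.
#' @return `sigma2_a + sigma2_litter + pi^2/3`.
#' @export
liability_sigma2_p <- function(sigma2_a, sigma2_litter = 0) {
  sigma2_a + sigma2_litter + pi^2 / 3
}

#' Sampling-based standard error of a variance-component function
#'
#' Draws parameter vectors from a multivariate Gaussian centred at the REML
#' estimates with the fit's sampling covariance, re-evaluates a scalar
#' function of the components (e.g. a heritability) for each draw, and
#' reports the standard deviation of the draws as the standard error.
#' Draws with any negative variance are rejected and redrawn, so ratios stay
#' defined. Normality of the draw distribution is assessed with a
#' skewness/kurtosis omnibus (Jarque-Bera type) test; the result is reported
#' but never gates the SE.
#'
#' @param fit A [reml_fit()] / [fit_threshold_trait()] result with
#'   `vcov_varcomp`.
#' @param expression A function taking a named numeric vector of variance
#'   components (names as in the rows of `fit$vcov_varcomp`) and returning a
#'   scalar.
#' @param n_draws Number of Monte-Carlo draws (the reference analysis uses
#'   10,000).
#' @param seed Integer seed for reproducibility.
#' @return List with `se`, `mean`, `draws` (invisibly usable), `normal_p`
#'   (omnibus normality p-value) and `normal` (not rejected at 5%).
#' @export
sample_parameter_se <- function(fit, expression, n_draws = 10000, seed = 1) {
  V <- fit$vcov_varcomp
  if (is.null(V) || anyNA(V))
    stop("fit has no usable sampling covariance of the variance components")
  mu <- .vc_natural(fit$varcomp, fit$residual_cov, !is.null(fit$fix_residual))
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values))) {
    warning("sampling covariance projected to nearest positive semi-definite")
    ev$values <- pmax(ev$values, 0)
    V <- ev$vectors %*% diag(ev$values, nrow(V)) %*% t(ev$vectors)
    dimnames(V) <- list(names(mu), names(mu))
  }
  if (sum(abs(V)) == 0) {
    val <- expression(mu)
    return(list(se = 0, mean = val, draws = rep(val, 0), normal_p = NA_real_,
                normal = NA))
  }
  set.seed(seed)
  is_var <- grepl(":var\\(", names(mu)) |
    (grepl("^residual:", names(mu)) & !grepl("^residual:cov\\(", names(mu)))
  draws <- matrix(NA_real_, 0, length(mu))
  max_tries <- 50L
  tries <- 0L
  while (nrow(draws) < n_draws && tries < max_tries) {
    need <- n_draws - nrow(draws)
    cand <- MASS::mvrnorm(ceiling(need * 1.2) + 10, mu = mu, Sigma = V)
    ok <- apply(cand[, is_var, drop = FALSE] >= 0, 1, all)
    draws <- rbind(draws, cand[ok, , drop = FALSE])
    tries <- tries + 1L
  }
  if (nrow(draws) < n_draws)
    stop("could not obtain enough non-negative-variance draws")
  draws <- draws[seq_len(n_draws), , drop = FALSE]
  colnames(draws) <- names(mu)
  vals <- apply(draws, 1, expression)
  jb <- .jarque_bera(vals)
  list(se = stats::sd(vals), mean = mean(vals), draws = vals,
       normal_p = jb, normal = !is.na(jb) && jb >= 0.05)
}

# skewness/kurtosis omnibus normality test
.jarque_bera <- function(x) {
  n <- length(x)
  if (n < 8 || stats::sd(x) == 0) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  sk <- mean((x - m)^3) / s2^1.5
  ku <- mean((x - m)^4) / s2^2
  jb <- n / 6 * (sk^2 + (ku - 3)^2 / 4)
  stats::pchisq(jb, df = 2, lower.tail = FALSE)
}

#' Delta-method standard error of a variance-component function
#'
#' First-order Taylor SE, used as the small-covariance oracle for
#' [sample_parameter_se()].
#'
#' @inheritParams sample_parameter_se
#' @return The delta-method SE.
#' @export
delta_method_se <- function(fit, expression) {
  V <- fit$vcov_varcomp
  mu <- .vc_natural(fit$varcomp, fit$residual_cov, !is.null(fit$fix_residual))
  h <- pmax(abs(mu) * 1e-5, 1e-9)
  g <- vapply(seq_along(mu), function(i) {
    up <- mu; up[i] <- mu[i] + h[i]
    dn <- mu; dn[i] <- mu[i] - h[i]
    (expression(up) - expression(dn)) / (2 * h[i])
  }, 0)
  sqrt(max(0, as.numeric(t(g) %*% V %*% g)))
}

#' Student's t comparison of two heritabilities
#'
#' Two-sided t-test of `h2_a - h2_b` with standard error
#' `sqrt(SE_a^2 + SE_b^2)` and Welch-Satterthwaite degrees of freedom based
#' on the sampling draws behind each SE.
#'
#' @param h2_a,h2_b Heritability estimates.
#' @param se_a,se_b Their standard errors (must be positive).
#' @param df_a,df_b Degrees of freedom behind each SE (default
#'   `n_draws - 1 = 9999`).
#' @return List with `t`, `df` and `p`.
#' @export
compare_h2 <- function(h2_a, se_a, h2_b, se_b, df_a = 9999, df_b = 9999) {
  stopifnot(se_a > 0, se_b > 0)
  t <- (h2_a - h2_b) / sqrt(se_a^2 + se_b^2)
  df <- (se_a^2 + se_b^2)^2 / (se_a^4 / df_a + se_b^4 / df_b)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Boundary likelihood-ratio p-value (50:50 chi-square mixture)
#'
#' For a test of a parameter on the boundary of its space (a variance equal
#' to 0, or a correlation equal to 1), the LRT statistic is compared to a
#' 50:50 mixture of chi-square distributions with `q` and `q + 1` degrees of
#' freedom, where `q` is the number of random effects in the reduced model
#' (residual excluded) and chi-square with 0 df is a point mass at zero.
#'
#' @param T Likelihood-ratio statistic (non-negative).
#' @param q Number of random effects in the reduced model.
#' @return The mixture p-value.
#' @export
mixture_lrt_pvalue <- function(T, q) {
  if (!is.numeric(T) || any(T < 0)) stop("LRT statistic must be non-negative")
  stopifnot(q >= 0)
  p_q <- if (q == 0) as.numeric(T < 0) else
    stats::pchisq(T, df = q, lower.tail = FALSE)
  0.5 * p_q + 0.5 * stats::pchisq(T, df = q + 1, lower.tail = FALSE)
}

#' Assemble a genetic-parameter report
#'
#' Turns a collection of fits into the reported quantities: variance
#' components, ratios under the declared phenotypic-variance convention with
#' sampling SEs, and correlation matrices (genetic above the diagonal,
#' phenotypic below) from multi-trait fits.
#'
#' @param fits Named list of `cuni_fit` objects (single-trait fits).
#' @param mt_fits Optional named list of multi-trait `cuni_fit` objects used
#'   for the correlation matrix.
#' @param n_draws,seed Passed to [sample_parameter_se()] for the ratio SEs
#'   (set `n_draws = 0` to skip SEs).
#' @return A `cuni_param_report`: list with `components` (data frame of
#'   variance components and ratios per trait) and `correlations` (list with
#'   `traits`, `matrix` with genetic correlations above and phenotypic below
#'   the diagonal, and per-pair details).
#' @export
assemble_report <- function(fits, mt_fits = NULL, n_draws = 1000, seed = 1) {
  stopifnot(length(fits) >= 1)
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    vc <- fit$varcomp
    is_logit <- identical(fit$link, "logit")
    s2a <- if (!is.null(vc$genetic)) vc$genetic[1, 1] else 0
    s2c <- if (!is.null(vc$litter)) vc$litter[1, 1] else NA_real_
    s2me <- if (!is.null(vc$maternal_env)) vc$maternal_env[1, 1] else NA_real_
    s2pe <- if (!is.null(vc$perm_env)) vc$perm_env[1, 1] else NA_real_
    s2m <- if (!is.null(vc$genetic) && nrow(vc$genetic) > 1)
      vc$genetic[2, 2] else NA_real_
    s2e <- if (is_logit) pi^2 / 3 else vc$residual[1, 1]
    s2p <- sum(c(s2a, s2c, s2me, s2pe, s2m, s2e), na.rm = TRUE)
    if (!is.null(vc$genetic) && nrow(vc$genetic) > 1)
      s2p <- s2p + vc$genetic[1, 2]   # direct-maternal covariance convention
    h2 <- s2a / s2p
    ratio_se <- function(fn) {
      if (n_draws <= 0 || is.null(fit$vcov_varcomp) || anyNA(fit$vcov_varcomp))
        return(NA_real_)
      tryCatch(sample_parameter_se(fit, fn, n_draws = n_draws,
                                   seed = seed)$se,
               error = function(e) NA_real_)
    }
    mk_ratio <- function(which_num) {
      function(v) {
        comp <- .report_components(v, is_logit)
        sum(comp[which_num], na.rm = TRUE) / comp["s2p"]
      }
    }
    rows[[nm]] <- data.frame(
      trait = nm, sigma2_a = s2a, sigma2_litter = s2c, sigma2_matenv = s2me,
      sigma2_permenv = s2pe, sigma2_m = s2m, sigma2_e = s2e, sigma2_p = s2p,
      h2 = h2, h2_se = ratio_se(mk_ratio("s2a")),
      c2_litter = if (is.na(s2c)) NA_real_ else s2c / s2p,
      c2_matenv = if (is.na(s2me)) NA_real_ else s2me / s2p,
      c2_permenv = if (is.na(s2pe)) NA_real_ else s2pe / s2p,
      m2 = if (is.na(s2m)) NA_real_ else s2m / s2p,
      repeatability = if (is.na(s2pe)) NA_real_ else (s2a + s2pe) / s2p,
      boundary = length(fit$boundary) > 0,
      stringsAsFactors = FALSE)
  }
  components <- do.call(rbind, rows)
  rownames(components) <- NULL

  correlations <- NULL
  if (!is.null(mt_fits) && length(mt_fits)) {
    traits <- unique(unlist(lapply(mt_fits, function(f) f$design$traits)))
    M <- matrix(NA_real_, length(traits), length(traits),
                dimnames = list(traits, traits))
    diag(M) <- 1
    details <- list()
    for (nm in names(mt_fits)) {
      f <- mt_fits[[nm]]
      tt <- f$design$traits
      G <- f$varcomp$genetic
      Re <- f$varcomp$residual
      for (i in seq_along(tt)) for (j in seq_along(tt)) {
        if (i >= j) next
        rg <- G[i, j] / sqrt(G[i, i] * G[j, j])
        # phenotypic (co)variances: sum over all shared components
        Pi <- sum(vapply(f$varcomp, function(S)
          if (nrow(S) >= i) S[i, i] else 0, 0))
        Pj <- sum(vapply(f$varcomp, function(S)
          if (nrow(S) >= j) S[j, j] else 0, 0))
        Pij <- sum(vapply(f$varcomp, function(S)
          if (nrow(S) >= j) S[i, j] else 0, 0))
        rp <- Pij / sqrt(Pi * Pj)
        ti <- match(tt[i], traits); tj <- match(tt[j], traits)
        M[min(ti, tj), max(ti, tj)] <- rg
        M[max(ti, tj), min(ti, tj)] <- rp
        details[[paste(tt[i], tt[j], sep = "~")]] <-
          list(r_g = rg, r_p = rp, fit = nm)
      }
    }
    correlations <- list(traits = traits, matrix = M, details = details)
  }
  structure(list(components = components, correlations = correlations),
            class = "cuni_param_report")
}

# helper used by the ratio closures in assemble_report: map the natural
# parameter vector of a fit to named components
.report_components <- function(v, is_logit) {
  gv <- function(pat) {
    i <- grep(pat, names(v))
    if (length(i)) v[i[1]] else NA_real_
  }
  s2a <- gv("^genetic:var\\(.*direct\\)|^genetic:var\\([^,]*\\)$")
  s2c <- gv("^litter:var")
  s2me <- gv("^maternal_env:var")
  s2pe <- gv("^perm_env:var")
  s2m <- gv("^genetic:var\\(.*maternal\\)")
  s2am <- gv("^genetic:cov")
  s2e <- if (is_logit) pi^2 / 3 else gv("^residual:")
  s2p <- sum(c(s2a, s2c, s2me, s2pe, s2m, s2am, s2e), na.rm = TRUE)
  c(s2a = unname(s2a), s2c = unname(s2c), s2me = unname(s2me),
    s2pe = unname(s2pe), s2m = unname(s2m), s2e = unname(s2e),
    s2p = unname(s2p))
}

#' @export
print.cuni_param_report <- function(x, ...) {
  cat("<cuni_param_report>\n")
  print(x$components, digits = 3)
  if (!is.null(x$correlations)) {
    cat("correlations (genetic above diagonal, phenotypic below):\n")
    print(round(x$correlations$matrix, 3))
  }
  invisible(x)
}

#' Write a parameter report as delimited text
#' @param report A [assemble_report()] result.
#' @param dir Output directory.
#' @return Invisibly, the file paths written.
#' @export
write_param_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "variance_components.csv")
  utils::write.csv(report$components, p1, row.names = FALSE, quote = FALSE)
  paths <- p1
  if (!is.null(report$correlations)) {
    p2 <- file.path(dir, "correlations.csv")
    utils::write.csv(as.data.frame(report$correlations$matrix), p2,
                     quote = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
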