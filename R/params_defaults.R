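#' Reference genetic parameters for a two-environment maternal rabbit line
#'
#' Point estimates used as defaults throughout the package: liability-scale
#' variance components for the binary disease traits (non-specific disease
#' `resist`, respiratory `resp`, digestive `dig`) in the selection (S) and
#' challenging (Ch) environments, variance components for number born alive
#' (NBA) and weaning weight (WW, direct + maternal), and the genetic /
#' phenotypic correlations among the breeding-goal traits.
#'
#' With a logistic liability link the residual variance is pi^2/3 and the
#' liability-scale phenotypic variance convention is
#' `sigma2_p = sigma2_a + sigma2_litter + pi^2/3`.
#'
#' @return `default_disease_params()`: a named list (resist, resp, dig) of
#'   disease-trait blocks (see [disease_trait()]).
#' @export
default_disease_params <- function() {
  list(
    resist = disease_trait("resist",
                           sigma2_a = c(S = 0.15, Ch = 0.29),
                           sigma2_litter = c(S = 0.14, Ch = 0.01),
                           prevalence = c(S = 0.26, Ch = 0.41),
                           r_env = 0.70),
    resp = disease_trait("resp",
                         sigma2_a = c(S = 0.26, Ch = 0.31),
                         sigma2_litter = c(S = 0.19, Ch = 0.00),
                         prevalence = c(S = 0.14, Ch = 0.24),
                         r_env = 0.84),
    dig = disease_trait("dig",
                        sigma2_a = c(S = 0.26, Ch = 0.42),
                        sigma2_litter = c(S = 0.20, Ch = 0.04),
                        prevalence = c(S = 0.11, Ch = 0.16),
                        r_env = 0.48)
  )
}

#' @rdname default_disease_params
#' @return `default_production_params()`: a list with blocks `nba` (additive,
#'   permanent-environment and residual variances of litter size) and `ww`
#'   (direct and maternal additive, common-litter, maternal-environment and
#'   residual variances of weaning weight in g^2, with the direct-maternal
#'   genetic correlation).
#' @export
default_production_params <- function() {
  list(
    nba = list(mean = 9.92, sigma2_a = 1.71, sigma2_pe = 0.32, sigma2_e = 8.47),
    ww = list(mean = 664, sigma2_a = 2986, sigma2_m = 474,
              sigma2_litter = 1218, sigma2_matenv = 730, sigma2_e = 5620,
              r_direct_maternal = -0.71)
  )
}

#' @rdname default_disease_params
#' @details The direct-maternal genetic correlation of weaning weight is set
#'   to -0.71: the reported phenotypic variance of WW equals the sum of its
#'   components only when the direct-maternal covariance enters with a
#'   negative sign, and the predicted maternal responses are negative while
#'   direct responses are positive, both of which require a negative
#'   correlation of that magnitude.
#' @return `default_trait_correlations()`: list with `genetic` and
#'   `phenotypic` correlation matrices over
#'   (NBA, WW_direct, WW_maternal, Resist_S, Resist_Ch).
#' @export
default_trait_correlations <- function() {
  traits <- c("NBA", "WW_direct", "WW_maternal", "Resist_S", "Resist_Ch")
  g <- diag(5)
  dimnames(g) <- list(traits, traits)
  set <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  g <- set(g, "NBA", "WW_direct", -0.22)
  g <- set(g, "NBA", "WW_maternal", 0.51)
  g <- set(g, "NBA", "Resist_S", -0.08)
  g <- set(g, "NBA", "Resist_Ch", -0.06)
  g <- set(g, "WW_direct", "WW_maternal", -0.71)
  g <- set(g, "WW_direct", "Resist_S", -0.34)
  g <- set(g, "WW_direct", "Resist_Ch", -0.05)
  g <- set(g, "WW_maternal", "Resist_S", -0.06)
  g <- set(g, "WW_maternal", "Resist_Ch", -0.04)
  g <- set(g, "Resist_S", "Resist_Ch", 0.70)
  p <- diag(5)
  dimnames(p) <- list(traits, traits)
  p <- set(p, "NBA", "Resist_S", -0.38)
  p <- set(p, "NBA", "Resist_Ch", -0.37)
  p <- set(p, "NBA", "WW_direct", 0.03)
  p <- set(p, "WW_direct", "Resist_S", -0.13)
  p <- set(p, "WW_direct", "Resist_Ch", -0.11)
  list(genetic = g, phenotypic = p)
}

#' Observed-scale variance components for a binary trait
#'
#' Converts liability-scale heritability and common-litter ratios of a binary
#' trait with prevalence `p` to the observed (0/100 percent) scale, using the
#' standard threshold-model transformation `h2_obs = h2_liab * z^2 / (p q)`
#' where `z` is the standard-normal density at the threshold. The phenotypic
#' variance on the percent scale is `10000 p q`.
#'
#' @param h2_liab Liability-scale heritability.
#' @param p Prevalence (proportion affected).
#' @param c2_liab Liability-scale common-litter ratio.
#' @return List with `h2_obs`, `c2_obs`, and percent-scale `sigma2_p`,
#'   `sigma2_a`, `sigma2_c`, `sigma2_e`.
#' @export
liability_to_observed <- function(h2_liab, p, c2_liab = 0) {
  stopifnot(p > 0, p < 1, h2_liab >= 0, c2_liab >= 0)
  z <- stats::dnorm(stats::qnorm(1 - p))
  k <- z^2 / (p * (1 - p))
  sigma2_p <- 1e4 * p * (1 - p)
  h2_obs <- h2_liab * k
  c2_obs <- c2_liab * k
  list(h2_obs = h2_obs, c2_obs = c2_obs, sigma2_p = sigma2_p,
       sigma2_a = h2_obs * sigma2_p, sigma2_c = c2_obs * sigma2_p,
       sigma2_e = (1 - h2_obs - c2_obs) * sigma2_p)
}

#' Default multi-trait (co)variance structures for breeding-scheme evaluation
#'
#' Assembles the genetic covariance matrix and the environmental variance
#' components for the five breeding-goal traits
#' (NBA in kits, WW_direct and WW_maternal in g, Resist_S and Resist_Ch in
#' percent). Production-trait components come from
#' [default_production_params()]; the linear-scale Resist components are not
#' estimable from liability fits alone and default to the prevalence-scaled
#' conversion of [liability_to_observed()] (a documented configuration input,
#' not an estimate).
#'
#' @return List with elements `G` (5 x 5 genetic covariance), `sd_a` (base
#'   genetic standard deviations), `env` (per-trait environmental variance
#'   components) and `r_phen` (phenotypic correlations used for same-animal
#'   record covariances).
#' @export
default_scheme_params <- function() {
  pp <- default_production_params()
  dd <- default_disease_params()
  cors <- default_trait_correlations()
  pi2_3 <- pi^2 / 3
  h2l_S <- dd$resist$sigma2_a[["S"]] /
    (dd$resist$sigma2_a[["S"]] + dd$resist$sigma2_litter[["S"]] + pi2_3)
  c2l_S <- dd$resist$sigma2_litter[["S"]] /
    (dd$resist$sigma2_a[["S"]] + dd$resist$sigma2_litter[["S"]] + pi2_3)
  h2l_C <- dd$resist$sigma2_a[["Ch"]] /
    (dd$resist$sigma2_a[["Ch"]] + dd$resist$sigma2_litter[["Ch"]] + pi2_3)
  c2l_C <- dd$resist$sigma2_litter[["Ch"]] /
    (dd$resist$sigma2_a[["Ch"]] + dd$resist$sigma2_litter[["Ch"]] + pi2_3)
  rs <- liability_to_observed(h2l_S, dd$resist$prevalence[["S"]], c2l_S)
  rc <- liability_to_observed(h2l_C, dd$resist$prevalence[["Ch"]], c2l_C)
  sd_a <- c(NBA = sqrt(pp$nba$sigma2_a),
            WW_direct = sqrt(pp$ww$sigma2_a),
            WW_maternal = sqrt(pp$ww$sigma2_m),
            Resist_S = sqrt(rs$sigma2_a),
            Resist_Ch = sqrt(rc$sigma2_a))
  G <- diag(sd_a) %*% cors$genetic %*% diag(sd_a)
  dimnames(G) <- dimnames(cors$genetic)
  env <- list(
    NBA = list(sigma2_pe = pp$nba$sigma2_pe, sigma2_e = pp$nba$sigma2_e),
    WW = list(sigma2_litter = pp$ww$sigma2_litter,
              sigma2_matenv = pp$ww$sigma2_matenv,
              sigma2_e = pp$ww$sigma2_e),
    Resist_S = list(sigma2_litter = rs$sigma2_c, sigma2_e = rs$sigma2_e),
    Resist_Ch = list(sigma2_litter = rc$sigma2_c, sigma2_e = rc$sigma2_e)
  )
  list(G = G, sd_a = sd_a, env = env, r_phen = cors$phenotypic)
}
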