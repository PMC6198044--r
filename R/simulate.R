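#' Disease-trait simulation block
#'
#' Describes one binary disease trait on the liability scale, expressed as
#' two correlated traits in the selection (S) and challenging (Ch)
#' environments. With the default logit link the liability residual is
#' standard logistic (variance pi^2/3); binary phenotypes are obtained by
#' thresholding the liability at zero.
#'
#' @param name Trait name.
#' @param sigma2_a Named additive liability variances, `c(S=, Ch=)`.
#' @param sigma2_litter Named common-litter liability variances.
#' @param prevalence Named target marginal prevalences; used to solve the
#'   liability intercepts unless `intercept` is given.
#' @param r_env Cross-environment additive genetic correlation.
#' @param intercept Optional named liability intercepts (overrides
#'   `prevalence`).
#' @param link `"logit"` (default) or `"probit"`.
#' @param batch_sd,farm_sd Standard deviations of the Gaussian batch and
#'   Ch-farm effects on the liability scale.
#' @param sex_diff Male minus female liability difference (applied as +/-
#'   half around the intercept).
#' @return A `cuni_disease_trait` list.
#' @export
disease_trait <- function(name, sigma2_a, sigma2_litter, prevalence = NULL,
                          r_env = 0.7, intercept = NULL,
                          link = c("logit", "probit"),
                          batch_sd = 0.3, farm_sd = 0.2, sex_diff = 0.3) {
  link <- match.arg(link)
  stopifnot(all(sigma2_a >= 0), all(sigma2_litter >= 0), abs(r_env) <= 1)
  if (is.null(prevalence) && is.null(intercept))
    stop("either prevalence or intercept must be given")
  structure(list(name = name, sigma2_a = sigma2_a,
                 sigma2_litter = sigma2_litter, prevalence = prevalence,
                 r_env = r_env, intercept = intercept, link = link,
                 batch_sd = batch_sd, farm_sd = farm_sd, sex_diff = sex_diff),
            class = "cuni_disease_trait")
}

#' Simulation configuration for a two-environment rabbit population
#'
#' The default configuration emulates the study design of a maternal rabbit
#' line recorded over several years: 332 sires and 849 dams producing about
#' 23,800 growing kits over 4 parities of 7 kits, 29 weaning batches with
#' every second batch sent to the challenging environment (almost all males
#' plus enough females to make the Ch group 97% male), 4% of kits
#' cross-fostered at birth, disease prevalences of 26% (S) and 41% (Ch) for
#' the composite resistance trait, and the reference variance components of
#' [default_disease_params()] / [default_production_params()].
#'
#' @param n_sires,n_dams Numbers of base sires and dams.
#' @param parities Litters per dam.
#' @param kits_per_litter Kits born alive and reared per litter.
#' @param n_batches Number of weaning batches.
#' @param fraction_batches_ch Fraction of batches whose weaned kits are sent
#'   to the challenging environment.
#' @param male_fraction_ch Target fraction of males among Ch animals.
#' @param n_farms_ch Number of challenging-environment farms.
#' @param fostering_rate Fraction of kits cross-fostered to another dam.
#' @param sex_ratio Proportion of males at birth.
#' @param related_dams Give the dams a paternal pedigree layer (half-sib
#'   groups of does descending from founder grandsires), as in a closed
#'   nucleus; needed to separate additive from permanent-environment
#'   variance in repeated doe records.
#' @param seed Integer seed; the same config and seed give identical output.
#' @param diseases Named list of [disease_trait()] blocks.
#' @param composite_resist If `TRUE`, the composite trait `resist` is 1
#'   whenever `dig` or `resp` is 1 or an independent "other-disorder" latent
#'   trait (with the `resist` block's variances) exceeds its threshold; the
#'   other-disorder prevalence is calibrated so the composite hits the
#'   `resist` target. If `FALSE`, `resist` is simulated directly from its
#'   block.
#' @param production List with `nba` and `ww` blocks as in
#'   [default_production_params()], or `NULL` to skip production traits.
#' @param ww_batch_sd,ww_sex_diff,ww_parity_sd Fixed-effect scales for WW (g).
#' @param nba_ys_sd,nba_ps_sd Year-season and parity-status effect scales for
#'   NBA (kits).
#' @return A `cuni_sim_config` list.
#' @export
sim_config <- function(n_sires = 332, n_dams = 849, parities = 4,
                       kits_per_litter = 7, n_batches = 29,
                       fraction_batches_ch = 0.5, male_fraction_ch = 0.97,
                       n_farms_ch = 3, fostering_rate = 0.04,
                       sex_ratio = 0.5, related_dams = TRUE, seed = 1,
                       diseases = default_disease_params(),
                       composite_resist = TRUE,
                       production = default_production_params(),
                       ww_batch_sd = 30, ww_sex_diff = 20, ww_parity_sd = 25,
                       nba_ys_sd = 0.4, nba_ps_sd = 0.5) {
  stopifnot(n_sires > 0, n_dams > 0, parities > 0, kits_per_litter > 0,
            n_batches > 0, fraction_batches_ch >= 0, fraction_batches_ch <= 1,
            fostering_rate >= 0, fostering_rate <= 1,
            sex_ratio > 0, sex_ratio < 1,
            male_fraction_ch >= sex_ratio, male_fraction_ch <= 1)
  structure(as.list(environment()), class = "cuni_sim_config")
}

#' Marginal prevalence implied by a disease-trait block
#'
#' Integrates the inverse link over the Gaussian random-effect and
#' fixed-effect distribution on the liability scale: additive, common-litter,
#' batch and (in Ch) farm contributions are Gaussian; the binary sex effect
#' is averaged over the male fraction of the environment.
#'
#' @param params A [disease_trait()] block (with `intercept` set, or a target
#'   `prevalence` from which the intercept is first solved).
#' @param environment `"S"` or `"Ch"`.
#' @param male_fraction Proportion of males among animals of that
#'   environment; default 0.5.
#' @return The marginal probability of a record of 1.
#' @export
expected_prevalence <- function(params, environment = c("S", "Ch"),
                                male_fraction = 0.5) {
  environment <- match.arg(environment)
  mu <- if (!is.null(params$intercept)) params$intercept[[environment]]
        else solve_liability_intercept(params, environment, male_fraction)
  .marginal_prevalence(mu, params, environment, male_fraction)
}

.liability_sd <- function(params, environment) {
  v <- params$sigma2_a[[environment]] + params$sigma2_litter[[environment]] +
    params$batch_sd^2 + if (environment == "Ch") params$farm_sd^2 else 0
  sqrt(v)
}

.marginal_prevalence <- function(mu, params, environment, male_fraction) {
  s <- .liability_sd(params, environment)
  pfun <- if (params$link == "logit") stats::plogis else stats::pnorm
  one_sex <- function(shift) {
    if (s < 1e-12) return(pfun(mu + shift))
    stats::integrate(function(z) pfun(mu + shift + s * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }
  male_fraction * one_sex(params$sex_diff / 2) +
    (1 - male_fraction) * one_sex(-params$sex_diff / 2)
}

#' Solve the liability intercept for a target prevalence
#'
#' @inheritParams expected_prevalence
#' @param target Target prevalence; defaults to the block's `prevalence`.
#' @return The liability intercept.
#' @export
solve_liability_intercept <- function(params, environment = c("S", "Ch"),
                                      male_fraction = 0.5, target = NULL) {
  environment <- match.arg(environment)
  if (is.null(target)) target <- params$prevalence[[environment]]
  stopifnot(target > 0, target < 1)
  stats::uniroot(function(mu)
    .marginal_prevalence(mu, params, environment, male_fraction) - target,
    interval = c(-40, 40), tol = 1e-10)$root
}

# breeding values for a t-variate additive effect over a pedigree:
# founders ~ N(0, G); offspring = midparent + Mendelian N(0, G/2)
# (unknown-parent contributions keep the unconditional variance at G).
.sim_bv <- function(ped, G) {
  G <- as.matrix(G)
  t <- nrow(G)
  n <- nrow(ped)
  bv <- matrix(0, n, t)
  if (n == 0) return(bv)
  if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values < -1e-8 *
          max(1, max(abs(G)))))
    stop("implied genetic covariance matrix is not positive semi-definite")
  s <- ped$sire_idx; d <- ped$dam_idx
  # process in topological order, vectorized over "levels"
  level <- integer(n)
  for (i in seq_len(n))
    level[i] <- 1L + max(0L, if (s[i] > 0) level[s[i]] else 0L,
                         if (d[i] > 0) level[d[i]] else 0L)
  for (lv in sort(unique(level))) {
    idx <- which(level == lv)
    m <- length(idx)
    mid <- 0.5 * ((bv[pmax(s[idx], 1L), , drop = FALSE] * (s[idx] > 0)) +
                  (bv[pmax(d[idx], 1L), , drop = FALSE] * (d[idx] > 0)))
    # Mendelian/founder variance: G * (1 - 0.25*known_parents)
    known <- (s[idx] > 0) + (d[idx] > 0)
    for (k in 0:2) {
      sub <- which(known == k)
      if (!length(sub)) next
      vfac <- 1 - 0.25 * k
      noise <- matrix(MASS::mvrnorm(length(sub), mu = rep(0, t),
                                    Sigma = vfac * G),
                      nrow = length(sub), ncol = t)
      bv[idx[sub], ] <- mid[sub, , drop = FALSE] + noise
    }
  }
  bv
}

#' Simulate a pedigreed two-environment population
#'
#' Generates the full study design described in [sim_config()]: a base
#' population of unrelated sires and dams, litters over parities allocated to
#' weaning batches, environment allocation by batch (all males and a
#' calibrated fraction of females from Ch batches go to Ch), cross-fostering
#' at the configured rate, correlated liabilities for the disease traits in
#' the two environments, weaning weight with direct + maternal genetic,
#' common-litter and maternal-environment effects, and repeated litter-size
#' records per doe with a permanent-environment effect.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @return A `cuni_simulation` list with elements `pedigree`
#'   ([as_pedigree()]), `phenotypes` (list of `animals` and `litters` data
#'   frames), `true_values` (breeding values of all animals), `fostering`
#'   (the fostering events applied) and `config`.
#' @export
simulate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cuni_sim_config"))
  set.seed(seed)
  cf <- config

  # ---- pedigree skeleton -------------------------------------------------
  sire_id <- sprintf("S%04d", seq_len(cf$n_sires))
  dam_id <- sprintf("D%04d", seq_len(cf$n_dams))
  dam_sire <- sort(rep(sire_id, length.out = cf$n_dams))
  gs_id <- character(0)
  dam_gs <- rep("0", cf$n_dams)
  if (isTRUE(cf$related_dams)) {
    n_gs <- max(3L, round(cf$n_sires / 2))
    gs_id <- sprintf("G%04d", seq_len(n_gs))
    dam_gs <- sample(rep(gs_id, length.out = cf$n_dams))
  }
  # litters: dam x parity
  lit <- expand.grid(dam = dam_id, parity = seq_len(cf$parities),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lit <- lit[order(lit$parity, lit$dam), , drop = FALSE]
  n_lit <- nrow(lit)
  lit$litter <- sprintf("L%05d", seq_len(n_lit))
  lit$sire <- dam_sire[match(lit$dam, dam_id)]
  lit$batch <- sprintf("B%02d", ((seq_len(n_lit) - 1L) %% cf$n_batches) + 1L)
  batch_num <- as.integer(sub("B", "", lit$batch))
  lit$ch_batch <- (batch_num %% 2L == 0L) &
    (batch_num <= 2L * round(cf$n_batches * cf$fraction_batches_ch))

  n_kits <- n_lit * cf$kits_per_litter
  kid <- sprintf("K%06d", seq_len(n_kits))
  klit <- rep(seq_len(n_lit), each = cf$kits_per_litter)
  sex <- ifelse(stats::runif(n_kits) < cf$sex_ratio, "M", "F")
  # females follow males to Ch with the probability that yields the target
  # male fraction among Ch animals
  q_f <- cf$sex_ratio * (1 - cf$male_fraction_ch) /
    (cf$male_fraction_ch * (1 - cf$sex_ratio))
  to_ch <- lit$ch_batch[klit] &
    (sex == "M" | stats::runif(n_kits) < q_f)
  env <- ifelse(to_ch, "Ch", "S")
  farm <- rep(NA_character_, n_kits)
  farm[to_ch] <- sprintf("F%d", sample.int(cf$n_farms_ch, sum(to_ch),
                                           replace = TRUE))

  n_gs <- length(gs_id)
  n_base <- n_gs + cf$n_sires + cf$n_dams
  ped_df <- data.frame(
    animal = c(gs_id, sire_id, dam_id, kid),
    sire = c(rep("0", n_gs + cf$n_sires), dam_gs, lit$sire[klit]),
    dam = c(rep("0", n_base), lit$dam[klit]),
    sex = c(rep("M", n_gs + cf$n_sires), rep("F", cf$n_dams), sex),
    batch = c(rep(NA_character_, n_base), lit$batch[klit]),
    environment = c(rep(NA_character_, n_base), env),
    litter = c(rep(NA_character_, n_base), lit$litter[klit]),
    stringsAsFactors = FALSE)
  ped <- as_pedigree(ped_df)

  # ---- cross-fostering ---------------------------------------------------
  n_foster <- round(cf$fostering_rate * n_kits)
  fostering <- data.frame(kit = character(0), adoptive_dam = character(0))
  if (n_foster > 0) {
    fk <- sample(kid, n_foster)
    fk_lit <- klit[match(fk, kid)]
    adopt <- character(n_foster)
    for (i in seq_len(n_foster)) {
      cand <- which(lit$batch == lit$batch[fk_lit[i]] &
                    seq_len(n_lit) != fk_lit[i])
      if (!length(cand)) cand <- setdiff(seq_len(n_lit), fk_lit[i])
      adopt[i] <- lit$dam[sample(cand, 1L)]
    }
    fostering <- data.frame(kit = fk, adoptive_dam = adopt,
                            stringsAsFactors = FALSE)
    ped <- assign_rearing_effects(ped, fostering)
  }

  # convenience lookups in pedigree order
  porder <- ped$animal
  is_kit <- grepl("^K", porder)

  # ---- disease traits ----------------------------------------------------
  mf_S <- .env_male_fraction(cf, "S")
  mf_C <- .env_male_fraction(cf, "Ch")
  sim_traits <- cf$diseases
  if (isTRUE(cf$composite_resist) &&
      all(c("resist", "resp", "dig") %in% names(sim_traits))) {
    other <- sim_traits$resist
    other$name <- "other"
    # calibrate the other-disorder prevalence so that, under independent
    # liabilities, P(dig | resp | other) hits the resist target
    for (e in c("S", "Ch")) {
      pd <- sim_traits$dig$prevalence[[e]]
      pr <- sim_traits$resp$prevalence[[e]]
      pt <- sim_traits$resist$prevalence[[e]]
      po <- 1 - (1 - pt) / ((1 - pd) * (1 - pr))
      other$prevalence[[e]] <- max(1e-4, po)
    }
    sim_traits$resist <- NULL
    sim_traits$other <- other
  }

  animals <- data.frame(animal = porder[is_kit], stringsAsFactors = FALSE)
  ai <- match(animals$animal, porder)
  animals$environment <- ped$environment[ai]
  animals$batch <- ped$batch[ai]
  animals$sex <- ped$sex[ai]
  animals$farm <- farm[match(animals$animal, kid)]
  animals$dam <- ped$biological_dam[ai]
  animals$rearing_dam <- ped$rearing_dam[ai]
  animals$litter <- ped$litter[ai]
  animals$rearing_litter <- ped$rearing_litter[ai]
  animals$parity <- lit$parity[match(animals$litter, lit$litter)]

  tv <- data.frame(animal = porder, stringsAsFactors = FALSE)
  rlit_all <- unique(stats::na.omit(ped$rearing_litter))

  for (tn in names(sim_traits)) {
    blk <- sim_traits[[tn]]
    G2 <- .disease_G2(blk)
    bv <- .sim_bv(ped, G2)
    tv[[paste0(tn, "_S")]] <- bv[, 1]
    tv[[paste0(tn, "_Ch")]] <- bv[, 2]
    mu <- c(S = if (!is.null(blk$intercept)) blk$intercept[["S"]] else
              solve_liability_intercept(blk, "S", mf_S),
            Ch = if (!is.null(blk$intercept)) blk$intercept[["Ch"]] else
              solve_liability_intercept(blk, "Ch", mf_C))
    batch_eff <- stats::rnorm(cf$n_batches, 0, blk$batch_sd)
    names(batch_eff) <- sprintf("B%02d", seq_len(cf$n_batches))
    farm_eff <- stats::rnorm(cf$n_farms_ch, 0, blk$farm_sd)
    names(farm_eff) <- sprintf("F%d", seq_len(cf$n_farms_ch))
    lit_eff_z <- stats::rnorm(length(rlit_all))
    names(lit_eff_z) <- rlit_all
    e_env <- animals$environment
    sd_lit <- sqrt(blk$sigma2_litter[e_env])
    resid <- if (blk$link == "logit") stats::rlogis(nrow(animals))
             else stats::rnorm(nrow(animals))
    a_use <- ifelse(e_env == "S", bv[ai, 1], bv[ai, 2])
    liab <- mu[e_env] + batch_eff[animals$batch] +
      ifelse(animals$sex == "M", blk$sex_diff / 2, -blk$sex_diff / 2) +
      ifelse(is.na(animals$farm), 0, farm_eff[animals$farm]) +
      a_use + sd_lit * lit_eff_z[animals$rearing_litter] + resid
    animals[[tn]] <- as.integer(liab > 0)
  }
  if (isTRUE(cf$composite_resist) && "other" %in% names(animals)) {
    animals$resist <- as.integer(animals$dig | animals$resp | animals$other)
  }

  # ---- production traits -------------------------------------------------
  litters <- NULL
  if (!is.null(cf$production)) {
    pp <- cf$production
    # WW: direct + maternal bivariate additive effect
    Gw <- matrix(c(pp$ww$sigma2_a,
                   pp$ww$r_direct_maternal * sqrt(pp$ww$sigma2_a * pp$ww$sigma2_m),
                   pp$ww$r_direct_maternal * sqrt(pp$ww$sigma2_a * pp$ww$sigma2_m),
                   pp$ww$sigma2_m), 2, 2)
    bvw <- .sim_bv(ped, Gw)
    tv$ww_direct <- bvw[, 1]
    tv$ww_maternal <- bvw[, 2]
    batch_eff_w <- stats::rnorm(cf$n_batches, 0, cf$ww_batch_sd)
    names(batch_eff_w) <- sprintf("B%02d", seq_len(cf$n_batches))
    parity_eff_w <- stats::rnorm(cf$parities, 0, cf$ww_parity_sd)
    lit_c <- stats::rnorm(length(rlit_all), 0, sqrt(pp$ww$sigma2_litter))
    names(lit_c) <- rlit_all
    dam_me <- stats::rnorm(cf$n_dams, 0, sqrt(pp$ww$sigma2_matenv))
    names(dam_me) <- dam_id
    rd_i <- match(animals$rearing_dam, porder)
    ww <- pp$ww$mean + batch_eff_w[animals$batch] +
      ifelse(animals$sex == "M", cf$ww_sex_diff / 2, -cf$ww_sex_diff / 2) +
      parity_eff_w[animals$parity] +
      bvw[ai, 1] + bvw[rd_i, 2] + lit_c[animals$rearing_litter] +
      dam_me[animals$rearing_dam] +
      stats::rnorm(nrow(animals), 0, sqrt(pp$ww$sigma2_e))
    animals$ww <- pmax(1, round(ww))

    # NBA: repeated doe records over parities
    bvn <- .sim_bv(ped, matrix(pp$nba$sigma2_a, 1, 1))[, 1]
    tv$nba <- bvn
    pe <- stats::rnorm(cf$n_dams, 0, sqrt(pp$nba$sigma2_pe))
    names(pe) <- dam_id
    ys_levels <- paste0("YS", ((as.integer(sub("B", "", lit$batch)) - 1L) %/% 2L) + 1L)
    ys_eff <- stats::rnorm(length(unique(ys_levels)), 0, cf$nba_ys_sd)
    names(ys_eff) <- unique(ys_levels)
    lact <- stats::runif(n_lit) < 0.6
    ps_level <- paste0("P", pmin(lit$parity, 5L), ifelse(lact, "_lact", "_dry"))
    ps_eff <- stats::rnorm(length(unique(ps_level)), 0, cf$nba_ps_sd)
    names(ps_eff) <- unique(ps_level)
    nba <- pp$nba$mean + ys_eff[ys_levels] + ps_eff[ps_level] +
      bvn[match(lit$dam, porder)] + pe[lit$dam] +
      stats::rnorm(n_lit, 0, sqrt(pp$nba$sigma2_e))
    litters <- data.frame(dam = lit$dam, parity = lit$parity,
                          batch = lit$batch, year_season = ys_levels,
                          physiological_status = ifelse(lact, "lact", "dry"),
                          nba = pmax(0, round(nba)),
                          stringsAsFactors = FALSE)
  }

  rownames(animals) <- NULL
  structure(list(pedigree = ped,
                 phenotypes = list(animals = animals, litters = litters),
                 true_values = tv, fostering = fostering, config = cf),
            class = "cuni_simulation")
}

.disease_G2 <- function(blk) {
  sa <- sqrt(blk$sigma2_a)
  matrix(c(sa[["S"]]^2, blk$r_env * sa[["S"]] * sa[["Ch"]],
           blk$r_env * sa[["S"]] * sa[["Ch"]], sa[["Ch"]]^2), 2, 2)
}

# expected male fraction per environment under batch-based allocation
.env_male_fraction <- function(cf, environment) {
  fb <- cf$fraction_batches_ch
  sr <- cf$sex_ratio
  q_f <- sr * (1 - cf$male_fraction_ch) / (cf$male_fraction_ch * (1 - sr))
  if (environment == "Ch") return(cf$male_fraction_ch)
  males_S <- sr * (1 - fb)
  total_S <- (1 - fb) + fb * (1 - sr) * (1 - q_f)
  if (total_S <= 0) return(sr)
  males_S / total_S
}

#' @export
print.cuni_simulation <- function(x, ...) {
  an <- x$phenotypes$animals
  cat(sprintf("<cuni_simulation> %d animals in pedigree, %d with records (%d S, %d Ch)\n",
              nrow(x$pedigree), nrow(an), sum(an$environment == "S"),
              sum(an$environment == "Ch")))
  for (tn in intersect(c("resist", "resp", "dig"), names(an))) {
    cat(sprintf("  %-6s prevalence S %.3f  Ch %.3f\n", tn,
                mean(an[[tn]][an$environment == "S"]),
                mean(an[[tn]][an$environment == "Ch"])))
  }
  invisible(x)
}

#' Write simulation outputs as delimited text files
#'
#' @param sim A [simulate_population()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             animals = file.path(dir, "animals.csv"),
             litters = file.path(dir, "litters.csv"),
             true_values = file.path(dir, "true_values.csv"))
  write_pedigree(sim$pedigree, paths["pedigree"])
  utils::write.csv(sim$phenotypes$animals, paths["animals"], row.names = FALSE,
                   quote = FALSE)
  if (!is.null(sim$phenotypes$litters))
    utils::write.csv(sim$phenotypes$litters, paths["litters"],
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$true_values, paths["true_values"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
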