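#' Standardized selection intensity under truncation
#'
#' Mean standardized superiority of the selected group when the best
#' fraction `p` of candidates is kept on a normally distributed criterion:
#' `i = phi(x) / p` with `x` the upper-`p` quantile. With a finite number of
#' candidates `N` a Burrows-type correction is applied,
#' `i_N = i - (1 - p) / (2 p i (N + 1))`; a mean pairwise correlation `rho`
#' among the candidates' index values reduces the effective candidate number
#' to `1 + (N - 1)(1 - rho)` before the correction.
#'
#' @param p Selected fraction in (0, 1].
#' @param N Number of candidates (default infinite).
#' @param rho Mean correlation among candidate index values.
#' @return The selection intensity.
#' @export
selection_intensity <- function(p, N = Inf, rho = 0) {
  if (!is.numeric(p) || p <= 0 || p > 1) stop("selected fraction must be in (0, 1]")
  if (p == 1) return(0)
  x <- stats::qnorm(1 - p)
  i <- stats::dnorm(x) / p
  if (is.finite(N)) {
    Neff <- 1 + (N - 1) * (1 - rho)
    i <- i - (1 - p) / (2 * p * i * (Neff + 1))
  }
  max(0, i)
}

#' Breeding-scheme configuration
#'
#' Describes a closed nucleus with discrete generations and single-stage
#' truncation selection on a pseudo-BLUP index, and the recording plan of
#' the information sources available on the selection candidate at 70 days:
#' its own records, its full-sib and paternal-half-sib group means in each
#' environment, and its dam's repeated litter-size records. All candidates
#' are raised in the selection environment; when the challenging environment
#' is recorded, a quarter of the sibs is tested there (and therefore carries
#' Resist_Ch instead of Resist_S records).
#'
#' @param n_sires,n_dams Selected parents per generation.
#' @param kits_per_litter Progeny per litter.
#' @param selected_fraction_males,selected_fraction_females Selected
#'   fractions for the two paths.
#' @param dam_records_nba Number of litter-size records of the dam available
#'   at selection.
#' @param record_ww,record_resist_s,record_resist_ch Recording switches.
#' @param fraction_sibs_ch Fraction of sibs tested in Ch when
#'   `record_resist_ch`.
#' @param use_own_records,use_sib_records,use_dam_nba Source switches
#'   (mass-selection degenerate schemes set `use_sib_records = FALSE` etc.).
#' @param parent_index Include the parents' index values as information
#'   (pseudo-BLUP); `FALSE` gives a plain sib index.
#' @param bulmer Iterate the Bulmer genetic-variance recursion to
#'   equilibrium.
#' @param rho_candidates Mean index correlation among candidates for the
#'   finite-number intensity correction.
#' @return A `cuni_scheme`.
#' @export
scheme_config <- function(n_sires = 35, n_dams = 140, kits_per_litter = 7,
                          selected_fraction_males = 0.15,
                          selected_fraction_females = 0.25,
                          dam_records_nba = 3,
                          record_ww = TRUE, record_resist_s = FALSE,
                          record_resist_ch = FALSE, fraction_sibs_ch = 0.25,
                          use_own_records = TRUE, use_sib_records = TRUE,
                          use_dam_nba = FALSE,
                          parent_index = TRUE, bulmer = TRUE,
                          rho_candidates = 0) {
  stopifnot(n_sires > 0, n_dams > 0, n_dams %% n_sires == 0 || TRUE,
            kits_per_litter >= 1,
            selected_fraction_males > 0, selected_fraction_males <= 1,
            selected_fraction_females > 0, selected_fraction_females <= 1,
            fraction_sibs_ch >= 0, fraction_sibs_ch <= 1)
  structure(as.list(environment()), class = "cuni_scheme")
}

# template family pedigree used for all record covariances: a candidate X
# with full sibs (F1, F2), paternal half sibs in two other litters
# (H1a, H1b | H2a), their dams, and the common sire.
.template_family <- function() {
  ped <- as_pedigree(data.frame(
    animal = c("S", "D", "D2a", "D2b", "X", "F1", "F2", "H1a", "H1b", "H2a"),
    sire = c(0, 0, 0, 0, "S", "S", "S", "S", "S", "S"),
    dam = c(0, 0, 0, 0, "D", "D", "D", "D2a", "D2a", "D2b"),
    sex = c("M", "F", "F", "F", "M", "M", "F", "M", "F", "M"),
    stringsAsFactors = FALSE))
  A <- compute_A(ped)
  dam_of <- c(S = NA, D = NA, D2a = NA, D2b = NA, X = "D", F1 = "D", F2 = "D",
              H1a = "D2a", H1b = "D2a", H2a = "D2b")
  litter_of <- c(S = NA, D = NA, D2a = NA, D2b = NA, X = "L0", F1 = "L0",
                 F2 = "L0", H1a = "L1", H1b = "L1", H2a = "L2")
  list(A = A, dam_of = dam_of, litter_of = litter_of)
}

# genetic loads of one record of a given type on a given template animal
.rec_loads <- function(animal, type, tmpl) {
  switch(type,
    WW = list(c(animal, "WW_direct"), c(tmpl$dam_of[[animal]], "WW_maternal")),
    RS = list(c(animal, "Resist_S")),
    RC = list(c(animal, "Resist_Ch")),
    NBA = list(c(animal, "NBA")))
}

# covariance between two single records on template animals a1, a2
.cov_rec <- function(a1, t1, a2, t2, G, env, tmpl, dam_records,
                     ecov_same_animal = NULL) {
  gen <- 0
  for (l1 in .rec_loads(a1, t1, tmpl)) for (l2 in .rec_loads(a2, t2, tmpl)) {
    if (is.na(l1[1]) || is.na(l2[1])) next
    if (!(l1[2] %in% rownames(G)) || !(l2[2] %in% rownames(G))) next
    gen <- gen + tmpl$A[l1[1], l2[1]] * G[l1[2], l2[2]]
  }
  e <- 0
  same_animal <- identical(a1, a2)
  same_litter <- !is.na(tmpl$litter_of[[a1]]) &&
    identical(tmpl$litter_of[[a1]], tmpl$litter_of[[a2]])
  same_rdam <- !is.na(tmpl$dam_of[[a1]]) &&
    identical(tmpl$dam_of[[a1]], tmpl$dam_of[[a2]])
  if (t1 == t2) {
    if (t1 == "WW") {
      if (same_litter) e <- e + env$WW$sigma2_litter
      if (same_rdam) e <- e + env$WW$sigma2_matenv
      if (same_animal) e <- e + env$WW$sigma2_e
    } else if (t1 == "RS") {
      if (same_litter) e <- e + env$Resist_S$sigma2_litter
      if (same_animal) e <- e + env$Resist_S$sigma2_e
    } else if (t1 == "RC") {
      if (same_litter) e <- e + env$Resist_Ch$sigma2_litter
      if (same_animal) e <- e + env$Resist_Ch$sigma2_e
    } else if (t1 == "NBA") {
      if (same_animal)
        e <- e + env$NBA$sigma2_pe + env$NBA$sigma2_e / dam_records
    }
  } else if (same_animal && !is.null(ecov_same_animal)) {
    key <- paste(sort(c(t1, t2)), collapse = ":")
    e <- e + (ecov_same_animal[[key]] %||% 0)
  }
  gen + e
}

# same-animal environmental covariances between record types, fixed at the
# base-generation scale from the phenotypic correlations
.ecov_table <- function(G0, env, r_phen, tmpl, dam_records) {
  out <- list()
  ptypes <- c(WW = "WW_direct", RS = "Resist_S", RC = "Resist_Ch")
  pvar <- vapply(names(ptypes), function(tt)
    .cov_rec("X", tt, "X", tt, G0, env, tmpl, dam_records), 0)
  pairs <- list(c("RS", "WW"), c("RC", "WW"))
  for (pr in pairs) {
    tr1 <- ptypes[[pr[1]]]; tr2 <- ptypes[[pr[2]]]
    if (!(tr1 %in% rownames(r_phen)) || !(tr2 %in% rownames(r_phen))) next
    rp <- r_phen[tr1, tr2]
    gen <- .cov_rec("X", pr[1], "X", pr[2], G0, env, tmpl, dam_records)
    out[[paste(sort(pr), collapse = ":")]] <-
      rp * sqrt(pvar[[pr[1]]] * pvar[[pr[2]]]) - gen
  }
  out
}

# information sources for a candidate under the scheme's recording plan;
# each is a group mean of records of one type over one relative class
.build_sources <- function(scheme) {
  src <- list()
  add <- function(id, class, type, n, per_litter = NA) {
    src[[id]] <<- list(id = id, class = class, type = type, n = n,
                       per_litter = per_litter)
  }
  n_fs <- scheme$kits_per_litter - 1
  dams_per_sire <- max(1, round(scheme$n_dams / scheme$n_sires))
  L_hs <- dams_per_sire - 1
  n_hs <- L_hs * scheme$kits_per_litter
  fch <- if (scheme$record_resist_ch) scheme$fraction_sibs_ch else 0
  if (scheme$use_own_records) {
    if (scheme$record_ww) add("own_WW", "own", "WW", 1)
    if (scheme$record_resist_s) add("own_RS", "own", "RS", 1)
  }
  if (scheme$use_sib_records && n_fs > 0) {
    if (scheme$record_ww) add("fs_WW", "fs", "WW", n_fs)
    if (scheme$record_resist_s && n_fs * (1 - fch) > 0)
      add("fs_RS", "fs", "RS", n_fs * (1 - fch))
    if (scheme$record_resist_ch && n_fs * fch > 0)
      add("fs_RC", "fs", "RC", n_fs * fch)
  }
  if (scheme$use_sib_records && n_hs > 0) {
    if (scheme$record_ww) add("hs_WW", "hs", "WW", n_hs, n_hs / L_hs)
    if (scheme$record_resist_s && n_hs * (1 - fch) > 0)
      add("hs_RS", "hs", "RS", n_hs * (1 - fch), n_hs * (1 - fch) / L_hs)
    if (scheme$record_resist_ch && n_hs * fch > 0)
      add("hs_RC", "hs", "RC", n_hs * fch, n_hs * fch / L_hs)
  }
  if (scheme$use_dam_nba) add("dam_NBA", "dam", "NBA", 1)
  src
}

# overlap (number of shared animals) between two record subsets of the same
# relative class: WW is recorded on every sib, RS on the S-tested subset,
# RC on the Ch-tested subset
.subset_overlap <- function(t1, n1, t2, n2) {
  if (t1 == t2) return(min(n1, n2))
  if ("WW" %in% c(t1, t2)) return(min(n1, n2))
  0  # RS and RC subsets are disjoint
}

.cov_sources <- function(s1, s2, G, env, tmpl, scheme, ecov) {
  dr <- scheme$dam_records_nba
  cr <- function(a1, a2) .cov_rec(a1, s1$type, a2, s2$type, G, env, tmpl,
                                  dr, ecov)
  cls <- c(s1$class, s2$class)
  if (s1$class == s2$class && s1$class %in% c("own", "dam")) {
    if (s1$type == s2$type) return(cr("X", "X"))  # variance of a single record
    return(cr(if (s1$class == "dam") "D" else "X",
              if (s2$class == "dam") "D" else "X"))
  }
  if (s1$class == s2$class && s1$class == "fs") {
    n1 <- s1$n; n2 <- s2$n
    n_same <- .subset_overlap(s1$type, n1, s2$type, n2)
    c_same <- cr("F1", "F1")
    c_lit <- cr("F1", "F2")
    return((n_same * c_same + (n1 * n2 - n_same) * c_lit) / (n1 * n2))
  }
  if (s1$class == s2$class && s1$class == "hs") {
    n1 <- s1$n; n2 <- s2$n
    m1 <- s1$per_litter; m2 <- s2$per_litter
    L <- n1 / m1
    n_same <- .subset_overlap(s1$type, n1, s2$type, n2)
    n_same_lit <- L * m1 * m2 - n_same
    n_diff <- n1 * n2 - L * m1 * m2
    c_same <- cr("H1a", "H1a")
    c_lit <- cr("H1a", "H1b")
    c_dif <- cr("H1a", "H2a")
    return((n_same * c_same + n_same_lit * c_lit + n_diff * c_dif) /
             (n1 * n2))
  }
  # distinct classes: uniform pair covariance
  rep_of <- c(own = "X", fs = "F1", hs = "H1a", dam = "D")
  cr(rep_of[[s1$class]], rep_of[[s2$class]])
}

# Cov(source mean, genetic value of the candidate for each trait)
.cov_source_g <- function(s, G, tmpl) {
  rep_of <- c(own = "X", fs = "F1", hs = "H1a", dam = "D")
  a <- rep_of[[s$class]]
  out <- stats::setNames(numeric(ncol(G)), colnames(G))
  for (l in .rec_loads(a, s$type, tmpl)) {
    if (is.na(l[1]) || !(l[2] %in% rownames(G))) next
    out <- out + tmpl$A[l[1], "X"] * G[l[2], ]
  }
  out
}

# coefficients of Cov(I_parent, g_t(template animal)) in units of
# Cov(I, g_t) of the parent itself
.parent_chi <- function(parent) {
  if (parent == "sire")
    c(X = 0.5, F1 = 0.5, F2 = 0.5, H1a = 0.5, H1b = 0.5, H2a = 0.5,
      S = 1, D = 0, D2a = 0, D2b = 0)
  else
    c(X = 0.5, F1 = 0.5, F2 = 0.5, H1a = 0, H1b = 0, H2a = 0,
      S = 0, D = 1, D2a = 0, D2b = 0)
}

#' Deterministic prediction of multi-trait selection response
#'
#' Predicts per-generation responses to truncation selection on a
#' pseudo-BLUP index in a closed nucleus with discrete generations. The
#' index combines, per candidate, the information sources defined by the
#' scheme (own records, full-sib and half-sib group means in each
#' environment, the dam's repeated litter-size records) and, when
#' `parent_index` is on, the parents' own index values, whose moments are
#' carried over from the previous generation with the truncation-selection
#' reduction `Cov*(I, .) = (1 - k) Cov(I, .)`. Index weights are
#' `b = P^{-1} C v`; the genetic covariance matrix is iterated through the
#' Bulmer recursion `G' = G/2 - (k_m + k_f)/4 (cc')/sigma_I^2 + G0/2` to its
#' equilibrium, and responses are reported at equilibrium as
#' `R_j = i_bar Cov(I, g_j) / sigma_I`, averaged over the sire and dam
#' selection paths.
#'
#' @param scheme A [scheme_config()].
#' @param params List with `G` (genetic covariance over the goal traits),
#'   `env` (environmental components per record type) and `r_phen`
#'   (phenotypic correlations), as from [default_scheme_params()].
#' @param objective A [breeding_objective()].
#' @param tol Convergence tolerance of the equilibrium iteration.
#' @param max_iter Maximum iterations.
#' @return A `cuni_response`: list with `response` (trait units per
#'   generation), `response_sd` (in base genetic standard deviations),
#'   `accuracy` (index-objective correlation per path), `sigma_I`,
#'   `intensity`, `G_eq` (equilibrium genetic covariance), `sources`,
#'   `b` (index weights) and `iterations`.
#' @export
predict_response <- function(scheme, params, objective, tol = 1e-9,
                             max_iter = 100) {
  stopifnot(inherits(scheme, "cuni_scheme"), inherits(objective, "cuni_objective"))
  G0 <- as.matrix(params$G)
  traits <- colnames(G0)
  v <- .align_weights(objective, traits)
  tmpl <- .template_family()
  env <- params$env
  ecov <- .ecov_table(G0, env, params$r_phen, tmpl, scheme$dam_records_nba)
  sources <- .build_sources(scheme)
  if (!length(sources)) stop("the scheme records no information sources")
  ns <- length(sources)

  p_m <- scheme$selected_fraction_males
  p_f <- scheme$selected_fraction_females
  N_m <- scheme$n_sires / p_m
  N_f <- scheme$n_dams / p_f
  i_m <- selection_intensity(p_m, N_m, scheme$rho_candidates)
  i_f <- selection_intensity(p_f, N_f, scheme$rho_candidates)
  k_m <- i_m * (i_m - stats::qnorm(1 - p_m))
  k_f <- i_f * (i_f - stats::qnorm(1 - p_f))
  ibar <- (i_m + i_f) / 2
  kbar <- (k_m + k_f) / 2

  G <- G0
  prev <- NULL   # previous-generation index summaries for the parent rows
  resp <- stats::setNames(rep(0, length(traits)), traits)
  out_b <- NULL
  sI2 <- 0
  for (it in seq_len(max_iter)) {
    P <- matrix(0, ns, ns, dimnames = list(names(sources), names(sources)))
    for (i in seq_len(ns)) for (j in i:ns) {
      P[i, j] <- P[j, i] <- .cov_sources(sources[[i]], sources[[j]], G, env,
                                         tmpl, scheme, ecov)
    }
    C <- t(vapply(sources, .cov_source_g, numeric(length(traits)),
                  G = G, tmpl = tmpl))
    rown <- names(sources)
    if (scheme$parent_index && !is.null(prev) && prev$sI2 > 1e-12) {
      # parent index rows: sire and dam index values from the previous
      # (equilibrium-converging) generation
      chi_s <- .parent_chi("sire"); chi_d <- .parent_chi("dam")
      cov_par_src <- function(chi, kp) {
        vapply(sources, function(s) {
          rep_of <- c(own = "X", fs = "F1", hs = "H1a", dam = "D")
          a <- rep_of[[s$class]]
          tot <- 0
          for (l in .rec_loads(a, s$type, tmpl)) {
            if (is.na(l[1])) next
            tot <- tot + chi[[l[1]]] * prev$c[l[2]]
          }
          (1 - kp) * tot
        }, 0)
      }
      ps_row <- cov_par_src(chi_s, k_m)
      pd_row <- cov_par_src(chi_d, k_f)
      P <- rbind(cbind(P, sire_index = ps_row, dam_index = pd_row),
                 sire_index = c(ps_row, (1 - k_m) * prev$sI2, 0),
                 dam_index = c(pd_row, 0, (1 - k_f) * prev$sI2))
      C <- rbind(C, sire_index = (1 - k_m) * 0.5 * prev$c,
                 dam_index = (1 - k_f) * 0.5 * prev$c)
      rown <- c(rown, "sire_index", "dam_index")
    }
    cv <- as.vector(C %*% v)
    if (!all(is.finite(P)) || !all(is.finite(cv)))
      stop("non-finite information matrix; the equilibrium iteration ",
           "diverged for objective '", objective$name, "'")
    scaleP <- max(diag(P))
    if (!is.finite(scaleP) || scaleP <= 0)
      stop("singular information matrix P; sources: ",
           paste(rown, collapse = ", "))
    b <- tryCatch(solve(P, cv), error = function(e) NULL)
    if (is.null(b))  # near-singular (e.g. vanishing parent-index variance):
      b <- tryCatch(solve(P + diag(1e-10 * scaleP, nrow(P)), cv),
                    error = function(e)
                      stop("singular information matrix P; sources: ",
                           paste(rown, collapse = ", ")))
    sI2_new <- sum(b * cv)
    sH0 <- as.numeric(t(v) %*% G0 %*% v)
    if (sI2_new <= 1e-12 * max(1, sH0)) {
      resp_new <- stats::setNames(rep(0, length(traits)), traits)
      c_full <- stats::setNames(rep(0, length(traits)), traits)
      sI2_new <- 0
    } else {
      c_full <- as.vector(t(C) %*% b)
      names(c_full) <- traits
      resp_new <- ibar * c_full / sqrt(sI2_new)
    }
    # Bulmer update of the genetic covariance among the next candidates
    G_new <- if (scheme$bulmer && sI2_new > 0)
      0.5 * G - 0.25 * (k_m + k_f) * tcrossprod(c_full) / sI2_new + 0.5 * G0
    else G
    done <- max(abs(resp_new - resp)) < tol &&
      (is.null(prev) || max(abs(G_new - G)) < tol * max(1, max(abs(G0))))
    resp <- resp_new
    out_b <- stats::setNames(b, rown)
    sI2 <- sI2_new
    prev <- list(c = c_full, sI2 = sI2_new)
    G <- G_new
    if (done && it > 1) break
  }
  sH2 <- as.numeric(t(v) %*% G %*% v)
  sd0 <- sqrt(pmax(diag(G0), 0))
  structure(list(
    response = resp,
    response_sd = ifelse(sd0 > 0, resp / sd0, 0),
    accuracy = if (sH2 > 0) sqrt(sI2 / sH2) else 0,
    sigma_I = sqrt(max(sI2, 0)),
    intensity = c(males = i_m, females = i_f, mean = ibar),
    k = c(males = k_m, females = k_f),
    G_eq = G, sources = names(sources), b = out_b, iterations = it,
    objective = objective$name),
    class = "cuni_response")
}

#' @export
print.cuni_response <- function(x, ...) {
  cat(sprintf("<cuni_response> objective %s | accuracy %.3f | sigma_I %.3f\n",
              x$objective, x$accuracy, x$sigma_I))
  df <- data.frame(response = x$response, in_sigma_a = x$response_sd)
  print(round(df, 4))
  invisible(x)
}

#' Response table over objectives and recording modalities
#'
#' Predicts per-generation responses for each breeding objective under each
#' applicable Resist_Ch recording modality, in the layout of a
#' scheme-comparison report (rows = traits, columns = scenario x recording).
#'
#' @param objectives Named list of [breeding_objective()]s.
#' @param params As in [predict_response()].
#' @param scheme Base [scheme_config()]; recording switches are set per
#'   scenario.
#' @return Data frame of responses, one column per scenario.
#' @export
response_table <- function(objectives, params,
                           scheme = scheme_config()) {
  cols <- list()
  for (nm in names(objectives)) {
    obj <- objectives[[nm]]
    has_dis <- any(c("Resist_S", "Resist_Ch") %in% names(obj$weights))
    modes <- if (has_dis) c(TRUE, FALSE) else FALSE
    for (rec_ch in modes) {
      sc <- scheme
      sc$record_resist_s <- has_dis
      sc$record_resist_ch <- rec_ch
      r <- predict_response(sc, params, obj)
      cols[[paste0(nm, if (has_dis) (if (rec_ch) "_recCh" else "_noCh") else "")]] <-
        r$response
    }
  }
  as.data.frame(cols)
}
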