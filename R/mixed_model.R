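#' Model specification for an animal model
#'
#' Declares the response, fixed factors, random terms and link of a
#' single-trait animal model. Random terms are named incidence rules:
#' \describe{
#'   \item{`animal`}{direct additive genetic effect, A-structured over the
#'     pedigree (for litter-level traits the doe's additive effect).}
#'   \item{`litter`}{common rearing-litter environment, iid.}
#'   \item{`maternal_env`}{rearing-dam environment, iid.}
#'   \item{`maternal_genetic`}{rearing-dam additive genetic effect,
#'     A-structured; when present together with `animal` the two form one
#'     correlated genetic term (direct + maternal).}
#'   \item{`perm_env`}{doe permanent environment for repeated litter records,
#'     iid.}
#' }
#' Fostered kits carry the adoptive dam in `rearing_dam`/`rearing_litter`,
#' so their maternal and litter incidences point to the adoptive mother
#' while `animal` follows the biological pedigree.
#'
#' @param trait Response column name in the phenotype table.
#' @param fixed Character vector of fixed factor column names.
#' @param random Character vector of random term names (see Details).
#' @param link `"identity"` for linear models, `"logit"` for threshold
#'   (liability) models of binary traits.
#' @param unit `"animal"` (one record per animal) or `"litter"` (one record
#'   per doe-parity).
#' @param environment Optional `"S"`/`"Ch"` subset of the records.
#' @param label Trait label used in multi-trait output (defaults to
#'   `trait`/`trait_env`).
#' @return A `cuni_model_spec`.
#' @export
model_spec <- function(trait, fixed = character(), random = "animal",
                       link = c("identity", "logit"),
                       unit = c("animal", "litter"), environment = NULL,
                       label = NULL) {
  link <- match.arg(link)
  unit <- match.arg(unit)
  known <- c("animal", "litter", "maternal_env", "maternal_genetic", "perm_env")
  if (!all(random %in% known))
    stop("unknown random term(s): ", paste(setdiff(random, known), collapse = ", "))
  if (is.null(label))
    label <- if (is.null(environment)) trait else paste(trait, environment, sep = "_")
  structure(list(trait = trait, fixed = fixed, random = random, link = link,
                 unit = unit, environment = environment, label = label),
            class = "cuni_model_spec")
}

#' Assemble design matrices for one or several traits
#'
#' Builds the response, fixed-effect and random-term incidence matrices for a
#' (possibly multi-trait) animal model from a pedigree and phenotype tables.
#' Fixed factors use reference-level (corner) contrasts in file order.
#' Maternal and litter terms are indexed by the rearing dam / rearing litter,
#' so cross-fostered kits load on the adoptive mother.
#'
#' @param specs A [model_spec()] or list of them (multi-trait).
#' @param ped A [as_pedigree()] pedigree.
#' @param pheno Phenotype list with `animals` and optionally `litters` data
#'   frames (as produced by [simulate_population()]).
#' @return A `cuni_design` bundle used by [reml_fit()] and
#'   [fit_threshold_trait()].
#' @export
build_design <- function(specs, ped, pheno) {
  if (inherits(specs, "cuni_model_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, inherits(ped, "cuni_pedigree"))
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate trait labels")

  per <- lapply(specs, .design_one_trait, ped = ped, pheno = pheno)
  y <- unlist(lapply(per, `[[`, "y"), use.names = FALSE)
  n_t <- vapply(per, function(d) length(d$y), 0L)
  trait_of_obs <- rep(seq_along(per), n_t)
  units <- unlist(lapply(per, `[[`, "unit_id"), use.names = FALSE)

  # block-diagonal fixed-effects matrix, full rank within trait
  Xs <- lapply(per, `[[`, "X")
  X <- as.matrix(Matrix::bdiag(Xs))
  assign <- unlist(lapply(seq_along(per), function(t)
    paste(labels[t], per[[t]]$assign, sep = ":")), use.names = FALSE)
  colnames(X) <- unlist(lapply(seq_along(per), function(t)
    paste(labels[t], colnames(per[[t]]$X), sep = ":")), use.names = FALSE)

  # group random terms across traits
  group_of <- c(animal = "genetic", maternal_genetic = "genetic",
                litter = "litter", maternal_env = "maternal_env",
                perm_env = "perm_env")
  terms <- list()
  Ainv <- NULL
  for (t in seq_along(per)) {
    for (rn in names(per[[t]]$rterms)) {
      g <- group_of[[rn]]
      eff <- per[[t]]$rterms[[rn]]
      eff$trait <- t
      eff$name <- paste(labels[t],
                        if (rn == "maternal_genetic") "maternal"
                        else if (rn == "animal" && g == "genetic") "direct"
                        else rn, sep = ":")
      terms[[g]] <- c(terms[[g]], list(eff))
    }
  }
  n <- length(y)
  term_list <- list()
  for (g in names(terms)) {
    effs <- terms[[g]]
    struct <- if (g == "genetic") "A" else "I"
    if (struct == "A") {
      if (is.null(Ainv)) Ainv <- compute_A_inverse(ped)
      q <- nrow(Ainv)
      levels <- ped$animal
    } else {
      levels <- sort(unique(unlist(lapply(effs, function(e) e$level_id))))
      q <- length(levels)
    }
    Zs <- lapply(effs, function(e) {
      rows <- which(trait_of_obs == e$trait)
      j <- match(e$level_id, levels)
      Matrix::sparseMatrix(i = rows, j = j, x = 1, dims = c(n, q))
    })
    term_list[[g]] <- list(
      name = g, struct = struct, q = q, levels = levels,
      effects = vapply(effs, `[[`, "", "name"),
      Z = do.call(cbind, Zs),
      Ainv = if (struct == "A") Ainv else NULL)
  }
  # cache log|A| for the likelihood constant
  for (g in names(term_list)) {
    tm <- term_list[[g]]
    term_list[[g]]$logdetA <- if (tm$struct == "A")
      -2 * determinant(Matrix::Cholesky(tm$Ainv, LDL = FALSE), sqrt = TRUE)$modulus[1]
    else 0
  }
  structure(list(y = y, X = X, assign = assign, traits = labels,
                 trait_of_obs = trait_of_obs, units = units,
                 terms = term_list, specs = specs, n = n),
            class = "cuni_design")
}

.design_one_trait <- function(spec, ped, pheno) {
  data <- if (spec$unit == "animal") pheno$animals else pheno$litters
  if (is.null(data)) stop("no phenotype table for unit '", spec$unit, "'")
  if (!is.null(spec$environment))
    data <- data[data$environment == spec$environment, , drop = FALSE]
  if (!spec$trait %in% names(data))
    stop("trait '", spec$trait, "' not found in phenotype table")
  keep <- !is.na(data[[spec$trait]])
  for (f in spec$fixed) {
    if (!f %in% names(data))
      stop("fixed factor '", f, "' not found in phenotype table")
    keep <- keep & !is.na(data[[f]])
  }
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[spec$trait]])
  # factors with a single observed level are unestimable under corner
  # constraints; drop them
  single <- vapply(spec$fixed, function(f)
    length(unique(data[[f]])) < 2, TRUE)
  spec$fixed <- spec$fixed[!single]
  fml <- if (length(spec$fixed))
    stats::as.formula(paste("~", paste(spec$fixed, collapse = "+")))
  else ~1
  for (f in spec$fixed) data[[f]] <- factor(data[[f]])
  X <- stats::model.matrix(fml, data)
  asg <- attr(X, "assign")
  asg_name <- c("(Intercept)", spec$fixed)[asg + 1L]
  # drop rank-deficient columns (aliased levels)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_c <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, keep_c, drop = FALSE]
    asg_name <- asg_name[keep_c]
  }

  rterms <- list()
  for (rn in spec$random) {
    level_id <- switch(rn,
      animal = if (spec$unit == "animal") data$animal else data$dam,
      maternal_genetic = data$rearing_dam,
      litter = data$rearing_litter,
      maternal_env = data$rearing_dam,
      perm_env = data$dam)
    if (anyNA(level_id))
      stop("missing level for random term '", rn, "'")
    bad <- if (rn %in% c("animal", "maternal_genetic"))
      !(level_id %in% ped$animal) else rep(FALSE, length(level_id))
    if (any(bad))
      stop("level '", level_id[bad][1], "' of term '", rn,
           "' is not in the pedigree")
    rterms[[rn]] <- list(level_id = as.character(level_id))
  }
  unit_id <- if (spec$unit == "animal") as.character(data$animal)
             else paste(data$dam, data$parity, sep = ":")
  list(y = y, X = X, assign = asg_name, rterms = rterms,
       unit_id = paste(spec$unit, unit_id, sep = ":"), data = data)
}

# ---------------------------------------------------------------------------
# REML engine: derivative-free evaluation of the restricted log-likelihood
# through sparse mixed-model equations.

# parameter layout: for each term a log-Cholesky vector of its t x t
# covariance (diagonal first as log-sd, then row-wise off-diagonals), then
# residual log-sds per trait (+ atanh correlations for shared-unit pairs),
# unless the residual is fixed.
.theta_layout <- function(design, fix_residual, residual_cov) {
  lay <- list()
  off <- 0L
  for (g in names(design$terms)) {
    t_k <- length(design$terms[[g]]$effects)
    npar <- t_k * (t_k + 1) / 2
    lay[[g]] <- list(offset = off, t = t_k, n = npar)
    off <- off + npar
  }
  nt <- length(design$traits)
  res <- NULL
  if (is.null(fix_residual)) {
    ncor <- if (residual_cov && nt > 1) nt * (nt - 1) / 2 else 0L
    res <- list(offset = off, t = nt, n = nt + ncor, cor = ncor > 0)
    off <- off + res$n
  }
  list(terms = lay, residual = res, n = off)
}

.chol_from_par <- function(par, t) {
  L <- matrix(0, t, t)
  diag(L) <- exp(par[seq_len(t)])
  if (t > 1) L[lower.tri(L)] <- par[(t + 1):length(par)]
  L %*% t(L)
}

.par_from_cov <- function(S) {
  t <- nrow(S)
  L <- t(chol(S + diag(1e-10 * max(diag(S), 1), t)))
  c(log(diag(L)), L[lower.tri(L)])
}

.theta_to_vc <- function(theta, design, lay, fix_residual) {
  vc <- list()
  for (g in names(lay$terms)) {
    li <- lay$terms[[g]]
    S <- .chol_from_par(theta[li$offset + seq_len(li$n)], li$t)
    dimnames(S) <- list(design$terms[[g]]$effects, design$terms[[g]]$effects)
    vc[[g]] <- S
  }
  nt <- length(design$traits)
  if (is.null(lay$residual)) {
    Se <- diag(fix_residual, nt)
  } else {
    li <- lay$residual
    sds <- exp(theta[li$offset + seq_len(nt)])
    Se <- diag(sds^2, nt)
    if (li$cor) {
      rs <- tanh(theta[li$offset + nt + seq_len(li$n - nt)])
      k <- 1L
      for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
        Se[i, j] <- Se[j, i] <- rs[k] * sds[i] * sds[j]
        k <- k + 1L
      }
    }
  }
  dimnames(Se) <- list(design$traits, design$traits)
  vc$residual <- Se
  vc
}

# residual inverse and log-determinant given the residual covariance;
# shared observation units get dense within-unit blocks
.make_Rinv <- function(design, Se, weights = NULL) {
  n <- design$n
  tr <- design$trait_of_obs
  if (!is.null(weights)) {
    rinv <- weights / Se[1, 1]
    return(list(Rinv = Matrix::Diagonal(n, rinv),
                logdet = sum(log(Se[1, 1] / weights))))
  }
  dup <- duplicated(design$units) | duplicated(design$units, fromLast = TRUE)
  if (!any(dup) || all(abs(Se[lower.tri(Se)]) < 1e-300)) {
    v <- diag(Se)[tr]
    return(list(Rinv = Matrix::Diagonal(n, 1 / v), logdet = sum(log(v))))
  }
  ii <- jj <- integer(0); xx <- numeric(0); logdet <- 0
  singles <- which(!dup)
  ii <- singles; jj <- singles; xx <- 1 / diag(Se)[tr[singles]]
  logdet <- sum(log(diag(Se)[tr[singles]]))
  for (u in unique(design$units[dup])) {
    rows <- which(design$units == u)
    S <- Se[tr[rows], tr[rows], drop = FALSE]
    Si <- solve(S)
    logdet <- logdet + determinant(S, logarithm = TRUE)$modulus[1]
    ii <- c(ii, rep(rows, each = length(rows)))
    jj <- c(jj, rep(rows, times = length(rows)))
    xx <- c(xx, as.vector(Si))
  }
  list(Rinv = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)),
       logdet = logdet)
}

.reml_neg2 <- function(theta, env) {
  d <- env$design
  vc <- .theta_to_vc(theta, d, env$lay, env$fix_residual)
  R <- .make_Rinv(d, vc$residual, env$weights)
  W <- env$W
  p <- ncol(d$X)
  n <- d$n
  WtRi <- Matrix::t(W) %*% R$Rinv
  M <- WtRi %*% W
  rhs <- as.vector(WtRi %*% d$y)
  # G inverse blocks + likelihood constants
  Ginv_list <- list()
  logG <- 0
  for (g in names(d$terms)) {
    tm <- d$terms[[g]]
    S <- vc[[g]]
    dS <- determinant(S, logarithm = TRUE)
    if (dS$sign <= 0) return(1e10)
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si)) return(1e10)
    K <- if (tm$struct == "A") tm$Ainv else Matrix::Diagonal(tm$q)
    Ginv_list[[g]] <- kronecker(Si, K)
    logG <- logG + tm$q * dS$modulus[1] + length(tm$effects) * tm$logdetA
  }
  Ginv <- Matrix::bdiag(c(list(Matrix::Matrix(0, p, p, sparse = TRUE)), Ginv_list))
  C <- Matrix::forceSymmetric(M + Ginv)
  ch <- tryCatch(suppressWarnings(Matrix::Cholesky(C, LDL = FALSE)),
                 error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetC <- 2 * determinant(ch, sqrt = TRUE)$modulus[1]
  sol <- as.vector(Matrix::solve(ch, rhs))
  yRy <- sum(d$y * as.vector(R$Rinv %*% d$y))
  yPy <- yRy - sum(rhs * sol)
  val <- (n - p) * log(2 * pi) + R$logdet + logG + logdetC + yPy
  env$last <- list(sol = sol, chol = ch, vc = vc, yPy = yPy)
  as.numeric(val)
}

#' REML fit of a (multi-trait) linear animal model
#'
#' Estimates variance components by restricted maximum likelihood. The
#' restricted log-likelihood is evaluated exactly through sparse
#' mixed-model equations (Cholesky factorization of the coefficient
#' matrix) and maximized over a log-Cholesky parameterization of the
#' per-term covariance matrices (Nelder-Mead followed by a BFGS polish;
#' one-parameter problems use Brent's method). The sampling covariance of
#' the variance components is the inverse numerical observed information
#' at the optimum.
#'
#' Residual covariance between traits is only estimated for traits sharing
#' observation units; traits recorded on disjoint animals (e.g. the same
#' disease trait in the S and Ch environments) have their residual
#' covariance constrained to zero exactly.
#'
#' @param design A [build_design()] bundle.
#' @param start Optional named list of starting covariance matrices.
#' @param fix_residual Fix the residual variance at this value (threshold
#'   working scale); `NULL` to estimate.
#' @param weights Optional per-observation working weights (residual
#'   variance `fix_residual / w`).
#' @param residual_cov Estimate residual covariances between traits sharing
#'   units (default: yes, when such units exist).
#' @param vcov Compute the sampling covariance of the variance components.
#' @param control List: `maxit`, `reltol`, `boundary` (variance floor as a
#'   fraction of total variance).
#' @return A `cuni_fit` with elements `varcomp` (list of covariance
#'   matrices, one per random term plus `residual`), `loglik`, `fixef`,
#'   `vcov_fixef`, `ranef`, `vcov_varcomp`, `converged`, `boundary`.
#' @export
reml_fit <- function(design, start = NULL, fix_residual = NULL,
                     weights = NULL, residual_cov = NULL, vcov = TRUE,
                     control = list()) {
  stopifnot(inherits(design, "cuni_design"))
  ctl <- utils::modifyList(list(maxit = 2000, reltol = 1e-12,
                                boundary = 1e-7), control)
  shared <- any(duplicated(design$units))
  if (is.null(residual_cov)) residual_cov <- shared
  if (residual_cov && !shared) residual_cov <- FALSE
  lay <- .theta_layout(design, fix_residual, residual_cov)
  env <- new.env()
  env$design <- design
  env$lay <- lay
  env$fix_residual <- fix_residual
  env$weights <- weights
  env$W <- cbind(Matrix::Matrix(design$X, sparse = TRUE),
                 do.call(cbind, lapply(design$terms, `[[`, "Z")))

  vy <- stats::var(design$y)
  degenerate <- !is.finite(vy) || vy <= 1e-12 * max(1, mean(design$y)^2)
  if (degenerate) {
    # constant response: every variance is at the lower boundary
    vy <- 1
    theta_fix <- numeric(lay$n)
    for (g in names(lay$terms)) {
      li <- lay$terms[[g]]
      theta_fix[li$offset + seq_len(li$n)] <-
        .par_from_cov(diag(1e-8, li$t))
    }
    if (!is.null(lay$residual)) {
      li <- lay$residual
      theta_fix[li$offset + seq_len(li$t)] <- log(sqrt(1e-8))
    }
  }
  theta0 <- numeric(lay$n)
  k_terms <- length(design$terms) + is.null(fix_residual)
  for (g in names(lay$terms)) {
    li <- lay$terms[[g]]
    S0 <- if (!is.null(start[[g]])) start[[g]]
          else diag(vy / (k_terms + 1), li$t)
    theta0[li$offset + seq_len(li$n)] <- .par_from_cov(as.matrix(S0))
  }
  if (!is.null(lay$residual)) {
    li <- lay$residual
    s0 <- if (!is.null(start$residual)) sqrt(diag(as.matrix(start$residual)))
          else rep(sqrt(vy / 2), li$t)
    theta0[li$offset + seq_len(li$t)] <- log(s0)
  }

  f <- function(th) .reml_neg2(th, env)
  converged <- TRUE
  if (degenerate) {
    opt <- list(par = theta_fix, value = f(theta_fix), convergence = 0)
  } else if (lay$n == 1 && !length(design$terms)) {
    # fixed effects only: REML residual variance has the closed form
    # RSS / (n - p)
    qrX <- qr(design$X)
    rss <- sum(qr.resid(qrX, design$y)^2)
    opt <- list(par = log(sqrt(rss / (design$n - ncol(design$X)))),
                value = NA_real_, convergence = 0)
    opt$value <- f(opt$par)
  } else if (lay$n == 1) {
    opt <- stats::optim(theta0, f, method = "Brent", lower = theta0 - 25,
                        upper = theta0 + 25,
                        control = list(reltol = ctl$reltol))
  } else {
    opt <- stats::optim(theta0, f, method = "Nelder-Mead",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
    opt2 <- tryCatch(
      stats::optim(opt$par, f, method = "BFGS",
                   control = list(maxit = 200, reltol = ctl$reltol,
                                  ndeps = rep(1e-5, lay$n))),
      error = function(e) NULL)
    if (!is.null(opt2) && opt2$value <= opt$value) opt <- opt2
    # coordinate-wise Brent polish for high-precision optima
    if (isTRUE(ctl$polish %||% TRUE)) {
      for (sweep in 1:2) {
        improved <- 0
        for (i in seq_len(lay$n)) {
          oi <- stats::optimize(function(v) {
            th <- opt$par; th[i] <- v; f(th)
          }, interval = opt$par[i] + c(-0.3, 0.3), tol = 1e-12)
          if (oi$objective < opt$value) {
            improved <- improved + (opt$value - oi$objective)
            opt$par[i] <- oi$minimum
            opt$value <- oi$objective
          }
        }
        if (improved < 1e-8) break
      }
      converged <- improved < 1e-4
    } else {
      converged <- opt$convergence == 0
    }
  }
  neg2 <- f(opt$par)  # refresh env$last at the optimum
  vc <- env$last$vc

  # boundary flags
  floorv <- ctl$boundary * vy
  boundary <- character(0)
  for (g in names(vc)) {
    dv <- diag(as.matrix(vc[[g]]))
    low <- dv < floorv
    if (any(low) && g != "residual")
      boundary <- c(boundary, paste(g, names(dv %||% seq_along(dv))[low]))
  }

  # solutions: fixed and random effects at the optimum
  p <- ncol(design$X)
  sol <- env$last$sol
  fixef <- stats::setNames(sol[seq_len(p)], colnames(design$X))
  Vb <- tryCatch({
    E <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                              dims = c(length(sol), p))
    as.matrix(Matrix::solve(env$last$chol, E))[seq_len(p), , drop = FALSE]
  }, error = function(e) matrix(NA_real_, p, p))
  dimnames(Vb) <- list(names(fixef), names(fixef))
  ranef <- list()
  off <- p
  for (g in names(design$terms)) {
    tm <- design$terms[[g]]
    t_k <- length(tm$effects)
    u <- matrix(sol[off + seq_len(tm$q * t_k)], ncol = t_k)
    dimnames(u) <- list(tm$levels, tm$effects)
    ranef[[g]] <- u
    off <- off + tm$q * t_k
  }

  fit <- structure(list(
    varcomp = vc, theta = opt$par, loglik = -neg2 / 2, neg2 = neg2,
    fixef = fixef, vcov_fixef = Vb, ranef = ranef,
    converged = converged, boundary = boundary,
    design = design, lay = lay, fix_residual = fix_residual,
    weights = weights, residual_cov = residual_cov,
    n = design$n, p = p), class = "cuni_fit")
  if (vcov) fit$vcov_varcomp <- .varcomp_vcov(fit, env)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# natural-scale variance parameter vector (vech per term + residual)
.vc_natural <- function(vc, residual_cov, fixed_res) {
  out <- numeric(0)
  for (g in names(vc)) {
    S <- as.matrix(vc[[g]])
    t <- nrow(S)
    if (g == "residual") {
      if (fixed_res) next
      v <- diag(S)
      names(v) <- paste0("residual:", colnames(S) %||% seq_len(t))
      out <- c(out, v)
      if (residual_cov && t > 1) {
        for (i in seq_len(t - 1)) for (j in (i + 1):t) {
          cv <- S[i, j]
          names(cv) <- paste0("residual:cov(", i, ",", j, ")")
          out <- c(out, cv)
        }
      }
    } else {
      nm <- colnames(S) %||% as.character(seq_len(t))
      for (i in seq_len(t)) for (j in i:t) {
        v <- S[j, i]
        names(v) <- if (i == j) paste0(g, ":var(", nm[i], ")")
                    else paste0(g, ":cov(", nm[i], ",", nm[j], ")")
        out <- c(out, v)
      }
    }
  }
  out
}

.natural_to_vclist <- function(v, template, residual_cov, fixed_res) {
  out <- template
  k <- 1L
  for (g in names(template)) {
    S <- as.matrix(template[[g]])
    t <- nrow(S)
    if (g == "residual") {
      if (fixed_res) next
      for (i in seq_len(t)) { S[i, i] <- v[k]; k <- k + 1L }
      if (residual_cov && t > 1)
        for (i in seq_len(t - 1)) for (j in (i + 1):t) {
          S[i, j] <- S[j, i] <- v[k]; k <- k + 1L
        }
    } else {
      for (i in seq_len(t)) for (j in i:t) {
        S[j, i] <- S[i, j] <- v[k]; k <- k + 1L
      }
    }
    out[[g]] <- S
  }
  out
}

# evaluate -2 restricted log-likelihood at arbitrary covariance values
.neg2_at_vc <- function(vclist, fit) {
  lay <- fit$lay
  theta <- numeric(lay$n)
  ok <- TRUE
  for (g in names(lay$terms)) {
    li <- lay$terms[[g]]
    S <- as.matrix(vclist[[g]])
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(NA_real_)
    theta[li$offset + seq_len(li$n)] <- .par_from_cov(S)
  }
  if (!is.null(lay$residual)) {
    li <- lay$residual
    Se <- as.matrix(vclist$residual)
    sds <- sqrt(diag(Se))
    theta[li$offset + seq_len(li$t)] <- log(sds)
    if (li$cor) {
      k <- 1L
      for (i in seq_len(li$t - 1)) for (j in (i + 1):li$t) {
        r <- Se[i, j] / (sds[i] * sds[j])
        if (abs(r) >= 1) return(NA_real_)
        theta[li$offset + li$t + k] <- atanh(r)
        k <- k + 1L
      }
    }
  }
  env <- new.env()
  env$design <- fit$design
  env$lay <- lay
  env$fix_residual <- fit$fix_residual
  env$weights <- fit$weights
  env$W <- cbind(Matrix::Matrix(fit$design$X, sparse = TRUE),
                 do.call(cbind, lapply(fit$design$terms, `[[`, "Z")))
  .reml_neg2(theta, env)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood of a fitted model's design at an
#' arbitrary set of covariance matrices (same structure as `fit$varcomp`).
#' Used for likelihood-ratio tests of constrained models and for
#' local-optimality checks.
#'
#' @param fit A [reml_fit()] result.
#' @param varcomp Named list of covariance matrices.
#' @return Log-likelihood value (`NA` if the covariances are not positive
#'   definite).
#' @export
reml_loglik_at <- function(fit, varcomp) {
  v <- .neg2_at_vc(varcomp, fit)
  if (is.na(v)) return(NA_real_)
  -v / 2
}

.varcomp_vcov <- function(fit, env) {
  v0 <- .vc_natural(fit$varcomp, fit$residual_cov, !is.null(fit$fix_residual))
  np <- length(v0)
  template <- fit$varcomp
  fn <- function(v) {
    vl <- .natural_to_vclist(v, template, fit$residual_cov,
                             !is.null(fit$fix_residual))
    .neg2_at_vc(vl, fit)
  }
  h <- pmax(abs(v0) * 1e-3, 1e-7)
  H <- matrix(NA_real_, np, np)
  f0 <- fn(v0)
  fp <- fm <- numeric(np)
  for (i in seq_len(np)) {
    vi <- v0; vi[i] <- v0[i] + h[i]; fp[i] <- fn(vi)
    vi <- v0; vi[i] <- v0[i] - h[i]; fm[i] <- fn(vi)
  }
  for (i in seq_len(np)) {
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
    if (i < np) for (j in (i + 1):np) {
      vpp <- v0; vpp[i] <- v0[i] + h[i]; vpp[j] <- v0[j] + h[j]
      vmm <- v0; vmm[i] <- v0[i] - h[i]; vmm[j] <- v0[j] - h[j]
      fpp <- fn(vpp); fmm <- fn(vmm)
      H[i, j] <- H[j, i] <-
        (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h[i] * h[j])
    }
  }
  dimnames(H) <- list(names(v0), names(v0))
  if (anyNA(H)) return(structure(H * NA_real_, note = "boundary"))
  V <- tryCatch(2 * solve(H), error = function(e) MASS::ginv(H) * 2)
  dimnames(V) <- dimnames(H)
  V
}

#' @export
print.cuni_fit <- function(x, ...) {
  cat(sprintf("<cuni_fit> traits: %s | logLik(REML) = %.3f%s\n",
              paste(x$design$traits, collapse = ", "), x$loglik,
              if (!x$converged) " (NOT converged)" else ""))
  for (g in names(x$varcomp)) {
    S <- as.matrix(x$varcomp[[g]])
    if (nrow(S) == 1) cat(sprintf("  %-12s %.6g\n", g, S[1, 1]))
    else {
      cat(sprintf("  %s:\n", g))
      print(round(S, 6))
    }
  }
  if (length(x$boundary))
    cat("  boundary:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Relative residual of the mixed-model equations at the solution
#'
#' Diagnostic for the invariant that BLUE/BLUP solutions satisfy the
#' Henderson equations.
#'
#' @param fit A [reml_fit()] result.
#' @return Maximum relative residual of the linear system.
#' @export
mme_residual <- function(fit) {
  d <- fit$design
  vc <- fit$varcomp
  R <- .make_Rinv(d, vc$residual, fit$weights)
  W <- cbind(Matrix::Matrix(d$X, sparse = TRUE),
             do.call(cbind, lapply(d$terms, `[[`, "Z")))
  WtRi <- Matrix::t(W) %*% R$Rinv
  M <- WtRi %*% W
  p <- ncol(d$X)
  Ginv_list <- lapply(names(d$terms), function(g) {
    tm <- d$terms[[g]]
    K <- if (tm$struct == "A") tm$Ainv else Matrix::Diagonal(tm$q)
    kronecker(solve(as.matrix(vc[[g]])), K)
  })
  C <- Matrix::forceSymmetric(M + Matrix::bdiag(
    c(list(Matrix::Matrix(0, p, p, sparse = TRUE)), Ginv_list)))
  rhs <- as.vector(WtRi %*% d$y)
  sol <- c(fit$fixef, unlist(lapply(fit$ranef, function(u) as.vector(u))))
  r <- as.vector(C %*% sol) - rhs
  max(abs(r)) / max(1, max(abs(rhs)))
}
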