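#' Breeding objectives over true breeding values
#'
#' A breeding objective is a linear combination `H = w' A` of the true
#' breeding values of the goal traits, with weights in currency units per
#' physical trait unit (here: NBA in kits, WW_direct and WW_maternal in g,
#' Resist_S and Resist_Ch in percentage points of disease incidence).
#'
#' @param name Objective name.
#' @param weights Named numeric vector of weights (euro per trait unit).
#' @return A `cuni_objective`.
#' @export
breeding_objective <- function(name, weights) {
  stopifnot(is.numeric(weights), length(names(weights)) == length(weights),
            all(is.finite(weights)))
  structure(list(name = name, weights = weights), class = "cuni_objective")
}

#' The four reference breeding objectives
#'
#' Production-only plus three variants adding resistance to non-specific
#' disease recorded in the selection environment, the challenging
#' environment, or both (disease weights negative: lower incidence is
#' favourable).
#'
#' @return Named list of [breeding_objective()]s.
#' @export
default_breeding_objectives <- function() {
  base <- c(NBA = 3, WW_direct = 0.15, WW_maternal = 0.15)
  list(
    HResist_S = breeding_objective("HResist_S", c(base, Resist_S = -130)),
    HResist_Ch = breeding_objective("HResist_Ch", c(base, Resist_Ch = -130)),
    HResist_S_Ch = breeding_objective("HResist_S_Ch",
                                      c(base, Resist_S = -65, Resist_Ch = -65)),
    HProduction = breeding_objective("HProduction", base)
  )
}

.align_weights <- function(obj, traits) {
  missing <- setdiff(names(obj$weights), traits)
  if (length(missing))
    stop("objective '", obj$name, "' weights trait(s) absent from the ",
         "genetic covariance matrix: ", paste(missing, collapse = ", "))
  w <- stats::setNames(numeric(length(traits)), traits)
  w[names(obj$weights)] <- obj$weights
  w
}

#' Covariance between two breeding objectives
#'
#' `Cov(H_i, H_j) = w_i' G w_j` with `G` the genetic covariance matrix of
#' the union of the traits; traits absent from an objective carry weight 0.
#'
#' @param wi,wj [breeding_objective()]s.
#' @param G Genetic covariance matrix with trait dimnames.
#' @return The covariance (currency^2).
#' @export
objective_covariance <- function(wi, wj, G) {
  G <- as.matrix(G)
  traits <- colnames(G)
  a <- .align_weights(wi, traits)
  b <- .align_weights(wj, traits)
  as.numeric(t(a) %*% G %*% b)
}

#' Correlation between two breeding objectives
#'
#' @inheritParams objective_covariance
#' @return The correlation, in `[-1, 1]`.
#' @export
objective_correlation <- function(wi, wj, G) {
  vi <- objective_covariance(wi, wi, G)
  vj <- objective_covariance(wj, wj, G)
  if (vi <= 0 || vj <= 0)
    stop("zero-variance breeding objective: ",
         if (vi <= 0) wi$name else wj$name)
  r <- objective_covariance(wi, wj, G) / sqrt(vi * vj)
  max(-1, min(1, r))
}

#' Correlation table over a set of objectives
#'
#' @param objectives Named list of [breeding_objective()]s.
#' @param G Genetic covariance matrix.
#' @return Symmetric correlation matrix.
#' @export
objective_correlation_table <- function(objectives, G) {
  k <- length(objectives)
  M <- diag(k)
  nm <- vapply(objectives, `[[`, "", "name")
  dimnames(M) <- list(nm, nm)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j)
      M[i, j] <- M[j, i] <-
        objective_correlation(objectives[[i]], objectives[[j]], G)
  }
  M
}

#' Desired-gains search for objective weights
#'
#' Adjusts the weights of the targeted traits until the predicted
#' per-generation responses from [predict_response()] match the desired
#' gains, by damped Gauss-Newton iteration on the weight vector (a
#' trial-and-error automation of the desired-gains approach). Traits not in
#' `targets` keep the base weights.
#'
#' @param base A [breeding_objective()] providing starting weights.
#' @param targets Named numeric vector of desired per-generation responses
#'   (trait units) for a subset of traits.
#' @param scheme A [scheme_config()].
#' @param params A parameter set as from [default_scheme_params()].
#' @param tol Relative tolerance on each targeted response (default 2%).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @return A [breeding_objective()] with attributes `achieved` (responses),
#'   `converged` and `iterations`.
#' @export
desired_gains_search <- function(base, targets, scheme, params,
                                 tol = 0.02, max_iter = 40) {
  stopifnot(inherits(base, "cuni_objective"), length(targets) >= 1)
  tn <- names(targets)
  w <- base$weights
  if (!all(tn %in% names(w)))
    w[setdiff(tn, names(w))] <- 0
  resp_fun <- function(wv) {
    obj <- breeding_objective(base$name, wv)
    tryCatch(predict_response(scheme, params, obj)$response[tn],
             error = function(e) rep(NA_real_, length(tn)))
  }
  scale_t <- pmax(abs(targets), 1e-8)
  cur <- resp_fun(w)
  converged <- all(abs(cur - targets) / scale_t <= tol)
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    # numerical Jacobian of targeted responses wrt targeted weights
    J <- matrix(0, length(tn), length(tn), dimnames = list(tn, tn))
    for (k in tn) {
      h <- max(abs(w[k]) * 0.05, 0.5)
      wp <- w; wp[k] <- w[k] + h
      J[, k] <- (resp_fun(wp) - cur) / h
    }
    step <- tryCatch(solve(J, targets - cur), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)) || anyNA(J)) {
      warning("response insensitive to the targeted weights; ",
              "returning best effort")
      break
    }
    # damped update; a step is only taken if it improves the fit
    lam <- 1
    stalled <- FALSE
    repeat {
      w_new <- w
      w_new[tn] <- w[tn] + lam * step
      new <- resp_fun(w_new)
      if (!anyNA(new) &&
          sum(((new - targets) / scale_t)^2) <
          sum(((cur - targets) / scale_t)^2)) break
      lam <- lam / 2
      if (lam < 1 / 64) { stalled <- TRUE; break }
    }
    if (stalled) break
    # responses are invariant to rescaling the whole weight vector; keep the
    # iterate on a bounded scale
    s <- sqrt(sum(w_new^2) / max(sum(base$weights^2), 1e-12))
    if (s > 10) w_new <- w_new / s
    w <- w_new
    cur <- resp_fun(w)
    converged <- all(abs(cur - targets) / scale_t <= tol)
  }
  out <- breeding_objective(base$name, w)
  attr(out, "achieved") <- cur
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}
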