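#' Pedigree objects
#'
#' A `cuni_pedigree` is a validated, topologically sorted pedigree for a
#' two-environment breeding population. It is a data frame with one row per
#' animal and (at least) the columns `animal`, `sire`, `dam`, `sex`, `batch`,
#' `environment`, `biological_dam` and `rearing_dam`, plus integer index
#' columns (`sire_idx`, `dam_idx`, `rearing_dam_idx`) that map parents to row
#' positions (0 = unknown). Unknown parents are treated as unrelated founders
#' drawn from a single base population.
#'
#' @param x A data frame with columns `animal`, `sire`, `dam` and optionally
#'   `sex`, `batch`, `environment`, `rearing_dam`, `litter`, `rearing_litter`.
#'   Unknown parents are coded `0`, `NA` or `""`.
#' @return A `cuni_pedigree` object in topological order (parents before
#'   offspring).
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("animal", "sire", "dam")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("pedigree is missing required column(s): ", paste(miss, collapse = ", "))
  x$animal <- as.character(x$animal)
  x$sire <- .clean_parent(x$sire)
  x$dam <- .clean_parent(x$dam)
  if (anyNA(x$animal) || any(x$animal == ""))
    stop("missing animal id at line ", which(is.na(x$animal) | x$animal == "")[1])
  if (anyDuplicated(x$animal))
    stop("duplicated animal id: ", x$animal[duplicated(x$animal)][1])
  if (!"sex" %in% names(x)) x$sex <- rep(NA_character_, nrow(x))
  x$sex <- as.character(x$sex)
  for (cc in intersect(c("sex", "batch", "environment", "litter",
                         "rearing_litter"), names(x))) {
    x[[cc]] <- as.character(x[[cc]])
    x[[cc]][x[[cc]] %in% c("", "NA")] <- NA_character_
  }
  bad_sex <- !is.na(x$sex) & !x$sex %in% c("M", "F")
  if (any(bad_sex))
    stop("unknown sex code '", x$sex[bad_sex][1], "' at line ", which(bad_sex)[1])
  if (!"batch" %in% names(x)) x$batch <- rep(NA_character_, nrow(x))
  if (!"environment" %in% names(x)) x$environment <- rep(NA_character_, nrow(x))
  bad_env <- !is.na(x$environment) & !x$environment %in% c("S", "Ch")
  if (any(bad_env))
    stop("unknown environment code '", x$environment[bad_env][1],
         "' at line ", which(bad_env)[1])
  x$biological_dam <- x$dam
  if (!"rearing_dam" %in% names(x)) x$rearing_dam <- x$dam
  x$rearing_dam <- .clean_parent(x$rearing_dam)
  if (!"litter" %in% names(x)) {
    x$litter <- ifelse(is.na(x$dam), NA_character_, paste0("lit_", x$dam))
  }
  if (!"rearing_litter" %in% names(x)) x$rearing_litter <- x$litter

  # parents must exist as animals when not unknown
  for (col in c("sire", "dam", "rearing_dam")) {
    known <- !is.na(x[[col]])
    absent <- known & !(x[[col]] %in% x$animal)
    if (any(absent))
      stop(col, " '", x[[col]][absent][1], "' of animal '",
           x$animal[absent][1], "' is not in the pedigree")
  }

  ord <- .pedigree_toposort(x$animal, x$sire, x$dam)
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  x$sire_idx <- .parent_index(x$sire, x$animal)
  x$dam_idx <- .parent_index(x$dam, x$animal)
  x$rearing_dam_idx <- .parent_index(x$rearing_dam, x$animal)
  class(x) <- c("cuni_pedigree", "data.frame")
  x
}

.clean_parent <- function(p) {
  p <- as.character(p)
  p[is.na(p) | p %in% c("0", "", ".", "NA")] <- NA_character_
  p
}

.parent_index <- function(parent, ids) {
  i <- match(parent, ids)
  i[is.na(i)] <- 0L
  as.integer(i)
}

# Kahn topological sort; reports one animal on a cycle.
.pedigree_toposort <- function(animal, sire, dam) {
  n <- length(animal)
  id <- seq_len(n)
  si <- match(sire, animal)
  di <- match(dam, animal)
  # children adjacency
  indeg <- integer(n)
  edges_from <- c(si[!is.na(si)], di[!is.na(di)])
  edges_to <- c(id[!is.na(si)], id[!is.na(di)])
  for (k in seq_along(edges_to)) indeg[edges_to[k]] <- indeg[edges_to[k]] + 1L
  adj <- split(edges_to, edges_from)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    ch <- adj[[as.character(v)]]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) < n) {
    offender <- animal[setdiff(id, out)[1]]
    stop("pedigree contains a cycle involving animal '", offender, "'")
  }
  out
}

#' Read a pedigree from a delimited text file
#'
#' The file must have a header naming at least `animal`, `sire` and `dam`;
#' comma or tab separation is auto-detected. Unknown parents are coded by
#' `0` or an empty field.
#'
#' @param path Path to a delimited text file.
#' @param quiet Suppress the sire/dam/animal count message.
#' @return A [as_pedigree()] object.
#' @export
load_pedigree <- function(path, quiet = FALSE) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty pedigree file (no header): ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE)
  ped <- as_pedigree(df)
  if (!quiet)
    message(sprintf("pedigree: %d animals, %d sires, %d dams",
                    nrow(ped), length(unique(stats::na.omit(ped$sire))),
                    length(unique(stats::na.omit(ped$dam)))))
  ped
}

#' Inbreeding coefficients from a pedigree
#'
#' Exact pedigree inbreeding via a memoized additive-relationship recursion
#' (a(i,j) = 0.5 (a(i, s_j) + a(i, d_j)) for j younger than i, with
#' a(i,i) = 1 + F_i). Only the relationship entries actually required are
#' computed, so deep dense matrices are never formed.
#'
#' @param ped A `cuni_pedigree`.
#' @return Numeric vector of inbreeding coefficients F, in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "cuni_pedigree"))
  n <- nrow(ped)
  if (n == 0) return(numeric(0))
  s <- ped$sire_idx; d <- ped$dam_idx
  Fcoef <- rep(NA_real_, n)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  arel <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) 1 + 0.5 * arel(s[i], d[i])
         else 0.5 * (arel(i, s[j]) + arel(i, d[j]))
    memo[[key]] <- v
    v
  }
  for (i in seq_len(n)) {
    Fcoef[i] <- if (s[i] > 0L && d[i] > 0L) 0.5 * arel(s[i], d[i]) else 0
    memo[[paste0(i, ":", i)]] <- 1 + Fcoef[i]
  }
  Fcoef
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive (numerator) relationship matrix A by the
#' tabular method, including inbreeding. Founders (unknown parents) are
#' assumed unrelated and non-inbred.
#'
#' @param ped A `cuni_pedigree`.
#' @return A dense symmetric matrix with dimnames = animal ids; attribute
#'   `"F"` carries the inbreeding coefficients (diag(A) - 1).
#' @export
compute_A <- function(ped) {
  stopifnot(inherits(ped, "cuni_pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  s <- ped$sire_idx; d <- ped$dam_idx
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (si > 0) A[j, si] else 0) + (if (di > 0) A[j, di] else 0))
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + (if (si > 0 && di > 0) 0.5 * A[si, di] else 0)
  }
  attr(A, "F") <- diag(A) - 1
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for: the Mendelian sampling
#' variance of animal i is d_i = 0.5 - 0.25 (F_s + F_d) when both parents are
#' known, 0.75 - 0.25 F_p with one known parent, and 1 for founders.
#'
#' @param ped A `cuni_pedigree`.
#' @return A sparse symmetric `Matrix::dsCMatrix` A-inverse with dimnames =
#'   animal ids.
#' @export
compute_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "cuni_pedigree"))
  n <- nrow(ped)
  if (n == 0)
    return(methods::as(Matrix::Matrix(0, 0, 0, sparse = TRUE), "symmetricMatrix"))
  Fcoef <- inbreeding(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  Fs <- ifelse(s > 0, Fcoef[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0, Fcoef[pmax(d, 1L)], 0)
  dvec <- ifelse(s > 0 & d > 0, 0.5 - 0.25 * (Fs + Fd),
          ifelse(s > 0 | d > 0, 0.75 - 0.25 * ifelse(s > 0, Fs, Fd), 1))
  alpha <- 1 / dvec
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    a <- alpha[i]; si <- s[i]; di <- d[i]
    add(i, i, a)
    if (si > 0) { add(si, si, 0.25 * a); add(i, si, -0.5 * a); add(si, i, -0.5 * a) }
    if (di > 0) { add(di, di, 0.25 * a); add(i, di, -0.5 * a); add(di, i, -0.5 * a) }
    if (si > 0 && di > 0) { add(si, di, 0.25 * a); add(di, si, 0.25 * a) }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Reassign rearing effects for cross-fostered kits
#'
#' Maternal genetic, maternal environmental and common-litter effects of a
#' fostered kit are carried by the adoptive suckling mother and her litter;
#' the direct additive effect continues to follow the biological pedigree,
#' so relationships are unaffected.
#'
#' @param ped A `cuni_pedigree`.
#' @param fostering A data frame with columns `kit` and `adoptive_dam`
#'   (animal ids). An empty data frame leaves the pedigree unchanged.
#' @return The pedigree with updated `rearing_dam` / `rearing_litter`.
#' @export
assign_rearing_effects <- function(ped, fostering) {
  stopifnot(inherits(ped, "cuni_pedigree"))
  fostering <- as.data.frame(fostering)
  if (!nrow(fostering)) return(ped)
  stopifnot(all(c("kit", "adoptive_dam") %in% names(fostering)))
  kit_i <- match(as.character(fostering$kit), ped$animal)
  if (anyNA(kit_i))
    stop("fostered kit '", fostering$kit[is.na(kit_i)][1], "' is not in the pedigree")
  dam_i <- match(as.character(fostering$adoptive_dam), ped$animal)
  if (anyNA(dam_i))
    stop("adoptive dam '", fostering$adoptive_dam[is.na(dam_i)][1],
         "' is not in the pedigree")
  dam_sex <- ped$sex[dam_i]
  if (any(!is.na(dam_sex) & dam_sex != "F"))
    stop("adoptive dam '", ped$animal[dam_i][which(!is.na(dam_sex) & dam_sex != "F")[1]],
         "' is not female")
  ped$rearing_dam[kit_i] <- ped$animal[dam_i]
  ped$rearing_dam_idx[kit_i] <- dam_i
  # rearing litter follows the adoptive dam's litter of the same batch if one
  # exists; otherwise a litter keyed by the adoptive dam
  ped$rearing_litter[kit_i] <- paste0("lit_", ped$animal[dam_i])
  for (k in seq_along(kit_i)) {
    sibs <- which(ped$dam_idx == dam_i[k] & seq_len(nrow(ped)) != kit_i[k])
    if (length(sibs)) ped$rearing_litter[kit_i[k]] <- ped$rearing_litter[sibs[1]]
  }
  ped
}

#' @export
print.cuni_pedigree <- function(x, ...) {
  cat(sprintf("<cuni_pedigree> %d animals (%d sires, %d dams, %d founders)\n",
              nrow(x), length(unique(stats::na.omit(x$sire))),
              length(unique(stats::na.omit(x$dam))),
              sum(x$sire_idx == 0 & x$dam_idx == 0)))
  invisible(x)
}

#' Write a pedigree to a delimited text file
#' @param ped A `cuni_pedigree`.
#' @param path Output file path.
#' @export
write_pedigree <- function(ped, path) {
  cols <- c("animal", "sire", "dam", "sex", "batch", "environment",
            "biological_dam", "rearing_dam", "litter", "rearing_litter")
  out <- as.data.frame(ped)[, intersect(cols, names(ped)), drop = FALSE]
  parent_cols <- intersect(c("sire", "dam", "biological_dam", "rearing_dam"),
                           names(out))
  for (c in parent_cols) out[[c]][is.na(out[[c]])] <- "0"
  for (c in setdiff(names(out), parent_cols)) out[[c]][is.na(out[[c]])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
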