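#' @name ocsel
#' @title Optimal contribution selection
#'
#' @description
#' Classical optimal contribution selection: find nonnegative candidate
#' contributions summing to one that maximize group genetic merit
#' \eqn{c'\hat g} subject to a cap on the expected rate of inbreeding,
#' computed from the group coancestry \eqn{c'Gc/2} of the selected set.
#' When the cap cannot be met, the minimum-coancestry solution is returned
#' and merit is effectively not considered.
NULL

#' Parameters for optimal contribution selection
#'
#' @param deltaF_max maximum expected rate of inbreeding per generation
#'   (default 0.01, the 1\% cap recommended by the FAO).
#' @param current_mean_f mean inbreeding proxy of the current generation
#'   (genomic mean-coancestry baseline), in [0, 1).
#' @return a list of class \code{oc_params}.
#' @export
oc_params <- function(deltaF_max = 0.01, current_mean_f = 0) {
  if (deltaF_max <= 0 || deltaF_max >= 1)
    stop("oc_params: deltaF_max must be in (0, 1)", call. = FALSE)
  if (current_mean_f < 0 || current_mean_f >= 1)
    stop("oc_params: current_mean_f must be in [0, 1)", call. = FALSE)
  structure(list(deltaF_max = deltaF_max, current_mean_f = current_mean_f),
            class = "oc_params")
}

#' Expected rate of inbreeding of a contribution vector
#'
#' \deqn{\Delta F = \frac{c'Gc/2 - \bar f_t}{1 - \bar f_t}}
#' where \eqn{c'Gc/2} is the group coancestry of the selected set (the
#' expected inbreeding of its offspring) and \eqn{\bar f_t} the current mean
#' inbreeding proxy.  Negative values are floored at 0.
#'
#' @param contributions numeric vector of contributions (nonnegative,
#'   summing to 1), or an \code{oc_contrib} object.
#' @param G relationship \code{gmatrix} over the candidate set.
#' @param current_mean_f current mean inbreeding proxy, in [0, 1).
#' @return the expected rate of inbreeding (a number >= 0).
#' @export
expected_deltaF <- function(contributions, G, current_mean_f = 0) {
  if (inherits(contributions, "oc_contrib"))
    contributions <- contributions$contribution
  if (current_mean_f >= 1)
    stop("expected_deltaF: current_mean_f must be < 1", call. = FALSE)
  cc <- as.numeric(contributions)
  coan <- as.numeric(cc %*% unclass(G) %*% cc) / 2
  max(0, (coan - current_mean_f) / (1 - current_mean_f))
}

new_contrib <- function(ids, contribution, gebv, deltaF, feasible, method) {
  merit <- if (all(is.na(gebv))) NA_real_ else sum(contribution * gebv)
  structure(list(ids = ids, contribution = contribution, gebv = gebv,
                 merit = merit, deltaF = deltaF, feasible = feasible,
                 method = method),
            class = "oc_contrib")
}

#' @export
print.oc_contrib <- function(x, ...) {
  cat(sprintf("Contribution vector (%s): %d candidates, %d with c > 0\n",
              x$method, length(x$ids), sum(x$contribution > 1e-12)))
  cat(sprintf("  merit = %s, expected deltaF = %.6g, feasible = %s\n",
              if (is.na(x$merit)) "NA" else format(x$merit),
              x$deltaF, x$feasible))
  invisible(x)
}

# symmetric solve; falls back to a diagonal ridge when G is not PD
sym_solve <- function(A, B, ridge = 1e-2) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    diag(A) <- diag(A) + ridge
    ch <- chol(A)
  }
  backsolve(ch, forwardsolve(t(ch), B))
}

#' Minimum-coancestry contributions
#'
#' Minimizes the group coancestry \eqn{c'Gc} subject to \eqn{\sum c = 1},
#' \eqn{c \ge 0}: the unconstrained solution \eqn{G^{-1}1/(1'G^{-1}1)} with
#' iterative elimination of negative entries (plus a KKT reintroduction
#' check), ignoring genetic merit.
#'
#' @param G relationship \code{gmatrix} over the candidates.
#' @param gebv optional GEBVs, only carried through for reporting.
#' @param current_mean_f baseline mean inbreeding for the reported
#'   expected rate of inbreeding.
#' @return an \code{oc_contrib} object (feasibility flag \code{TRUE}; the
#'   flag refers to the merit-constrained problem and is set \code{FALSE}
#'   only when \code{\link{optimal_contributions}} falls back to this
#'   solution).
#' @export
min_coancestry <- function(G, gebv = NULL, current_mean_f = 0) {
  A <- unclass(G)
  n <- nrow(A)
  ids <- rownames(A) %||% as.character(seq_len(n))
  if (is.null(gebv)) gebv <- rep(NA_real_, n)
  act <- rep(TRUE, n)
  cvec <- numeric(n)
  for (it in seq_len(10L * n)) {
    x1 <- sym_solve(A[act, act, drop = FALSE], rep(1, sum(act)))
    ca <- as.numeric(x1) / sum(x1)
    if (any(ca < -1e-12)) {
      w <- which(act)
      act[w[ca < -1e-12]] <- FALSE
      if (sum(act) == 1) { cvec[] <- 0; cvec[act] <- 1; break }
      next
    }
    cvec[] <- 0
    cvec[act] <- pmax(ca, 0)
    # KKT: inactive candidates must not lower the objective if reintroduced
    gc_ <- as.numeric(A %*% cvec)
    muv <- sum(cvec * gc_)
    viol <- which(!act & gc_ < muv - 1e-10)
    if (length(viol) == 0) break
    act[viol[which.min(gc_[viol])]] <- TRUE
  }
  cvec <- cvec / sum(cvec)
  new_contrib(ids, cvec, gebv,
              expected_deltaF(cvec, G, current_mean_f),
              feasible = TRUE, method = "min_coancestry")
}

#' Optimal contributions under an inbreeding-rate cap
#'
#' Maximizes group merit \eqn{c'\hat g} subject to \eqn{\sum c = 1},
#' \eqn{c \ge 0} and \eqn{\Delta F(c) \le} \code{deltaF_max}, via the
#' Lagrangian closed form \eqn{c = G^{-1}(\hat g - \lambda_0 1)/\lambda}
#' on the active set, with \eqn{\lambda, \lambda_0} set by the two equality
#' constraints, iterative zeroing of negative contributions, and a KKT
#' reintroduction check.  If the cap is below the minimum achievable rate,
#' the minimum-coancestry solution is returned with the feasibility flag
#' set to \code{FALSE}.
#'
#' @param gebv numeric vector of candidate GEBVs.
#' @param G relationship \code{gmatrix} over the same candidates (the
#'   allele-sharing similarity matrix by default in the update pipeline).
#' @param params an \code{\link{oc_params}} object.
#' @return an \code{oc_contrib} object with achieved merit, achieved
#'   expected rate of inbreeding, and the feasibility flag.
#' @export
optimal_contributions <- function(gebv, G, params = oc_params()) {
  A <- unclass(G)
  n <- nrow(A)
  if (length(gebv) != n)
    stop("optimal_contributions: gebv/G dimension mismatch", call. = FALSE)
  ids <- rownames(A) %||% as.character(seq_len(n))
  f0 <- params$current_mean_f
  K <- f0 + params$deltaF_max * (1 - f0)  # max allowed group coancestry
  tol <- 1e-9

  cmin <- min_coancestry(G, gebv, f0)
  phimin <- as.numeric(cmin$contribution %*% A %*% cmin$contribution)
  if (phimin / 2 > K + tol) {
    cmin$feasible <- FALSE
    cmin$method <- "oc_fallback_min_coancestry"
    return(cmin)
  }
  if (abs(phimin / 2 - K) <= tol) {
    cmin$method <- "oc_boundary"
    return(cmin)
  }
  # unconstrained merit maximum: the top-GEBV vertex (ties: first id)
  top <- order(-gebv, seq_len(n))[1]
  if (A[top, top] / 2 <= K + tol) {
    cvec <- numeric(n); cvec[top] <- 1
    return(new_contrib(ids, cvec, gebv, expected_deltaF(cvec, G, f0),
                       feasible = TRUE, method = "oc_vertex"))
  }
  # cap binding: equality-constrained Lagrangian on the active set
  act <- rep(TRUE, n)
  cvec <- numeric(n)
  for (it in seq_len(10L * n)) {
    w <- which(act)
    GA <- A[w, w, drop = FALSE]
    sol <- sym_solve(GA, cbind(1, gebv[w]))
    x1 <- sol[, 1]; xg <- sol[, 2]
    a <- sum(x1); b <- sum(xg); d <- sum(gebv[w] * xg)
    u <- 1 - 2 * K * a
    lam <- NA_real_; lam0 <- NA_real_
    if (u >= -1e-14) {
      ca <- x1 / a                       # active set too tight: coancestry min
    } else {
      disc <- max(0, u * (b^2 - a * d))
      lam0 <- b / a + sqrt(disc) / (a * u)
      lam <- b - lam0 * a
      ca <- if (lam <= 1e-14) x1 / a else (xg - lam0 * x1) / lam
    }
    if (any(ca < -1e-12)) {
      act[w[ca < -1e-12]] <- FALSE
      if (sum(act) == 1) {
        k <- which(act)
        cvec[] <- 0; cvec[k] <- 1
        break
      }
      next
    }
    cvec[] <- 0
    cvec[w] <- pmax(ca, 0)
    # KKT for inactive candidates: g_j - lam*(Gc)_j - lam0 <= 0
    if (is.finite(lam) && lam > 1e-14) {
      gc_ <- as.numeric(A %*% cvec)
      s <- gebv - lam * gc_ - lam0
      viol <- which(!act & s > 1e-8 * max(1, abs(lam0)))
      if (length(viol) > 0) {
        act[viol[which.max(s[viol])]] <- TRUE
        next
      }
    }
    break
  }
  if (sum(cvec) <= 0) {              # iteration cap hit mid-elimination
    w <- which(act)
    cvec[w] <- pmax(sym_solve(A[w, w, drop = FALSE], rep(1, length(w))), 0)
  }
  cvec <- pmax(cvec, 0)
  cvec <- cvec / sum(cvec)
  new_contrib(ids, cvec, gebv, expected_deltaF(cvec, G, f0),
              feasible = TRUE, method = "oc")
}

#' Pick a fixed-size update group from a contribution vector
#'
#' Returns the \code{n} candidates with the largest contributions; ties are
#' broken by higher GEBV, then by id.  Zero-contribution candidates are
#' admitted only when fewer than \code{n} contributions are positive (a
#' message is emitted).
#'
#' @param contrib an \code{oc_contrib} object.
#' @param n group size.
#' @return character vector of selected ids.
#' @export
select_update_group <- function(contrib, n) {
  if (n <= 0) stop("select_update_group: n must be positive", call. = FALSE)
  if (n > length(contrib$ids))
    stop("select_update_group: n exceeds candidate count", call. = FALSE)
  gebv <- contrib$gebv
  if (all(is.na(gebv))) gebv <- rep(0, length(contrib$ids))
  o <- order(-contrib$contribution, -gebv, seq_along(contrib$ids))
  n_pos <- sum(contrib$contribution > 1e-12)
  if (n_pos < n)
    message("select_update_group: only ", n_pos,
            " positive contributions; admitting zero-contribution candidates")
  contrib$ids[o[seq_len(n)]]
}
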