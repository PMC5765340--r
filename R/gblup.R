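#' Fit a weighted GBLUP model with fixed variance components
#'
#' Solves the single-trait mixed-model equations
#' \deqn{(W/\sigma^2_e + G^{-1}/\sigma^2_g)\,\hat g = W (y - \mu 1)/\sigma^2_e}
#' with \eqn{W = diag(w)} and \eqn{\mu} the generalized-least-squares mean,
#' using the algebraically identical variance form
#' \eqn{\hat g = \sigma^2_g G V^{-1} (y - \mu 1)},
#' \eqn{V = \sigma^2_g G + \sigma^2_e W^{-1}} (one Cholesky factorization).
#' Variance components are fixed, not estimated; only the mean and the
#' random genetic effects are fitted, matching evaluation on phenotypes
#' already corrected for fixed effects.  Record weights scale the residual
#' variance per record (progeny-based records carry weights > 1).
#'
#' @param G_ref \code{gmatrix} over the phenotyped reference individuals.
#' @param phenotypes numeric vector \code{y}, one record per reference
#'   individual (same order as \code{G_ref}).
#' @param weights positive record weights, recycled (default 1).
#' @param sigma2_g,sigma2_e fixed genetic and residual variances.
#' @param ridge diagonal stabilizer added to \code{G_ref} before solving
#'   (default 1e-2; set 0 for an exactly positive-definite G).
#' @return an object of class \code{gblup} with components \code{mu} (GLS
#'   mean), \code{gebv} (named GEBV vector over reference ids), \code{alpha}
#'   (the projection vector \eqn{G_{ref}^{-1}\hat g}, used for candidate
#'   prediction), the inputs, and \code{lambda} = sigma2_e/sigma2_g.
#' @seealso \code{\link{predict_candidates}}
#' @export
fit_gblup <- function(G_ref, phenotypes, weights = 1,
                      sigma2_g = 423390, sigma2_e = 987910, ridge = 1e-2) {
  n <- length(phenotypes)
  if (nrow(G_ref) != n || ncol(G_ref) != n)
    stop("fit_gblup: G_ref must be square over the phenotyped set",
         call. = FALSE)
  w <- rep_len(weights, n)
  if (any(w <= 0)) stop("fit_gblup: weights must be positive", call. = FALSE)
  if (sigma2_g <= 0 || sigma2_e <= 0)
    stop("fit_gblup: variance components must be positive", call. = FALSE)
  Gw <- unclass(G_ref)
  if (ridge > 0) diag(Gw) <- diag(Gw) + ridge
  V <- sigma2_g * Gw + diag(sigma2_e / w, n)
  ch <- tryCatch(chol(V), error = function(e)
    stop("fit_gblup: singular system after ridge (rcond = ",
         format(rcond(V)), ")", call. = FALSE))
  Vinv_solve <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  one <- rep(1, n)
  Vi1 <- Vinv_solve(one)
  mu <- sum(Vi1 * phenotypes) / sum(Vi1)
  alpha <- sigma2_g * Vinv_solve(phenotypes - mu)
  gebv <- as.numeric(Gw %*% alpha)
  ids <- rownames(G_ref) %||% as.character(seq_len(n))
  names(gebv) <- ids
  names(alpha) <- ids
  structure(list(mu = mu, gebv = gebv, alpha = alpha,
                 ids = ids, y = phenotypes, w = w,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 lambda = sigma2_e / sigma2_g, ridge = ridge,
                 gmethod = attr(G_ref, "method")),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("GBLUP fit: %d reference records (%s G, ridge %g)\n",
              length(x$y), x$gmethod %||% "unknown", x$ridge))
  cat(sprintf("  fixed variances: sigma2_g = %.6g, sigma2_e = %.6g (lambda = %.4g)\n",
              x$sigma2_g, x$sigma2_e, x$lambda))
  cat(sprintf("  GLS mean mu = %.6g; GEBV range [%.6g, %.6g]\n",
              x$mu, min(x$gebv), max(x$gebv)))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(n = length(object$y), mu = object$mu,
              lambda = object$lambda, ridge = object$ridge,
              gebv_sd = stats::sd(object$gebv),
              resid_sd = stats::sd(res),
              gmethod = object$gmethod)
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat(sprintf("GBLUP summary: n = %d, mu = %.6g, lambda = %.4g, ridge = %g\n",
              x$n, x$mu, x$lambda, x$ridge))
  cat(sprintf("  GEBV sd = %.6g, residual sd = %.6g (%s G)\n",
              x$gebv_sd, x$resid_sd, x$gmethod %||% "unknown"))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$gebv

#' @export
fitted.gblup <- function(object, ...) object$mu + object$gebv

#' @export
residuals.gblup <- function(object, ...) object$y - object$mu - object$gebv

#' Predict GEBVs of unphenotyped candidates
#'
#' Projection prediction \eqn{\hat g_c = G_{cross} G_{ref}^{-1} \hat g_{ref}},
#' computed through the stored vector \eqn{\alpha = G_{ref}^{-1}\hat g_{ref}}
#' so no extra inversion is needed.  This equals including the candidates as
#' zero-weight records in a joint mixed-model solve.
#'
#' @param model a fitted \code{\link{fit_gblup}} object.
#' @param G_cross candidate-by-reference relationship block (columns in the
#'   reference order used at fit time; column names checked when present).
#' @return numeric vector of candidate GEBVs (named by \code{G_cross} row
#'   names when present).
#' @export
predict_candidates <- function(model, G_cross) {
  G_cross <- as.matrix(G_cross)
  if (ncol(G_cross) != length(model$alpha))
    stop("predict_candidates: cross block not conformable with the reference",
         call. = FALSE)
  cn <- colnames(G_cross)
  if (!is.null(cn) && !identical(cn, model$ids))
    stop("predict_candidates: reference id mismatch between blocks",
         call. = FALSE)
  out <- as.numeric(G_cross %*% model$alpha)
  names(out) <- rownames(G_cross)
  out
}

#' @rdname predict_candidates
#' @param object a \code{gblup} model.
#' @param ... unused.
#' @export
predict.gblup <- function(object, G_cross, ...) {
  if (missing(G_cross)) return(object$gebv)
  predict_candidates(object, G_cross)
}
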