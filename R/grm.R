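#' Marker quality control
#'
#' Filters markers of a dosage matrix by (i) call rate, (ii) departure from
#' Hardy-Weinberg equilibrium, and (iii) minor allele frequency.  Defaults
#' reproduce a standard chip QC: call rate > 90\%, HWE chi-square p-value
#' >= 1e-4 (markers departing with p < 1e-4 are removed), MAF > 1\%.
#' The HWE test is a 1-df chi-square on the three genotype class counts
#' against Hardy-Weinberg expectations, without continuity correction.
#'
#' @param genotypes numeric matrix of dosages in \{0,1,2\} with optional
#'   \code{NA}s; rows = individuals, columns = markers.
#' @param call_rate_min minimum fraction of non-missing calls (exclusive).
#' @param hwe_p_min markers with HWE p-value strictly below this are removed.
#' @param maf_min minimum minor allele frequency (exclusive).
#' @return the filtered matrix (individuals unchanged).  The per-marker
#'   removal log is attached as attribute \code{"qc_log"} (data.frame:
#'   marker, call_rate, maf, hwe_p, removed, reason).
#' @export
qc_filter <- function(genotypes, call_rate_min = 0.9, hwe_p_min = 1e-4,
                      maf_min = 0.01) {
  if (is.null(dim(genotypes)) || ncol(genotypes) == 0 ||
      nrow(genotypes) == 0)
    stop("qc_filter: empty genotype matrix", call. = FALSE)
  for (thr in c(call_rate_min, hwe_p_min, maf_min))
    if (thr < 0 || thr > 1)
      stop("qc_filter: thresholds must be in [0, 1]", call. = FALSE)
  n <- nrow(genotypes)
  call_rate <- colMeans(!is.na(genotypes))
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(genotypes)), function(j) {
    x <- genotypes[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    pj <- mean(x) / 2
    exp <- length(x) * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    if (any(exp == 0)) return(1)     # monomorphic: no departure testable
    stat <- sum((obs - exp)^2 / exp)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  reason <- character(ncol(genotypes))
  reason[!is.na(hwe_p) & hwe_p < hwe_p_min] <- "hwe"
  reason[maf <= maf_min] <- "maf"
  reason[call_rate <= call_rate_min] <- "call_rate"
  keep <- reason == ""
  if (!any(keep))
    stop("qc_filter: all markers removed by QC", call. = FALSE)
  log <- data.frame(
    marker = colnames(genotypes) %||% as.character(seq_len(ncol(genotypes))),
    call_rate = call_rate, maf = maf, hwe_p = hwe_p,
    removed = !keep, reason = ifelse(keep, "", reason),
    row.names = NULL)
  out <- genotypes[, keep, drop = FALSE]
  attr(out, "qc_log") <- log
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_gmatrix <- function(G, method, ids = NULL) {
  if (!is.null(ids)) dimnames(G) <- list(ids, ids)
  G <- (G + t(G)) / 2            # enforce exact symmetry
  structure(G, class = c("gmatrix", class(G)), method = method)
}

#' @export
print.gmatrix <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix (%s), %d x %d\n",
              attr(x, "method"), nrow(x), ncol(x)))
  cat(sprintf("  diagonal: mean %.4f, range [%.4f, %.4f]\n",
              mean(diag(x)), min(diag(x)), max(diag(x))))
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' G = ZZ' / (2 * sum_i p_i (1 - p_i)) with Z the column-centred genotype
#' matrix (dosage minus twice the allele frequency).  Missing dosages are
#' mean-imputed to 2 p_i before centring.
#'
#' @param genotypes dosage matrix (rows = individuals, columns = markers).
#' @param freqs optional per-marker allele frequencies; observed frequencies
#'   are used when omitted.
#' @return a \code{gmatrix} with method \code{"vanraden"}.
#' @export
vanraden_grm <- function(genotypes, freqs = NULL) {
  X <- as.matrix(genotypes)
  p <- if (is.null(freqs)) colMeans(X, na.rm = TRUE) / 2 else as.numeric(freqs)
  if (length(p) != ncol(X))
    stop("vanraden_grm: frequency vector length mismatch", call. = FALSE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * p[j]
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("vanraden_grm: all markers monomorphic (zero denominator)",
         call. = FALSE)
  Z <- sweep(X, 2, 2 * p)
  new_gmatrix(tcrossprod(Z) / denom, "vanraden", rownames(X))
}

#' Allele-sharing similarity relationship matrix
#'
#' G_jk = (2/N) * sum_i (x_ij - 1)(x_ik - 1) over the N markers, counting
#' shared alleles between individuals j and k.  Self-relationships lie in
#' [0, 2] and pairwise values in [-2, 2].  With allele frequencies fixed at
#' 0.5 for all loci the VanRaden construction yields exactly this matrix.
#'
#' @param genotypes dosage matrix with no missing entries
#'   (rows = individuals, columns = markers).
#' @return a \code{gmatrix} with method \code{"similarity"}.
#' @export
similarity_grm <- function(genotypes) {
  X <- as.matrix(genotypes)
  if (ncol(X) < 1) stop("similarity_grm: empty marker set", call. = FALSE)
  if (anyNA(X)) stop("similarity_grm: missing dosages not allowed",
                     call. = FALSE)
  M <- X - 1
  new_gmatrix(tcrossprod(M) * (2 / ncol(X)), "similarity", rownames(X))
}

# symmetric solve against B with a diagonal ridge (relationship matrices
# built from finite marker sets can be singular)
ridge_solve <- function(G, B, ridge = 1e-2) {
  A <- unclass(G)
  if (ridge > 0) diag(A) <- diag(A) + ridge
  ch <- tryCatch(chol(A), error = function(e)
    stop("ridge_solve: matrix not positive definite after ridge ",
         format(ridge), " (rcond = ", format(rcond(A)), ")", call. = FALSE))
  backsolve(ch, forwardsolve(t(ch), B))
}
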