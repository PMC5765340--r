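#' Observed heterozygosity
#'
#' Per individual, the fraction of marker loci at which the two alleles
#' differ (dosage 1), plus the group mean.
#'
#' @param genotypes dosage matrix in \{0,1,2\} (rows = individuals).
#' @return list with \code{per_individual} (named numeric vector) and
#'   \code{mean}.
#' @export
observed_heterozygosity <- function(genotypes) {
  X <- as.matrix(genotypes)
  if (ncol(X) == 0)
    stop("observed_heterozygosity: zero markers", call. = FALSE)
  h <- rowMeans(X == 1)
  list(per_individual = h, mean = mean(h))
}

#' Pedigree inbreeding coefficients
#'
#' Wright's F for every individual, by either the recursive tabular
#' relationship-matrix method (\code{method = "tabular"}) or the
#' Meuwissen-Luo style algorithm (\code{method = "meuwissen"}, the default,
#' linear memory).  The two agree to numerical precision and the tabular
#' route serves as the small-pedigree cross-check.
#'
#' @param ped data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (integer ids, 0 = unknown), parents listed before offspring.
#' @param method "meuwissen" or "tabular".
#' @return numeric vector of inbreeding coefficients, named by id.
#' @export
pedigree_inbreeding <- function(ped, method = c("meuwissen", "tabular")) {
  method <- match.arg(method)
  n <- nrow(ped)
  id <- ped$id
  pos <- match(ped$sire, id)   # NA or 0-parent -> founder side
  pos[is.na(pos) | ped$sire == 0] <- 0L
  pos2 <- match(ped$dam, id)
  pos2[is.na(pos2) | ped$dam == 0] <- 0L
  s <- as.integer(pos); d <- as.integer(pos2)
  if (any(s >= seq_len(n) & s > 0) || any(d >= seq_len(n) & d > 0))
    stop("pedigree_inbreeding: parents must be listed before offspring",
         call. = FALSE)
  f <- if (method == "tabular") inb_tabular(s, d, n) else inb_meuwissen(s, d, n)
  names(f) <- as.character(id)
  f
}

# tabular method: build the additive relationship matrix row by row
inb_tabular <- function(s, d, n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      prev <- seq_len(i - 1)
      ai <- numeric(i - 1)
      if (si > 0) ai <- ai + 0.5 * A[si, prev]
      if (di > 0) ai <- ai + 0.5 * A[di, prev]
      A[i, prev] <- ai
      A[prev, i] <- ai
    }
    A[i, i] <- 1 + if (si > 0 && di > 0) 0.5 * A[si, di] else 0
  }
  diag(A) - 1
}

# Meuwissen-Luo style: per animal, trace the ancestor path coefficients L
# over the actual ancestor set only (youngest first) and accumulate L^2 * D,
# where D is the within-family segregation variance
inb_meuwissen <- function(s, d, n) {
  f <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0) f[s[i]] else -1    # unknown parent: F = -1
    fd <- if (d[i] > 0) f[d[i]] else -1
    D[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0 || d[i] == 0) { f[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    acc <- 0
    for (j in i:1) {                       # youngest first; parents < child
      Lj <- L[j]
      if (Lj == 0) next
      acc <- acc + Lj * Lj * D[j]
      if (s[j] > 0) L[s[j]] <- L[s[j]] + 0.5 * Lj
      if (d[j] > 0) L[d[j]] <- L[d[j]] + 0.5 * Lj
    }
    f[i] <- acc - 1
  }
  f
}

#' Standardized prediction bias
#'
#' Per individual, \eqn{|GEBV_k - BV_k| / \sigma_G}, the absolute prediction
#' error standardized by the true breeding-value standard deviation of the
#' population under scrutiny; plus the group mean.
#'
#' @param gebv predicted breeding values.
#' @param bv true (or multi-record) breeding values.
#' @param sigma_G true-BV standard deviation of the evaluated group; when
#'   omitted, computed as \code{sd(bv)}.
#' @return list with \code{per_individual} and \code{mean}.
#' @export
prediction_bias <- function(gebv, bv, sigma_G = stats::sd(bv)) {
  if (!is.finite(sigma_G) || sigma_G <= 0)
    stop("prediction_bias: sigma_G must be positive", call. = FALSE)
  b <- abs(gebv - bv) / sigma_G
  list(per_individual = b, mean = mean(b))
}

#' Effective population size from mean inbreeding
#'
#' \eqn{N_e = 1/(2 f_t)} with \eqn{f_t} the mean inbreeding coefficient of
#' the population in generation t (the printed classical form, using the
#' inbreeding level).  At \eqn{f_t = 0} the quantity is undefined (infinite)
#' and \code{NA} is returned with a warning rather than a number.
#'
#' @param mean_f mean inbreeding coefficient in [0, 1).
#' @return effective size, or \code{NA} when \code{mean_f} is 0.
#' @export
effective_size <- function(mean_f) {
  if (mean_f < 0 || mean_f >= 1)
    stop("effective_size: mean_f must be in [0, 1)", call. = FALSE)
  if (mean_f == 0) {
    warning("effective_size: undefined (infinite) at mean_f = 0",
            call. = FALSE)
    return(NA_real_)
  }
  1 / (2 * mean_f)
}

#' Generation equivalents (pedigree completeness)
#'
#' Sum over ancestor generations g of the proportion of known ancestors at
#' depth g: \eqn{\sum_g n_{known}(g) / 2^g}.
#'
#' @param ped pedigree data.frame (id, sire, dam; 0 = unknown).
#' @param id the individual to evaluate.
#' @return the generation-equivalents statistic.
#' @export
generation_equivalents <- function(ped, id) {
  if (!id %in% ped$id)
    stop("generation_equivalents: unknown id ", id, call. = FALSE)
  idx <- function(i) match(i, ped$id)
  ge <- function(i, depth) {
    if (depth > 64) return(0)
    k <- idx(i)
    out <- 0
    for (p in c(ped$sire[k], ped$dam[k])) {
      if (!is.na(p) && p != 0 && !is.na(idx(p)))
        out <- out + 1 / 2 + ge(p, depth + 1) / 2
    }
    out
  }
  ge(id, 1)
}

#' Per-strategy generation trends
#'
#' For each strategy and metric, estimates the per-generation trend as the
#' mean of per-replicate ordinary least-squares slopes of the
#' per-generation group means, with the standard error across replicates and
#' a normal-approximation 95\% confidence interval.  Optionally applies the
#' arcsine-square-root transform to proportion-scale metrics
#' (heterozygosity, inbreeding) before fitting, and adjusts for the Ne/N
#' covariate within each replicate regression.
#'
#' @param metrics a metrics data.frame with columns \code{replicate},
#'   \code{generation}, \code{strategy} and the metric columns.
#' @param metric_cols which metric columns to fit (default the four
#'   evaluation variables).
#' @param arcsine apply asin(sqrt(x)) to \code{mean_het} and \code{mean_f}.
#' @param adjust_ne_over_n include Ne/N as a covariate in each replicate
#'   regression (requires an \code{ne_over_n} column).
#' @return data.frame (strategy, metric, slope, se, ci_low, ci_high,
#'   n_replicates).
#' @export
estimate_trends <- function(metrics,
                            metric_cols = c("mean_bv", "mean_bias",
                                            "mean_f", "mean_het"),
                            arcsine = FALSE, adjust_ne_over_n = FALSE) {
  if (length(unique(metrics$generation)) < 2)
    stop("estimate_trends: need at least 2 generations", call. = FALSE)
  rows <- list()
  for (strat in unique(metrics$strategy)) {
    ms <- metrics[metrics$strategy == strat, , drop = FALSE]
    reps <- unique(ms$replicate)
    if (length(reps) < 2)
      stop("estimate_trends: need at least 2 replicates per strategy",
           call. = FALSE)
    for (mc in metric_cols) {
      slopes <- vapply(reps, function(r) {
        mr <- ms[ms$replicate == r, , drop = FALSE]
        y <- mr[[mc]]
        if (arcsine && mc %in% c("mean_het", "mean_f")) y <- asin(sqrt(y))
        if (adjust_ne_over_n && "ne_over_n" %in% names(mr) &&
            sum(is.finite(mr$ne_over_n)) >= 3) {
          ok <- is.finite(y) & is.finite(mr$ne_over_n)
          fit <- stats::lm(y[ok] ~ mr$generation[ok] + mr$ne_over_n[ok])
          unname(stats::coef(fit)[2])
        } else {
          ok <- is.finite(y)
          fit <- stats::lm(y[ok] ~ mr$generation[ok])
          unname(stats::coef(fit)[2])
        }
      }, numeric(1))
      est <- mean(slopes)
      se <- stats::sd(slopes) / sqrt(length(slopes))
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strat, metric = mc, slope = est, se = se,
        ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
        n_replicates = length(slopes))
    }
  }
  do.call(rbind, rows)
}
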