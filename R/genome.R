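#' Genome specification
#'
#' Describes the simulated diploid genome: chromosome number and genetic
#' length, marker and QTL map positions, and the range from which founder
#' allele frequencies are drawn.  Marker loci carry no effect and are the
#' only loci used for relationship matrices and heterozygosity; QTL loci
#' carry the additive trait effects.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length genetic length of each chromosome in centimorgans.
#' @param n_markers_per_chr number of evenly spaced marker loci per chromosome.
#' @param n_qtl_per_chr number of QTL per chromosome, interleaved between
#'   markers so that marker and QTL positions are disjoint.
#' @param founder_allele_freq_range length-2 numeric in (0, 1): founder allele
#'   frequencies are drawn uniformly from this interval.
#'
#' @return An object of class \code{genome_spec}: a list with elements
#'   \code{n_chromosomes}, \code{chromosome_length}, \code{marker_positions}
#'   and \code{qtl_positions} (lists of per-chromosome position vectors, cM),
#'   \code{founder_allele_freq_range}, and precomputed locus bookkeeping
#'   (\code{loci}: data.frame with chromosome, position, type).
#' @export
genome_spec <- function(n_chromosomes = 10,
                        chromosome_length = 100,
                        n_markers_per_chr = 200,
                        n_qtl_per_chr = 20,
                        founder_allele_freq_range = c(0.05, 0.95)) {
  if (n_chromosomes < 1 || n_markers_per_chr < 1 || n_qtl_per_chr < 0)
    stop("genome_spec: counts must be positive", call. = FALSE)
  fr <- founder_allele_freq_range
  if (length(fr) != 2 || any(!is.finite(fr)) || fr[1] > fr[2] ||
      fr[1] <= 0 || fr[2] >= 1)
    stop("genome_spec: founder_allele_freq_range must lie within (0, 1)",
         call. = FALSE)
  # markers evenly spaced; QTL at midpoints of a thinned subset of intervals,
  # guaranteeing disjoint, strictly increasing positions
  marker_positions <- vector("list", n_chromosomes)
  qtl_positions <- vector("list", n_chromosomes)
  mpos <- seq(0, chromosome_length,
              length.out = n_markers_per_chr + 2)[2:(n_markers_per_chr + 1)]
  if (n_qtl_per_chr > 0) {
    idx <- round(seq(1, n_markers_per_chr - 1, length.out = n_qtl_per_chr))
    qpos <- (mpos[idx] + mpos[idx + 1]) / 2
  } else qpos <- numeric(0)
  for (chr in seq_len(n_chromosomes)) {
    marker_positions[[chr]] <- mpos
    qtl_positions[[chr]] <- qpos
  }
  loci <- do.call(rbind, lapply(seq_len(n_chromosomes), function(chr) {
    pos <- c(marker_positions[[chr]], qtl_positions[[chr]])
    type <- rep(c("marker", "qtl"),
                c(length(marker_positions[[chr]]),
                  length(qtl_positions[[chr]])))
    o <- order(pos)
    data.frame(chr = chr, pos = pos[o], type = type[o],
               stringsAsFactors = FALSE)
  }))
  if (any(unlist(lapply(split(loci$pos, loci$chr), function(p)
    any(diff(p) <= 0)))))
    stop("genome_spec: positions must be strictly increasing", call. = FALSE)
  loci$name <- ifelse(loci$type == "marker",
                      paste0("M", cumsum(loci$type == "marker")),
                      paste0("Q", cumsum(loci$type == "qtl")))
  structure(list(
    n_chromosomes = n_chromosomes,
    chromosome_length = chromosome_length,
    marker_positions = marker_positions,
    qtl_positions = qtl_positions,
    founder_allele_freq_range = fr,
    loci = loci,
    n_loci = nrow(loci),
    marker_idx = which(loci$type == "marker"),
    qtl_idx = which(loci$type == "qtl")
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome specification\n")
  cat(sprintf("  %d chromosomes x %.0f cM\n",
              x$n_chromosomes, x$chromosome_length))
  cat(sprintf("  %d markers, %d QTL\n",
              length(x$marker_idx), length(x$qtl_idx)))
  cat(sprintf("  founder allele frequencies ~ U(%.2f, %.2f)\n",
              x$founder_allele_freq_range[1], x$founder_allele_freq_range[2]))
  invisible(x)
}

#' Additive trait model
#'
#' Holds the QTL allele-substitution effects and the fixed variance
#' components of the quantitative trait.  The defaults reproduce a milk-yield
#' style trait: heritability 0.3 with genetic variance 423,390 kg^2 and
#' residual variance 987,910 kg^2.
#'
#' @param qtl_effects numeric vector of additive effects, one per QTL locus.
#' @param sigma2_g additive genetic variance (trait units squared).
#' @param sigma2_e residual variance (trait units squared).
#' @param offset constant subtracted from genotypic values so that breeding
#'   values are expressed as deviations from a base population mean
#'   (set by \code{\link{assign_trait}}; default 0).
#'
#' @return An object of class \code{trait_model} with fields
#'   \code{qtl_effects}, \code{sigma2_g}, \code{sigma2_e}, \code{offset} and
#'   the derived heritability \code{h2}.
#' @export
trait_model <- function(qtl_effects, sigma2_g = 423390, sigma2_e = 987910,
                        offset = 0) {
  if (sigma2_g <= 0 || sigma2_e < 0)
    stop("trait_model: variances must be positive", call. = FALSE)
  h2 <- sigma2_g / (sigma2_g + sigma2_e)
  structure(list(qtl_effects = as.numeric(qtl_effects),
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e, h2 = h2,
                 offset = offset),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Additive trait model\n")
  cat(sprintf("  %d QTL effects, sigma2_g = %.6g, sigma2_e = %.6g, h2 = %.3f\n",
              length(x$qtl_effects), x$sigma2_g, x$sigma2_e, x$h2))
  invisible(x)
}

# deterministic child seed derivation: keeps every derived seed a valid
# 32-bit R integer, so one root seed yields reproducible per-stage streams
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(h)
}
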