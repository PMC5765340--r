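#' @name synthpop
#' @title Forward-in-time population simulator
#'
#' @description
#' The simulator keeps a whole population in one object: two haplotype
#' matrices (rows = individuals, columns = loci in map order, alleles coded
#' 0/1), plus pedigree links, sex, birth generation, true breeding value,
#' phenotype and record weight.  Gametes are dropped through meiosis under
#' the Haldane model (no interference): crossover counts per chromosome are
#' Poisson with mean equal to the map length in Morgans and crossover
#' positions are uniform.
NULL

new_population <- function(hap1, hap2, sire, dam, sex, generation, genome,
                           tbv = NULL, phenotype = NULL, weight = NULL) {
  n <- nrow(hap1)
  structure(list(
    id = seq_len(n),
    sire = as.integer(sire), dam = as.integer(dam),
    sex = sex, generation = as.integer(generation),
    hap1 = hap1, hap2 = hap2,
    tbv = if (is.null(tbv)) rep(NA_real_, n) else tbv,
    phenotype = if (is.null(phenotype)) rep(NA_real_, n) else phenotype,
    weight = if (is.null(weight)) rep(1, n) else weight,
    genome = genome
  ), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population: %d individuals (%d male, %d female), generations %d-%d\n",
              length(x$id), sum(x$sex == "M"), sum(x$sex == "F"),
              min(x$generation), max(x$generation)))
  cat(sprintf("  %d loci (%d markers, %d QTL); %d phenotyped\n",
              x$genome$n_loci, length(x$genome$marker_idx),
              length(x$genome$qtl_idx), sum(!is.na(x$phenotype))))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a \code{population}.
#' @return integer count.
#' @export
pop_size <- function(pop) length(pop$id)

#' Marker dosage matrix of a set of individuals
#'
#' @param pop a \code{population}.
#' @param ids individual ids (default all).
#' @return integer matrix of genotype dosages in \{0,1,2\} over marker loci
#'   only (QTL are excluded, mirroring chip-based evaluation), with ids as
#'   row names and marker names as column names.
#' @export
marker_dosages <- function(pop, ids = pop$id) {
  m <- pop$genome$marker_idx
  x <- pop$hap1[ids, m, drop = FALSE] + pop$hap2[ids, m, drop = FALSE]
  dimnames(x) <- list(as.character(ids), pop$genome$loci$name[m])
  x
}

#' Extract one individual
#' @param pop a \code{population}.
#' @param id individual id.
#' @return list with fields id, sire, dam, sex, generation, hap1, hap2, tbv,
#'   phenotype, weight.
#' @export
get_individual <- function(pop, id) {
  if (!id %in% pop$id) stop("unknown individual id: ", id, call. = FALSE)
  list(id = id, sire = pop$sire[id], dam = pop$dam[id], sex = pop$sex[id],
       generation = pop$generation[id],
       hap1 = pop$hap1[id, ], hap2 = pop$hap2[id, ],
       tbv = pop$tbv[id], phenotype = pop$phenotype[id],
       weight = pop$weight[id])
}

#' Pedigree of a population
#' @param pop a \code{population}.
#' @return data.frame (id, sire, dam, generation), 0 = unknown parent.
#' @export
pedigree <- function(pop) {
  data.frame(id = pop$id, sire = pop$sire, dam = pop$dam,
             generation = pop$generation)
}

# per-chromosome recombination fractions between adjacent loci (Haldane):
# r = (1 - exp(-2d)) / 2 for map distance d in Morgans.  Under the Poisson
# crossover process the allele-inheritance pattern along a chromosome is a
# two-state Markov chain with exactly these switch probabilities, which is
# what the bulk gamete dropper uses.
chrom_blocks <- function(genome) {
  lapply(split(seq_len(genome$n_loci), genome$loci$chr), function(cols) {
    pos <- genome$loci$pos[cols]
    list(cols = cols, r = (1 - exp(-2 * diff(pos) / 100)) / 2)
  })
}

# draw one gamete per entry of `parents` (row indices into hap1/hap2);
# returns a matrix of gametes (rows = meioses, cols = all loci)
drop_gametes <- function(hap1, hap2, parents, blocks) {
  m <- length(parents)
  out <- matrix(0L, m, ncol(hap1))
  for (blk in blocks) {
    cols <- blk$cols
    L <- length(cols)
    ph <- matrix(0L, m, L)
    ph[, 1] <- stats::rbinom(m, 1L, 0.5)
    if (L > 1) for (j in 2:L) {
      sw <- stats::rbinom(m, 1L, blk$r[j - 1])
      ph[, j] <- (ph[, j - 1] + sw) %% 2L
    }
    h1 <- hap1[parents, cols, drop = FALSE]
    h2 <- hap2[parents, cols, drop = FALSE]
    out[, cols] <- h1 * (1L - ph) + h2 * ph
  }
  out
}

#' Sample one recombinant gamete from a parent
#'
#' Explicit meiosis for a single parent: per chromosome, the crossover count
#' is Poisson with mean the map length in Morgans, crossover positions are
#' uniform along the chromosome, and the starting haplotype is chosen at
#' random.  At every locus the returned allele is one of the parent's two.
#'
#' @param parent an individual as returned by \code{\link{get_individual}}
#'   (any list with \code{hap1} and \code{hap2} vectors over all loci).
#' @param genome the \code{\link{genome_spec}}.
#' @return integer vector: one haplotype over all loci.  The realized
#'   crossover count per chromosome is attached as attribute
#'   \code{"crossovers"}.
#' @export
sample_gamete <- function(parent, genome) {
  if (is.null(parent$hap1) || is.null(parent$hap2) ||
      length(parent$hap1) != genome$n_loci ||
      length(parent$hap2) != genome$n_loci)
    stop("sample_gamete: parent must carry two complete haplotypes",
         call. = FALSE)
  gam <- integer(genome$n_loci)
  nco <- integer(genome$n_chromosomes)
  for (chr in seq_len(genome$n_chromosomes)) {
    cols <- which(genome$loci$chr == chr)
    pos <- genome$loci$pos[cols]
    len_m <- genome$chromosome_length / 100
    k <- stats::rpois(1, len_m)
    nco[chr] <- k
    xo <- sort(stats::runif(k, 0, genome$chromosome_length))
    start <- stats::rbinom(1, 1L, 0.5)
    phase <- (start + findInterval(pos, xo)) %% 2L
    gam[cols] <- ifelse(phase == 0L, parent$hap1[cols], parent$hap2[cols])
  }
  attr(gam, "crossovers") <- nco
  gam
}

#' Simulate a founder population
#'
#' Builds founders in approximate Hardy-Weinberg equilibrium with
#' linkage disequilibrium induced by drift: initial allele frequencies are
#' drawn uniformly from the configured range, haplotypes are sampled
#' independently per locus, and the population is then mated at random for a
#' number of burn-in generations at a fixed census size before being
#' expanded to the requested founder counts.  Founders have unknown parents
#' (pedigree inbreeding 0 by definition); this generator is a documented
#' stand-in for an external historical-population simulator.
#'
#' @param genome a \code{\link{genome_spec}}.
#' @param n_males,n_females founder counts by sex.
#' @param n_burnin_generations burn-in generations of random mating
#'   (default 100).
#' @param burnin_size census size during burn-in (default 500).
#' @param seed integer seed; identical seed and configuration give a
#'   bit-identical population.
#' @return a \code{population} of generation 0 with unknown parents.
#' @export
simulate_founders <- function(genome, n_males = 1000, n_females = 1000,
                              n_burnin_generations = 100, burnin_size = 500,
                              seed = 1) {
  if (n_males < 1 || n_females < 1)
    stop("simulate_founders: founder counts must be positive", call. = FALSE)
  fr <- genome$founder_allele_freq_range
  set.seed(derive_seed(seed, 101))
  p <- stats::runif(genome$n_loci, fr[1], fr[2])
  blocks <- chrom_blocks(genome)
  draw_haps <- function(n) {
    matrix(stats::rbinom(n * genome$n_loci, 1L, rep(p, each = n)), nrow = n)
  }
  if (n_burnin_generations > 0) {
    n0 <- burnin_size
    hap1 <- draw_haps(n0); hap2 <- draw_haps(n0)
    sex <- rep(c("M", "F"), length.out = n0)
    for (g in seq_len(n_burnin_generations)) {
      set.seed(derive_seed(seed, 102, g))
      males <- which(sex == "M"); females <- which(sex == "F")
      si <- sample(males, n0, replace = TRUE)
      di <- sample(females, n0, replace = TRUE)
      h1 <- drop_gametes(hap1, hap2, si, blocks)
      h2 <- drop_gametes(hap1, hap2, di, blocks)
      hap1 <- h1; hap2 <- h2
      sex <- rep(c("M", "F"), length.out = n0)
    }
    # final expansion to the requested founder counts
    set.seed(derive_seed(seed, 103))
    n <- n_males + n_females
    males <- which(sex == "M"); females <- which(sex == "F")
    si <- sample(males, n, replace = TRUE)
    di <- sample(females, n, replace = TRUE)
    h1 <- drop_gametes(hap1, hap2, si, blocks)
    h2 <- drop_gametes(hap1, hap2, di, blocks)
    hap1 <- h1; hap2 <- h2
  } else {
    n <- n_males + n_females
    hap1 <- draw_haps(n); hap2 <- draw_haps(n)
  }
  sex <- rep(c("M", "F"), c(n_males, n_females))
  new_population(hap1, hap2, sire = rep(0L, n), dam = rep(0L, n),
                 sex = sex, generation = rep(0L, n), genome = genome)
}

#' True breeding values from QTL dosages
#' @param pop a \code{population}.
#' @param trait a \code{\link{trait_model}}.
#' @param ids individual ids (default all).
#' @return numeric vector of TBVs.
#' @export
compute_tbv <- function(pop, trait, ids = pop$id) {
  q <- pop$genome$qtl_idx
  if (length(trait$qtl_effects) != length(q))
    stop("compute_tbv: effect count does not match QTL count", call. = FALSE)
  dos <- pop$hap1[ids, q, drop = FALSE] + pop$hap2[ids, q, drop = FALSE]
  as.numeric(dos %*% trait$qtl_effects) - (trait$offset %||% 0)
}

#' Calibrate the trait model on a founder population
#'
#' Rescales the QTL effects by a single constant so that the sample variance
#' of founder true breeding values equals the target genetic variance
#' exactly, and centres breeding values at the founder mean (the base
#' population defines zero).  The calibration is scale-invariant:
#' multiplying all effects by any constant before calibration yields the
#' same calibrated model.
#'
#' @param pop founder \code{population}.
#' @param trait a \code{\link{trait_model}} with uncalibrated effects.
#' @param rescale if \code{TRUE} (default) rescale to \code{trait$sigma2_g}.
#' @return the calibrated \code{trait_model}.
#' @export
assign_trait <- function(pop, trait, rescale = TRUE) {
  tbv <- compute_tbv(pop, trait)
  v <- stats::var(tbv)
  if (v <= 0)
    stop("assign_trait: founder TBV variance is zero (all QTL monomorphic)",
         call. = FALSE)
  if (!rescale) return(trait)
  k <- sqrt(trait$sigma2_g / v)
  eff <- trait$qtl_effects * k
  cal <- trait_model(eff, trait$sigma2_g, trait$sigma2_e)
  # express TBVs as deviations from the founder mean
  cal$offset <- mean(compute_tbv(pop, cal))
  cal
}

#' Add phenotypes to individuals
#'
#' Phenotype = TBV + Normal(0, sigma2_e) noise, with the supplied record
#' weight (default 1, the single-record female analogue; weights > 1 emulate
#' progeny-based records).
#'
#' @param pop a \code{population} with TBVs set.
#' @param trait a \code{\link{trait_model}}.
#' @param ids ids to phenotype.
#' @param weight record weight(s), recycled over \code{ids}.
#' @return the updated \code{population}.
#' @export
add_phenotypes <- function(pop, trait, ids, weight = 1) {
  pop$phenotype[ids] <- pop$tbv[ids] +
    stats::rnorm(length(ids), 0, sqrt(trait$sigma2_e))
  pop$weight[ids] <- rep_len(weight, length(ids))
  pop
}

#' Create one offspring from a sire and a dam
#'
#' @param pop a \code{population} containing both parents.
#' @param sire_id,dam_id parent ids; the sire must be male and the dam female.
#' @param sex offspring sex, "M" or "F".
#' @param generation offspring birth generation (must exceed both parents').
#' @param trait a \code{\link{trait_model}} used for the TBV and, when
#'   \code{phenotype = TRUE}, the phenotype.
#' @param phenotype logical; draw a phenotype record for the offspring.
#' @return the \code{population} with one appended individual.
#' @export
make_offspring <- function(pop, sire_id, dam_id, sex, generation, trait,
                           phenotype = FALSE) {
  if (pop$sex[sire_id] != "M")
    stop("make_offspring: sire must be male", call. = FALSE)
  if (pop$sex[dam_id] != "F")
    stop("make_offspring: dam must be female", call. = FALSE)
  if (generation <= max(pop$generation[c(sire_id, dam_id)]))
    stop("make_offspring: offspring generation must exceed the parents'",
         call. = FALSE)
  g1 <- sample_gamete(get_individual(pop, sire_id), pop$genome)
  g2 <- sample_gamete(get_individual(pop, dam_id), pop$genome)
  append_offspring(pop, matrix(g1, 1), matrix(g2, 1),
                   sire = sire_id, dam = dam_id, sex = sex,
                   generation = generation, trait = trait,
                   phenotype = phenotype)
}

# append a batch of offspring given paternal/maternal gamete matrices
append_offspring <- function(pop, pat, mat, sire, dam, sex, generation,
                             trait, phenotype = FALSE) {
  n_new <- nrow(pat)
  pop$hap1 <- rbind(pop$hap1, pat)
  pop$hap2 <- rbind(pop$hap2, mat)
  pop$sire <- c(pop$sire, as.integer(sire))
  pop$dam <- c(pop$dam, as.integer(dam))
  pop$sex <- c(pop$sex, sex)
  pop$generation <- c(pop$generation, rep(as.integer(generation), n_new))
  new_ids <- length(pop$id) + seq_len(n_new)
  pop$id <- c(pop$id, new_ids)
  pop$tbv <- c(pop$tbv, rep(NA_real_, n_new))
  pop$phenotype <- c(pop$phenotype, rep(NA_real_, n_new))
  pop$weight <- c(pop$weight, rep(1, n_new))
  pop$tbv[new_ids] <- compute_tbv(pop, trait, new_ids)
  if (phenotype) pop <- add_phenotypes(pop, trait, new_ids)
  pop
}

# batch mating: one offspring per (sire, dam) pair via the bulk gamete
# dropper; sexes supplied by the caller
breed_batch <- function(pop, sires, dams, sexes, generation, trait,
                        phenotype = FALSE) {
  blocks <- chrom_blocks(pop$genome)
  pat <- drop_gametes(pop$hap1, pop$hap2, sires, blocks)
  mat <- drop_gametes(pop$hap1, pop$hap2, dams, blocks)
  append_offspring(pop, pat, mat, sire = sires, dam = dams, sex = sexes,
                   generation = generation, trait = trait,
                   phenotype = phenotype)
}
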