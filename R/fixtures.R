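#' Deterministic miniature data sets for the update experiment
#'
#' Simulates a founder cohort plus two descendant generations and labels
#' them as the three-cohort split used by the single-generation update
#' experiment: the oldest cohort A1 (phenotyped initial reference), the
#' middle cohort A2 (phenotyped update candidates) and the youngest cohort V
#' (unphenotyped validation, with held-out true breeding values).  The trait
#' keeps the default variance components (heritability 0.3) so metric
#' magnitudes stay on the same scale as real milk-yield evaluations.
#'
#' @param preset "tiny" (50 individuals, 200 markers) or "desk"
#'   (2,000 individuals, 2,000 markers).
#' @param seed integer seed; fixtures are byte-stable for a fixed seed.
#' @param outdir optional directory; when given, writes genotypes.tsv,
#'   phenotypes.tsv, pedigree.tsv, splits.tsv and bv.tsv there.
#' @return list with \code{genotypes} (dosage matrix, markers only),
#'   \code{phenotypes} (named vector over A1 and A2), \code{weights},
#'   \code{pedigree} (data.frame), \code{splits} (list A1/A2/V id vectors),
#'   \code{bv} (named true BVs over all ids), \code{trait} and \code{pop}.
#' @export
make_update_fixture <- function(preset = c("tiny", "desk"), seed = 7,
                                outdir = NULL) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    genome <- genome_spec(n_chromosomes = 5, chromosome_length = 100,
                          n_markers_per_chr = 40, n_qtl_per_chr = 5)
    n_founder <- 20; n_g1 <- 15; n_g2 <- 15
    burnin <- 20; burnin_size <- 40
  } else {
    genome <- genome_spec()
    n_founder <- 800; n_g1 <- 600; n_g2 <- 600
    burnin <- 50; burnin_size <- 400
  }
  pop <- simulate_founders(genome, n_founder %/% 2,
                           n_founder - n_founder %/% 2,
                           burnin, burnin_size,
                           seed = derive_seed(seed, 31))
  set.seed(derive_seed(seed, 32))
  trait <- assign_trait(pop, trait_model(stats::rnorm(length(genome$qtl_idx))))
  pop$tbv <- compute_tbv(pop, trait)
  grow <- function(pop, n, gen) {
    prev <- pop$id[pop$generation == gen - 1L]
    males <- prev[pop$sex[prev] == "M"]
    females <- prev[pop$sex[prev] == "F"]
    sires <- sample(males, n, replace = TRUE)
    dams <- sample(females, n, replace = TRUE)
    sexes <- rep(c("M", "F"), length.out = n)
    breed_batch(pop, sires, dams, sexes, gen, trait)
  }
  set.seed(derive_seed(seed, 33))
  pop <- grow(pop, n_g1, 1L)
  pop <- grow(pop, n_g2, 2L)
  A1 <- pop$id[pop$generation == 0L]
  A2 <- pop$id[pop$generation == 1L]
  V <- pop$id[pop$generation == 2L]
  set.seed(derive_seed(seed, 34))
  pop <- add_phenotypes(pop, trait, c(A1, A2))
  geno <- marker_dosages(pop)
  ids <- as.character(pop$id)
  phen <- stats::setNames(pop$phenotype, ids)[as.character(c(A1, A2))]
  wts <- stats::setNames(pop$weight, ids)[as.character(c(A1, A2))]
  bv <- stats::setNames(pop$tbv, ids)
  ped <- pedigree(pop)
  splits <- list(A1 = as.character(A1), A2 = as.character(A2),
                 V = as.character(V))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(geno, file.path(outdir, "genotypes.tsv"))
    write_phenotypes(data.frame(id = names(phen), phenotype = phen,
                                weight = wts),
                     file.path(outdir, "phenotypes.tsv"))
    write_pedigree(ped, file.path(outdir, "pedigree.tsv"))
    utils::write.table(
      data.frame(id = unlist(splits),
                 split = rep(names(splits), lengths(splits))),
      file.path(outdir, "splits.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(id = names(bv), bv = bv),
                       file.path(outdir, "bv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genotypes = geno, phenotypes = phen, weights = wts, pedigree = ped,
       splits = splits, bv = bv, trait = trait, pop = pop)
}

#' Hand-computable micro-fixtures with expected-output manifest
#'
#' Emits the known-answer cases used throughout the test suite as files:
#' a two-marker genotype whose VanRaden self-relationship is exactly 2, a
#' full-sib pedigree whose offspring inbreeding is 0.25, and an
#' identity-relationship optimal-contribution case whose cap sits exactly at
#' the minimum group coancestry so the contributions are uniform.  Expected
#' values are written alongside in \code{manifest.json}.
#'
#' @param outdir output directory.
#' @return (invisibly) the manifest list.
#' @export
make_known_answer_sets <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # 1: VanRaden self-relationship 2 at p = 0.5: Z = (-1, 1), denom = 1
  g1 <- matrix(c(0, 2), 1, 2, dimnames = list("i1", c("M1", "M2")))
  write_genotypes(g1, file.path(outdir, "gmatrix_micro.tsv"))
  # 2: full-sib mating: offspring of full sibs has F = 0.25
  ped <- data.frame(id = c("p1", "p2", "s1", "s2", "x"),
                    sire = c("0", "0", "p1", "p1", "s1"),
                    dam = c("0", "0", "p2", "p2", "s2"),
                    generation = c(0, 0, 1, 1, 2))
  write_pedigree(ped, file.path(outdir, "pedigree_micro.tsv"))
  # 3: G = I over 4 candidates, cap at the minimum 1/(2n): uniform c
  G <- diag(4)
  dimnames(G) <- list(paste0("c", 1:4), paste0("c", 1:4))
  write_gmatrix(G, file.path(outdir, "oc_micro_G.tsv"))
  utils::write.table(data.frame(id = paste0("c", 1:4),
                                gebv = c(4, 3, 2, 1)),
                     file.path(outdir, "oc_micro_gebv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    gmatrix_micro = list(file = "gmatrix_micro.tsv", freqs = c(0.5, 0.5),
                         expected_self_relationship = 2),
    pedigree_micro = list(file = "pedigree_micro.tsv",
                          expected_inbreeding = list(x = 0.25)),
    oc_micro = list(G = "oc_micro_G.tsv", gebv = "oc_micro_gebv.tsv",
                    deltaF_max = 0.125, current_mean_f = 0,
                    expected_contributions = rep(0.25, 4)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
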