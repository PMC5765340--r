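test_that("founder haplotypes follow the configured allele frequencies", {
  g <- genome_spec(n_chromosomes = 2, n_markers_per_chr = 50,
                   n_qtl_per_chr = 5,
                   founder_allele_freq_range = c(0.5, 0.5))
  pop <- simulate_founders(g, 1000, 1000, n_burnin_generations = 0, seed = 4)
  expect_equal(pop_size(pop), 2000)
  expect_true(all(pop$sire == 0) && all(pop$dam == 0))
  # each marker frequency within 4 SE of binomial(2n, 0.5)
  freq <- colMeans(marker_dosages(pop)) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 2000))
  expect_true(all(abs(freq - 0.5) < 4 * se))
})

test_that("founder simulation is seed-deterministic", {
  g <- tiny_genome()
  p1 <- simulate_founders(g, 10, 10, n_burnin_generations = 3,
                          burnin_size = 20, seed = 9)
  p2 <- simulate_founders(g, 10, 10, n_burnin_generations = 3,
                          burnin_size = 20, seed = 9)
  p3 <- simulate_founders(g, 10, 10, n_burnin_generations = 3,
                          burnin_size = 20, seed = 10)
  expect_identical(p1$hap1, p2$hap1)
  expect_identical(p1$hap2, p2$hap2)
  expect_false(identical(p1$hap1, p3$hap1))
})

test_that("invalid founder configuration errors", {
  expect_error(genome_spec(founder_allele_freq_range = c(0, 0.5)),
               "freq")
  expect_error(simulate_founders(tiny_genome(), 0, 10), "positive")
})

test_that("sample_gamete respects Mendelian constraints", {
  g <- tiny_genome()
  pop <- simulate_founders(g, 2, 2, n_burnin_generations = 0, seed = 1)
  parent <- get_individual(pop, 1)
  set.seed(42)
  for (k in 1:20) {
    gam <- sample_gamete(parent, g)
    ok <- gam == parent$hap1 | gam == parent$hap2
    expect_true(all(ok))
  }
  # homozygous parent: gamete equals the haplotype exactly
  hom <- list(hap1 = rep(1L, g$n_loci), hap2 = rep(1L, g$n_loci))
  expect_identical(as.integer(sample_gamete(hom, g)), rep(1L, g$n_loci))
})

test_that("crossover count matches the Poisson map-length mean", {
  g <- genome_spec(n_chromosomes = 1, chromosome_length = 100,
                   n_markers_per_chr = 10, n_qtl_per_chr = 0)
  parent <- list(hap1 = rep(0L, g$n_loci), hap2 = rep(1L, g$n_loci))
  set.seed(7)
  n_gam <- 10000
  counts <- vapply(seq_len(n_gam), function(i)
    sum(attr(sample_gamete(parent, g), "crossovers")), numeric(1))
  # mean 1.0 within 3 SE of Poisson(1)
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / n_gam))
})

test_that("offspring inherit one allele from each parent", {
  sys <- tiny_system(n = 12, seed = 5)
  pop <- sys$pop
  set.seed(11)
  pop2 <- make_offspring(pop, sire_id = 1, dam_id = 12, sex = "F",
                         generation = 1, trait = sys$trait)
  off <- get_individual(pop2, pop_size(pop2))
  s <- get_individual(pop, 1); d <- get_individual(pop, 12)
  expect_true(all(off$hap1 == s$hap1 | off$hap1 == s$hap2))
  expect_true(all(off$hap2 == d$hap1 | off$hap2 == d$hap2))
  # dosage at jointly homozygous loci is preserved
  hom <- which(s$hap1 == s$hap2 & d$hap1 == d$hap2 & s$hap1 == d$hap1)
  expect_true(all((off$hap1 + off$hap2)[hom] == (s$hap1 + s$hap2)[hom]))
  expect_error(make_offspring(pop, sire_id = 12, dam_id = 1, sex = "M",
                              generation = 1, trait = sys$trait),
               "male")
})

test_that("zero residual variance makes phenotype equal TBV", {
  sys <- tiny_system(n = 10, seed = 6)
  tr0 <- trait_model(sys$trait$qtl_effects, sys$trait$sigma2_g,
                     sigma2_e = 0)
  pop <- add_phenotypes(sys$pop, tr0, ids = 1:5)
  expect_equal(pop$phenotype[1:5], pop$tbv[1:5])
})

test_that("trait calibration hits the target variance and is scale invariant", {
  sys <- tiny_system(n = 40, seed = 8)
  tr <- sys$trait
  expect_equal(var(compute_tbv(sys$pop, tr)), 423390, tolerance = 1e-9)
  # doubling effects before calibration yields the same calibrated model
  tr2 <- assign_trait(sys$pop, trait_model(2 * tr$qtl_effects))
  expect_equal(tr2$qtl_effects, tr$qtl_effects, tolerance = 1e-12)
  # monomorphic QTL: zero variance errors
  g <- tiny_genome()
  pop0 <- simulate_founders(g, 5, 5, n_burnin_generations = 0, seed = 1)
  pop0$hap1[, g$qtl_idx] <- 0L
  pop0$hap2[, g$qtl_idx] <- 0L
  expect_error(assign_trait(pop0, trait_model(rnorm(length(g$qtl_idx)))),
               "variance")
})

test_that("heterozygosity decays at the drift rate under random mating", {
  g <- genome_spec(n_chromosomes = 2, n_markers_per_chr = 40,
                   n_qtl_per_chr = 2,
                   founder_allele_freq_range = c(0.5, 0.5))
  N <- 100; t <- 8; reps <- 20
  h_ratio <- vapply(seq_len(reps), function(r) {
    pop0 <- simulate_founders(g, N / 2, N / 2, n_burnin_generations = 0,
                              seed = 100 + r)
    h0 <- observed_heterozygosity(marker_dosages(pop0))$mean
    popt <- simulate_founders(g, N / 2, N / 2, n_burnin_generations = t,
                              burnin_size = N, seed = 100 + r)
    ht <- observed_heterozygosity(marker_dosages(popt))$mean
    ht / h0
  }, numeric(1))
  # burn-in runs t mating generations plus the final expansion mating
  expected <- (1 - 1 / (2 * N))^(t + 1)
  se <- sd(h_ratio) / sqrt(reps)
  expect_lt(abs(mean(h_ratio) - expected), 3 * se + 1e-6)
})
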