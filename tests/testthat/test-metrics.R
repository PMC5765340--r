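test_that("observed heterozygosity counts dosage-1 loci", {
  X <- rbind(a = c(0, 1, 2, 1), b = c(1, 1, 1, 1), c = c(0, 2, 2, 0))
  h <- observed_heterozygosity(X)
  expect_equal(unname(h$per_individual), c(0.5, 1, 0))
  expect_equal(h$mean, 0.5)
  expect_error(observed_heterozygosity(matrix(0, 2, 0)), "markers")
})

test_that("pedigree inbreeding reproduces classical values", {
  # offspring of full sibs with unrelated grandparents: F = 0.25
  full_sib <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                         dam = c(0, 0, 2, 2, 4))
  # offspring of half sibs (shared sire only): F = 0.125
  half_sib <- data.frame(id = 1:6, sire = c(0, 0, 0, 1, 1, 4),
                         dam = c(0, 0, 0, 2, 3, 5))
  for (m in c("meuwissen", "tabular")) {
    f1 <- pedigree_inbreeding(full_sib, m)
    expect_equal(unname(f1), c(0, 0, 0, 0, 0.25))
    f2 <- pedigree_inbreeding(half_sib, m)
    expect_equal(unname(f2[6]), 0.125)
  }
})

test_that("the two inbreeding algorithms agree on random pedigrees", {
  for (s in 1:6) {
    n <- sample(30:150, 1)
    ped <- random_pedigree(n, seed = 200 + s)
    fm <- pedigree_inbreeding(ped, "meuwissen")
    ft <- pedigree_inbreeding(ped, "tabular")
    expect_equal(fm, ft, tolerance = 1e-10)
  }
  # out-of-order pedigree errors
  bad <- data.frame(id = 1:3, sire = c(2, 0, 0), dam = c(3, 0, 0))
  expect_error(pedigree_inbreeding(bad), "before")
})

test_that("prediction bias is the standardized absolute error", {
  expect_equal(prediction_bias(c(1, 2), c(1, 2), 1)$mean, 0)
  expect_equal(prediction_bias(5, 3, 2)$per_individual, 1)
  expect_equal(prediction_bias(3, 1, 4)$mean, 0.5)
  expect_error(prediction_bias(1, 2, 0), "sigma_G")
})

test_that("effective size inverts mean inbreeding with an undefined guard", {
  expect_equal(effective_size(0.05), 10)
  expect_equal(effective_size(0.25), 2)
  expect_warning(ne0 <- effective_size(0), "undefined")
  expect_true(is.na(ne0))
  expect_error(effective_size(1), "mean_f")
})

test_that("generation equivalents sum known-ancestor proportions", {
  ped <- data.frame(id = c("a", "b", "x"), sire = c("0", "0", "a"),
                    dam = c("0", "0", "b"))
  expect_equal(generation_equivalents(ped, "x"), 1)
  ped2 <- data.frame(id = c(1:6, 9), sire = c(0, 0, 0, 0, 1, 3, 5),
                     dam = c(0, 0, 0, 0, 2, 4, 6))
  expect_equal(generation_equivalents(ped2, 9), 2)
  # one known parent whose own parents are both known: 0.5 + 0.5
  ped3 <- data.frame(id = c(1, 2, 3, 4), sire = c(0, 0, 1, 3),
                     dam = c(0, 0, 2, 0))
  expect_equal(generation_equivalents(ped3, 4), 1)
  expect_error(generation_equivalents(ped3, 99), "unknown")
})

test_that("trend estimation equals the per-replicate OLS oracle", {
  # exactly linear metric: slope recovered with zero SE
  gens <- 1:6
  m <- do.call(rbind, lapply(1:3, function(r)
    data.frame(replicate = r, generation = gens, strategy = "s",
               mean_bv = 10 + 3.5 * gens, mean_bias = 0.1 * gens,
               mean_f = 0.01 * gens, mean_het = 0.4 - 0.02 * gens)))
  tr <- estimate_trends(m)
  expect_equal(tr$slope[tr$metric == "mean_bv"], 3.5, tolerance = 1e-10)
  expect_equal(tr$se[tr$metric == "mean_bv"], 0, tolerance = 1e-10)
  # two replicates with different slopes: estimate is the average
  m2 <- rbind(
    data.frame(replicate = 1, generation = gens, strategy = "s",
               mean_bv = 2 * gens, mean_bias = 0, mean_f = 0,
               mean_het = 0),
    data.frame(replicate = 2, generation = gens, strategy = "s",
               mean_bv = 4 * gens, mean_bias = 0, mean_f = 0,
               mean_het = 0))
  tr2 <- estimate_trends(m2, metric_cols = "mean_bv")
  expect_equal(tr2$slope, 3, tolerance = 1e-10)
  # noisy table against a closed-form OLS oracle
  set.seed(31)
  m3 <- do.call(rbind, lapply(1:4, function(r)
    data.frame(replicate = r, generation = gens, strategy = "s",
               mean_bv = 5 * gens + rnorm(6), mean_bias = 0,
               mean_f = 0, mean_het = 0)))
  tr3 <- estimate_trends(m3, metric_cols = "mean_bv")
  ols <- vapply(1:4, function(r) {
    y <- m3$mean_bv[m3$replicate == r]
    sum((gens - mean(gens)) * (y - mean(y))) / sum((gens - mean(gens))^2)
  }, numeric(1))
  expect_equal(tr3$slope, mean(ols), tolerance = 1e-10)
  # arcsine transform changes the proportion-scale slopes
  m$mean_het <- 0.4 - 0.02 * m$generation
  tra <- estimate_trends(m, metric_cols = "mean_het", arcsine = TRUE)
  oracle_a <- vapply(1:3, function(r) {
    y <- asin(sqrt(0.4 - 0.02 * gens))
    sum((gens - mean(gens)) * (y - mean(y))) / sum((gens - mean(gens))^2)
  }, numeric(1))
  expect_equal(tra$slope, mean(oracle_a), tolerance = 1e-10)
})

test_that("metrics are invariant to individual ordering", {
  X <- random_dosages(12, 30, seed = 44)
  p <- sample(nrow(X))
  expect_equal(observed_heterozygosity(X[p, ])$mean,
               observed_heterozygosity(X)$mean)
  ped <- random_pedigree(40, seed = 45)
  f <- pedigree_inbreeding(ped)
  expect_equal(mean(f), mean(f[as.character(sample(ped$id))]))
})
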