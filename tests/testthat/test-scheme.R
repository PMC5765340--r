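# desk-scale-but-small configuration shared across scheme tests
mini_config <- function(n_generations = 3, n_replicates = 2) {
  scheme_config(n_generations = n_generations, n_sires = 10, n_dams = 30,
                ref_update_size = 10, n_replicates = n_replicates,
                n_founder_males = 60, n_founder_females = 60,
                genome = genome_spec(n_chromosomes = 3,
                                     n_markers_per_chr = 40,
                                     n_qtl_per_chr = 8),
                n_burnin_generations = 8, burnin_size = 60)
}

test_that("update_reference implements the three strategies", {
  refs <- 1:10
  cands <- 11:15
  gebv <- c(5, 4, 3, 2, 1)
  out <- update_reference(refs, cands, gebv, strategy = "truncation",
                          update_size = 2)
  expect_equal(attr(out, "added"), c(11L, 12L))
  expect_equal(sort(out), 1:12)
  set.seed(5)
  r1 <- update_reference(refs, cands, gebv, strategy = "random",
                         update_size = 3)
  set.seed(5)
  r2 <- update_reference(refs, cands, gebv, strategy = "random",
                         update_size = 3)
  expect_identical(r1, r2)
  G <- gsrefresh:::new_gmatrix(diag(5), "similarity", as.character(cands))
  o <- update_reference(refs, cands, gebv, G, strategy = "oc",
                        update_size = 2, oc_par = oc_params(0.9, 0))
  expect_equal(attr(o, "added")[1], 11L)   # top-GEBV vertex
  expect_error(update_reference(refs, cands, gebv, strategy = "random",
                                update_size = 9), "exceeds")
  expect_error(update_reference(refs, c(1, 11), c(1, 2),
                                strategy = "random", update_size = 1),
               "disjoint")
})

test_that("select_breeders applies the selection rates and the reuse cap", {
  males <- 1:250
  females <- 301:550
  prev_dams <- 601:1100
  gebv <- setNames(rnorm(1100), as.character(1:1100))
  uses <- setNames(rep(1L, 500), as.character(prev_dams))
  br <- select_breeders(males, females, prev_dams, gebv, n_sires = 150,
                        n_dams = 500, dam_uses = uses)
  expect_length(br$sires, 150)
  expect_length(br$dams, 500)
  expect_equal(length(br$sires) / length(males), 0.6)  # male selection rate
  expect_true(all(females %in% br$dams))               # female rate 1
  expect_equal(sum(br$dams %in% prev_dams), 250)       # previous-dam rate 0.5
  # dams over the reuse cap are excluded
  uses2 <- uses
  uses2[] <- 2L
  uses2[as.character(601:850)] <- 1L
  br2 <- select_breeders(males, females, prev_dams, gebv, 150, 500,
                         dam_uses = uses2)
  expect_true(all(br2$dams[br2$dams %in% prev_dams] %in% 601:850))
  # sires are the top-GEBV males
  expect_equal(sort(br$sires),
               sort(males[order(-gebv[as.character(males)])][1:150]))
})

test_that("one generation preserves the closed-population contract", {
  cfg <- mini_config()
  state <- gsrefresh:::init_scheme_state(cfg, "truncation", 1L, seed = 21)
  expect_length(state$ref_ids, 60)          # founder males
  state <- run_generation(state)
  pop <- state$pop
  off <- pop$id[pop$generation == 1]
  expect_length(off, cfg$n_dams)            # one offspring per dam
  expect_true(all(pop$sex[pop$sire[off]] == "M"))
  expect_true(all(pop$sex[pop$dam[off]] == "F"))
  m <- state$metrics[[1]]
  expect_equal(m$ref_size, 60)              # no update in generation 1
  state2 <- run_generation(state)
  expect_equal(state2$metrics[[2]]$ref_size, 70)
  # every offspring's parents were selected breeders
  off2 <- state2$pop$id[state2$pop$generation == 2]
  expect_true(all(state2$pop$generation[state2$pop$sire[off2]] == 1))
})

test_that("scenario metrics are deterministic and well-shaped", {
  cfg <- mini_config(n_generations = 3, n_replicates = 2)
  s1 <- suppressMessages(run_scenario(cfg, "truncation", seed = 33))
  s2 <- suppressMessages(run_scenario(cfg, "truncation", seed = 33))
  expect_identical(s1$metrics, s2$metrics)
  s3 <- suppressMessages(run_scenario(cfg, "truncation", seed = 34))
  expect_false(identical(s1$metrics$mean_bv, s3$metrics$mean_bv))
  m <- s1$metrics
  expect_equal(nrow(m), 2 * 3)              # replicates x generations
  expect_true(all(c("replicate", "generation", "strategy", "mean_bv",
                    "mean_het", "mean_f", "mean_bias", "ne",
                    "ne_over_n") %in% names(m)))
  # reference-size arithmetic at the test scale
  expect_equal(m$ref_size[m$replicate == 1], 60 + 10 * (0:2))
  # genetic merit responds to selection in most replicates
  slopes <- tapply(m$mean_bv, m$replicate, function(x) diff(range(x)))
  expect_true(mean(m$mean_bv[m$generation == 3]) >
                mean(m$mean_bv[m$generation == 1]))
})

test_that("single-generation update experiment runs on a synthetic fixture", {
  fx <- make_update_fixture("tiny", seed = 13)
  res <- run_update_experiment(fx$genotypes, fx$phenotypes, fx$splits,
                               fx$bv, sizes = c(5, 10),
                               top_n = 8, n_random = 3, ped = fx$pedigree,
                               seed = 3)
  expect_equal(nrow(res), 2 * (3 + 1 + 1))  # sizes x (random reps + 2)
  expect_true(all(res$strategy %in% c("random", "truncation", "oc")))
  expect_true(all(is.finite(res$mean_bv)))
  expect_true(all(is.finite(res$mean_het)))
  # top_n = |V|: selected group is V itself, metrics equal whole-group values
  resV <- run_update_experiment(fx$genotypes, fx$phenotypes, fx$splits,
                                fx$bv, sizes = 5,
                                strategies = "truncation",
                                top_n = length(fx$splits$V), n_random = 1,
                                seed = 3)
  expect_equal(resV$mean_bv, mean(fx$bv[fx$splits$V]))
  expect_error(run_update_experiment(fx$genotypes, fx$phenotypes,
                                     fx$splits, fx$bv, sizes = 1e4),
               "size")
})
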