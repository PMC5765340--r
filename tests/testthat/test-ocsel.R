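test_that("expected rate of inbreeding follows the group-coancestry formula", {
  # all contribution on one non-inbred individual with self-relationship 1
  G1 <- gsrefresh:::new_gmatrix(matrix(1, 1, 1), "similarity", "a")
  expect_equal(expected_deltaF(1, G1, 0), 0.5)
  # uniform contributions over n = 50 unrelated candidates
  G50 <- gsrefresh:::new_gmatrix(diag(50), "similarity")
  expect_equal(expected_deltaF(rep(1 / 50, 50), G50, 0), 0.01)
  # coancestry equal to the baseline: no increase
  expect_equal(expected_deltaF(rep(1 / 50, 50), G50, 0.01), 0)
  # negative increase floors at zero
  expect_equal(expected_deltaF(rep(1 / 50, 50), G50, 0.5), 0)
  expect_error(expected_deltaF(1, G1, 1), "current_mean_f")
})

test_that("min_coancestry solves identity, block and brute-force cases", {
  G <- gsrefresh:::new_gmatrix(diag(5), "similarity")
  cm <- min_coancestry(G)
  expect_equal(cm$contribution, rep(0.2, 5), tolerance = 1e-10)
  # tight family (high within-block relationship) gets less total weight
  B <- rbind(cbind(matrix(0.8, 3, 3) + diag(0.4, 3), matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), matrix(0.1, 3, 3) + diag(0.4, 3)))
  dimnames(B) <- list(1:6, 1:6)
  cb <- min_coancestry(gsrefresh:::new_gmatrix(B, "similarity"))
  expect_lt(sum(cb$contribution[1:3]), sum(cb$contribution[4:6]))
  # closed form for two uniform blocks: weights inversely proportional to
  # the per-block effective relationship
  # random 3-candidate instances vs exhaustive grid at resolution 1e-3
  for (s in 1:5) {
    G3 <- random_gmatrix(3, seed = 40 + s)
    cm3 <- min_coancestry(G3)
    obj <- as.numeric(cm3$contribution %*% unclass(G3) %*% cm3$contribution)
    grid_best <- Inf
    for (c1 in seq(0, 1, 1e-3)) for (c2 in seq(0, 1 - c1, 1e-3)) {
      cc <- c(c1, c2, 1 - c1 - c2)
      v <- as.numeric(cc %*% unclass(G3) %*% cc)
      if (v < grid_best) grid_best <- v
    }
    expect_lt(obj, grid_best + 1e-6)
  }
})

test_that("optimal_contributions honors the cap and the fallback", {
  # unconstrained cap: all contribution on the top-GEBV candidate
  G <- gsrefresh:::new_gmatrix(diag(4), "similarity", paste0("c", 1:4))
  ct <- optimal_contributions(c(2, 9, 5, 1), G, oc_params(0.9, 0))
  expect_equal(ct$contribution, c(0, 1, 0, 0))
  expect_true(ct$feasible)
  # cap at the minimum achievable: uniform regardless of GEBVs
  cb <- optimal_contributions(c(4, 3, 2, 1), G, oc_params(1 / 8, 0))
  expect_equal(cb$contribution, rep(0.25, 4), tolerance = 1e-9)
  expect_true(cb$feasible)
  # cap below the minimum: min-coancestry fallback, flagged infeasible
  cf <- optimal_contributions(c(4, 3, 2, 1), G, oc_params(0.05, 0))
  expect_false(cf$feasible)
  expect_equal(cf$contribution, rep(0.25, 4), tolerance = 1e-9)
  expect_error(optimal_contributions(1:3, G, oc_params()), "mismatch")
})

test_that("optimizer matches the brute-force simplex grid on 3-candidate instances", {
  for (s in 1:8) {
    G <- random_gmatrix(3, seed = 60 + s)
    set.seed(70 + s)
    gebv <- rnorm(3)
    dF <- runif(1, 0.02, 0.4)
    ct <- optimal_contributions(gebv, G, oc_params(dF, 0))
    K <- dF
    br <- brute_oc_3(gebv, G, K)
    if (ct$feasible && is.finite(br$merit)) {
      # continuous optimum must not fall below the grid optimum
      expect_gt(ct$merit, br$merit - 1e-4 * max(1, abs(br$merit)))
      expect_lte(ct$deltaF, dF + 1e-6)
    } else {
      # both routes agree the cap is unattainable
      expect_false(ct$feasible)
      expect_true(!is.finite(br$merit))
    }
  }
})

test_that("achieved merit dominates min-coancestry and tightens monotonically", {
  G <- random_gmatrix(12, seed = 81)
  set.seed(82)
  gebv <- rnorm(12, 0, 2)
  cm <- min_coancestry(G, gebv)
  merits <- c()
  caps <- c(0.35, 0.25, 0.15, 0.08, 0.05)
  for (dF in caps) {
    ct <- optimal_contributions(gebv, G, oc_params(dF, 0))
    if (ct$feasible) {
      expect_gte(ct$merit, cm$merit - 1e-8)
      expect_lte(ct$deltaF, dF + 1e-6)
      merits <- c(merits, ct$merit)
    }
  }
  expect_true(all(diff(merits) < 1e-8))   # merit non-increasing as cap drops
  # determinism
  c1 <- optimal_contributions(gebv, G, oc_params(0.15, 0))
  c2 <- optimal_contributions(gebv, G, oc_params(0.15, 0))
  expect_identical(c1$contribution, c2$contribution)
})

test_that("select_update_group ranks by contribution, GEBV, then id", {
  ct <- gsrefresh:::new_contrib(paste0("c", 1:5), c(0.5, 0.3, 0.2, 0, 0),
                                gebv = c(5, 4, 3, 2, 1), deltaF = 0,
                                feasible = TRUE, method = "oc")
  expect_equal(select_update_group(ct, 2), c("c1", "c2"))
  expect_equal(select_update_group(ct, 5), paste0("c", 1:5))
  uni <- gsrefresh:::new_contrib(paste0("c", 1:5), rep(0.2, 5),
                                 gebv = c(1, 5, 3, 4, 2), deltaF = 0,
                                 feasible = TRUE, method = "oc")
  expect_equal(select_update_group(uni, 3), c("c2", "c4", "c3"))
  expect_error(select_update_group(ct, 0), "positive")
  expect_message(select_update_group(ct, 4), "zero-contribution")
})
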