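# shared fixtures and independent oracles, built in code at test time

tiny_genome <- function(n_chr = 2, n_markers = 25, n_qtl = 5) {
  genome_spec(n_chromosomes = n_chr, chromosome_length = 100,
              n_markers_per_chr = n_markers, n_qtl_per_chr = n_qtl)
}

# random dosage matrix with ids
random_dosages <- function(n, m, seed = 1, p = 0.5) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, p), n, m,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("M", seq_len(m))))
  X
}

# random positive-definite relationship matrix on a similarity-like scale
random_gmatrix <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  G <- crossprod(A) / n + diag(n) * 0.3
  G <- (G + t(G)) / 2
  dimnames(G) <- list(seq_len(n), seq_len(n))
  gsrefresh:::new_gmatrix(G, "similarity")
}

# joint mixed-model-equation oracle for GBLUP with candidates as zero-weight
# records: solves the full MME on (reference + candidates) directly
joint_mme_oracle <- function(G_all, y_ref, w_ref, idx_ref, s2g, s2e,
                             ridge = 0) {
  n <- nrow(G_all)
  Ga <- unclass(G_all)
  if (ridge > 0) diag(Ga) <- diag(Ga) + ridge
  Gi <- solve(Ga)
  W <- matrix(0, n, n)
  diag(W)[idx_ref] <- w_ref
  yfull <- numeric(n)
  yfull[idx_ref] <- y_ref
  # GLS mean from the reference block of V = s2g*G + s2e*W^-1
  Vrr <- s2g * Ga[idx_ref, idx_ref] + diag(s2e / w_ref, length(idx_ref))
  Vi1 <- solve(Vrr, rep(1, length(idx_ref)))
  mu <- sum(Vi1 * y_ref) / sum(Vi1)
  LHS <- W / s2e + Gi / s2g
  RHS <- W %*% (yfull - mu) / s2e
  list(mu = mu, ghat = as.numeric(solve(LHS, RHS)))
}

# exhaustive simplex-grid maximizer for 3- or 4-candidate OC instances
# (vectorized over the whole grid)
brute_oc_grid <- function(gebv, G, K, step = 1e-3) {
  n <- length(gebv)
  G <- unclass(G)
  s <- seq(0, 1, step)
  if (n == 3) {
    M <- as.matrix(expand.grid(c1 = s, c2 = s))
    M <- M[rowSums(M) <= 1 + 1e-12, , drop = FALSE]
    M <- cbind(M, 1 - rowSums(M))
  } else if (n == 4) {
    M <- as.matrix(expand.grid(c1 = s, c2 = s, c3 = s))
    M <- M[rowSums(M) <= 1 + 1e-12, , drop = FALSE]
    M <- cbind(M, 1 - rowSums(M))
  } else stop("brute_oc_grid: n must be 3 or 4")
  qf <- rowSums((M %*% G) * M)
  ok <- qf / 2 <= K + 1e-12
  if (!any(ok)) return(list(merit = -Inf, c = NULL))
  merit <- as.numeric(M[ok, , drop = FALSE] %*% gebv)
  best <- which.max(merit)
  list(merit = merit[best], c = M[ok, , drop = FALSE][best, ])
}
brute_oc_3 <- function(gebv, G, K, step = 1e-3)
  brute_oc_grid(gebv, G, K, step)

# random valid pedigree: founders then offspring with parents drawn from
# earlier individuals of the right sex
random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    prev <- seq_len(i - 1)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males) == 0 || length(females) == 0) next
    sire[i] <- if (length(males) == 1) males else sample(males, 1)
    dam[i] <- if (length(females) == 1) females else sample(females, 1)
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam,
             generation = cumsum(seq_len(n) > n_founders) * 0 +
               as.integer(seq_len(n) > n_founders))
}

# tiny GBLUP-ready system: population, dosages, similarity G
tiny_system <- function(n = 30, seed = 2) {
  g <- tiny_genome()
  pop <- simulate_founders(g, n %/% 2, n - n %/% 2,
                           n_burnin_generations = 5, burnin_size = n,
                           seed = seed)
  set.seed(seed + 1)
  trait <- assign_trait(pop, trait_model(rnorm(length(g$qtl_idx))))
  pop$tbv <- compute_tbv(pop, trait)
  list(genome = g, pop = pop, trait = trait)
}
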