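# the desk-scale scenario comparison is expensive, so it is run once and
# shared between the acceptance checks that consume it
.scenario_cache <- new.env(parent = emptyenv())

acceptance_scenarios <- function(n_replicates = 10, seed = 42) {
  key <- paste0("scen_", n_replicates, "_", seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  cfg <- scheme_config(n_replicates = n_replicates,
                       n_burnin_generations = 30)
  out <- lapply(c(random = "random", truncation = "truncation", oc = "oc"),
                function(s)
                  suppressMessages(run_scenario(cfg, s, seed = seed)))
  .scenario_cache[[key]] <- out
  out
}

# random OC instance on simulated genotypes: similarity G plus GEBVs
random_oc_instance <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * 300, 2, runif(300, 0.1, 0.9)), n, 300,
              byrow = TRUE,
              dimnames = list(seq_len(n), NULL))
  G <- similarity_grm(X)
  list(G = G, gebv = rnorm(n, 0, 1),
       f0 = max(0, min(mean(unclass(G)) / 2, 1 - 1e-9)))
}
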