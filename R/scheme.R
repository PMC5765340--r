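#' Breeding scheme configuration
#'
#' Defaults reproduce the simulated dairy-cattle design: a closed population
#' bred from 150 sires and 500 dams per generation, one offspring per dam,
#' offspring sex ratio 0.5, dams usable for at most two generations, and a
#' reference population of 1000 phenotyped ancestral males grown by 150
#' newly phenotyped individuals every generation (1000 in generation 1 up to
#' 2350 in generation 10).
#'
#' @param n_generations number of selection generations (default 10).
#' @param n_sires,n_dams breeders per generation (150 / 500).
#' @param dam_reuse_generations maximum breeding generations per dam (2).
#' @param offspring_per_dam offspring per dam per generation (1).
#' @param sex_ratio probability an offspring is male (0.5).
#' @param ref_update_size individuals added to the reference each
#'   generation (150).
#' @param n_replicates replicates for \code{\link{run_scenario}} (desk
#'   default 10; the full design uses 50).
#' @param n_founder_males,n_founder_females ancestral population (1000 each).
#' @param genome a \code{\link{genome_spec}}.
#' @param sigma2_g,sigma2_e trait variance components (heritability 0.3).
#' @param n_burnin_generations,burnin_size founder burn-in settings.
#' @param ridge diagonal stabilizer for GBLUP solves.
#' @param deltaF_max inbreeding-rate cap for the oc strategy (0.01).
#' @return a list of class \code{scheme_config}.
#' @export
scheme_config <- function(n_generations = 10, n_sires = 150, n_dams = 500,
                          dam_reuse_generations = 2, offspring_per_dam = 1,
                          sex_ratio = 0.5, ref_update_size = 150,
                          n_replicates = 10,
                          n_founder_males = 1000, n_founder_females = 1000,
                          genome = genome_spec(),
                          sigma2_g = 423390, sigma2_e = 987910,
                          n_burnin_generations = 100, burnin_size = 500,
                          ridge = 1e-2, deltaF_max = 0.01) {
  cfg <- as.list(environment())
  counts <- c(n_generations, n_sires, n_dams, dam_reuse_generations,
              offspring_per_dam, ref_update_size, n_replicates,
              n_founder_males, n_founder_females)
  if (any(counts <= 0)) stop("scheme_config: counts must be positive",
                             call. = FALSE)
  if (sex_ratio <= 0 || sex_ratio >= 1)
    stop("scheme_config: sex_ratio must be in (0, 1)", call. = FALSE)
  structure(cfg, class = "scheme_config")
}

#' Strategy configuration for the reference update
#'
#' @param strategy one of "random", "truncation", "oc".
#' @param update_size individuals added per update (default 150).
#' @param oc an \code{\link{oc_params}} object (used when strategy = "oc").
#' @return a list of class \code{strategy_config}.
#' @export
strategy_config <- function(strategy = c("random", "truncation", "oc"),
                            update_size = 150, oc = oc_params()) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy, update_size = update_size, oc = oc),
            class = "strategy_config")
}

#' Choose the reference-update group and extend the reference
#'
#' Implements the three updating strategies: \code{random} draws uniformly
#' without replacement; \code{truncation} takes the top GEBVs (ties by id);
#' \code{oc} runs \code{\link{optimal_contributions}} under the
#' inbreeding-rate cap and takes the \code{update_size} largest
#' contributions.
#'
#' @param reference current reference ids.
#' @param candidates candidate ids, disjoint from the reference.
#' @param gebv candidate GEBVs (same order as \code{candidates}).
#' @param G relationship \code{gmatrix} over the candidates (used by oc).
#' @param strategy a \code{\link{strategy_config}} or strategy name.
#' @param update_size group size (taken from the strategy config when
#'   omitted).
#' @param oc_par \code{\link{oc_params}} for the oc strategy.
#' @return the updated reference id vector (reference plus chosen group);
#'   the chosen ids are attached as attribute \code{"added"}.
#' @export
update_reference <- function(reference, candidates, gebv, G = NULL,
                             strategy = "random", update_size = NULL,
                             oc_par = oc_params()) {
  if (inherits(strategy, "strategy_config")) {
    if (is.null(update_size)) update_size <- strategy$update_size
    oc_par <- strategy$oc
    strategy <- strategy$strategy
  }
  if (is.null(update_size))
    stop("update_reference: update_size required", call. = FALSE)
  if (length(intersect(reference, candidates)) > 0)
    stop("update_reference: candidates must be disjoint from the reference",
         call. = FALSE)
  if (update_size > length(candidates))
    stop("update_reference: update_size exceeds candidate count",
         call. = FALSE)
  chosen <- switch(strategy,
    random = sample(candidates, update_size),
    truncation = candidates[order(-gebv, seq_along(candidates))][
      seq_len(update_size)],
    oc = {
      oc_fit <- optimal_contributions(gebv, G, oc_par)
      sel <- select_update_group(oc_fit, update_size)
      candidates[match(sel, as.character(candidates))]
    },
    stop("update_reference: unknown strategy ", strategy, call. = FALSE))
  out <- c(reference, chosen)
  attr(out, "added") <- chosen
  out
}

#' Select sires and dams for the next generation
#'
#' Sires are the top-GEBV males of the current cohort (male selection rate
#' n_sires / cohort males).  Dams are all current-cohort females plus the
#' top-GEBV previously used dams, up to \code{n_dams} in total; dams that
#' have already bred \code{dam_reuse_generations} times are excluded.
#'
#' @param males,females current-cohort ids by sex.
#' @param prev_dams ids of the previous generation's dams.
#' @param gebv named GEBV vector covering all of the above ids.
#' @param n_sires,n_dams breeder counts.
#' @param dam_uses named integer vector: breeding generations already served
#'   per previous dam.
#' @param dam_reuse_generations maximum generations a dam may breed.
#' @return list with \code{sires} and \code{dams} id vectors.
#' @export
select_breeders <- function(males, females, prev_dams, gebv,
                            n_sires, n_dams, dam_uses = NULL,
                            dam_reuse_generations = 2) {
  if (length(males) < n_sires)
    stop("select_breeders: not enough male candidates", call. = FALSE)
  gm <- gebv[as.character(males)]
  sires <- males[order(-gm, seq_along(males))][seq_len(n_sires)]
  new_dams <- females
  n_keep <- n_dams - length(new_dams)
  if (n_keep < 0) {
    gf <- gebv[as.character(females)]
    new_dams <- females[order(-gf, seq_along(females))][seq_len(n_dams)]
    n_keep <- 0
  }
  kept <- integer(0)
  if (n_keep > 0) {
    eligible <- prev_dams
    if (!is.null(dam_uses))
      eligible <- prev_dams[dam_uses[as.character(prev_dams)] <
                              dam_reuse_generations]
    if (length(eligible) < n_keep) {
      # stochastic sex draws can leave too few reusable dams; top up with
      # the best over-cap dams rather than shrinking the dam herd
      extra <- setdiff(prev_dams, eligible)
      if (length(eligible) + length(extra) < n_keep)
        stop("select_breeders: not enough dams", call. = FALSE)
      message("select_breeders: reuse cap relaxed for ",
              n_keep - length(eligible), " dam(s)")
      ge <- gebv[as.character(extra)]
      extra <- extra[order(-ge, seq_along(extra))]
      eligible <- c(eligible, extra[seq_len(n_keep - length(eligible))])
    }
    ge <- gebv[as.character(eligible)]
    kept <- eligible[order(-ge, seq_along(eligible))][seq_len(n_keep)]
  }
  list(sires = sires, dams = c(new_dams, kept))
}

# initialize one replicate: founders, calibrated trait, initial reference of
# phenotyped ancestral males, first GBLUP fit, kinship bookkeeping
init_scheme_state <- function(config, strategy, replicate = 1L, seed = 1L) {
  genome <- config$genome
  pop <- simulate_founders(genome, config$n_founder_males,
                           config$n_founder_females,
                           config$n_burnin_generations, config$burnin_size,
                           seed = derive_seed(seed, replicate, 11))
  set.seed(derive_seed(seed, replicate, 12))
  trait0 <- trait_model(stats::rnorm(length(genome$qtl_idx)),
                        config$sigma2_g, config$sigma2_e)
  trait <- assign_trait(pop, trait0, rescale = TRUE)
  pop$tbv <- compute_tbv(pop, trait)
  ref_ids <- pop$id[pop$sex == "M"]
  set.seed(derive_seed(seed, replicate, 13))
  pop <- add_phenotypes(pop, trait, ref_ids)
  X <- marker_dosages(pop)
  p0 <- colMeans(X) / 2
  keep <- p0 > 0 & p0 < 1                 # drop markers fixed in founders
  X <- X[, keep, drop = FALSE]
  p0 <- p0[keep]
  denom <- 2 * sum(p0 * (1 - p0))
  Zref <- sweep(X[as.character(ref_ids), , drop = FALSE], 2, 2 * p0)
  Gref <- new_gmatrix(tcrossprod(Zref) / denom, "vanraden",
                      as.character(ref_ids))
  fit <- fit_gblup(Gref, pop$phenotype[ref_ids], pop$weight[ref_ids],
                   config$sigma2_g, config$sigma2_e, config$ridge)
  gebv <- rep(NA_real_, pop_size(pop))
  Fped <- rep(0, pop_size(pop))           # founders: no known parents
  Aset <- pop$id
  A <- diag(length(Aset))                 # founders treated as unrelated
  list(pop = pop, trait = trait, config = config, strategy = strategy,
       replicate = replicate, seed = seed,
       p0 = p0, denom = denom, marker_keep = keep,
       ref_ids = ref_ids, Zref = Zref, Gref = Gref, fit = fit,
       gebv = gebv, Fped = Fped, Aset = Aset, A = A,
       prev_dams = integer(0), dam_uses = integer(0),
       gen = 1L, metrics = list())
}

# centred marker rows for the two G constructions, restricted to the
# founder-segregating marker set
z_rows <- function(state, ids) {
  X <- marker_dosages(state$pop, ids)[, state$marker_keep, drop = FALSE]
  sweep(X, 2, 2 * state$p0)
}
m_rows <- function(state, ids) {
  marker_dosages(state$pop, ids)[, state$marker_keep, drop = FALSE] - 1
}

#' Advance the breeding scheme by one generation
#'
#' One pass of the selection loop: predict cohort GEBVs from the current
#' reference, update the reference with \code{update_size} cohort members
#' according to the strategy (from generation 2 onward), refit GBLUP on the
#' enlarged reference, re-predict the cohort, select breeders, mate sires to
#' dams at random (each dam once, sires reused at most
#' ceiling(n_dams/n_sires) times), produce one offspring per dam with a
#' Bernoulli(sex_ratio) sex draw, and record the per-generation metrics on
#' the breeding population.
#'
#' @param state scheme state from \code{init_scheme_state} or a previous
#'   call.
#' @return the advanced state, with one metrics row appended.
#' @export
run_generation <- function(state) {
  cfg <- state$config
  pop <- state$pop
  g <- state$gen
  set.seed(derive_seed(state$seed, state$replicate, 20, g))
  cohort <- pop$id[pop$generation == g - 1L]
  # GEBVs of the cohort from the reference as of entry
  in_ref <- cohort %in% state$ref_ids
  gebv_cohort <- numeric(length(cohort))
  if (any(in_ref))
    gebv_cohort[in_ref] <- state$fit$gebv[as.character(cohort[in_ref])]
  if (any(!in_ref)) {
    Zc <- z_rows(state, cohort[!in_ref])
    Gcross <- tcrossprod(Zc, state$Zref) / state$denom
    colnames(Gcross) <- state$fit$ids
    gebv_cohort[!in_ref] <- predict_candidates(state$fit, Gcross)
  }
  # reference update (from generation 2 onward)
  if (g >= 2L) {
    cand <- cohort
    Mc <- m_rows(state, cand)
    Gsim <- new_gmatrix(tcrossprod(Mc) * (2 / ncol(Mc)), "similarity",
                        as.character(cand))
    # baseline on the scale of G: group coancestry of the current cohort
    # under uniform contributions, mean(G)/2
    f_cur <- max(0, min(mean(unclass(Gsim)) / 2, 1 - 1e-9))
    oc_par <- oc_params(cfg$deltaF_max, f_cur)
    newref <- update_reference(state$ref_ids, cand, gebv_cohort, Gsim,
                               strategy = state$strategy,
                               update_size = cfg$ref_update_size,
                               oc_par = oc_par)
    added <- attr(newref, "added")
    pop <- add_phenotypes(pop, state$trait, added)
    state$pop <- pop
    # grow the VanRaden reference G with the new block
    Znew <- z_rows(state, added)
    B <- tcrossprod(Znew, state$Zref) / state$denom
    C <- tcrossprod(Znew) / state$denom
    Gref <- rbind(cbind(unclass(state$Gref), t(B)), cbind(B, C))
    state$ref_ids <- c(state$ref_ids, added)
    ids_chr <- as.character(state$ref_ids)
    Gref <- new_gmatrix(Gref, "vanraden", ids_chr)
    state$Zref <- rbind(state$Zref, Znew)
    rownames(state$Zref) <- ids_chr
    state$Gref <- Gref
    state$fit <- fit_gblup(Gref, pop$phenotype[state$ref_ids],
                           pop$weight[state$ref_ids],
                           cfg$sigma2_g, cfg$sigma2_e, cfg$ridge)
    # re-predict the cohort from the updated reference
    in_ref <- cohort %in% state$ref_ids
    gebv_cohort[in_ref] <- state$fit$gebv[as.character(cohort[in_ref])]
    if (any(!in_ref)) {
      Zc <- z_rows(state, cohort[!in_ref])
      Gcross <- tcrossprod(Zc, state$Zref) / state$denom
      colnames(Gcross) <- state$fit$ids
      gebv_cohort[!in_ref] <- predict_candidates(state$fit, Gcross)
    }
  }
  state$gebv[cohort] <- gebv_cohort
  # breeder selection
  males <- cohort[pop$sex[cohort] == "M"]
  females <- cohort[pop$sex[cohort] == "F"]
  gebv_named <- state$gebv
  names(gebv_named) <- as.character(pop$id)
  if (g == 1L) {
    gf <- gebv_named[as.character(females)]
    breeders <- list(
      sires = males[order(-gebv_named[as.character(males)],
                          seq_along(males))][seq_len(cfg$n_sires)],
      dams = females[order(-gf, seq_along(females))][seq_len(cfg$n_dams)])
  } else {
    breeders <- select_breeders(males, females, state$prev_dams, gebv_named,
                                cfg$n_sires, cfg$n_dams, state$dam_uses,
                                cfg$dam_reuse_generations)
  }
  sires <- breeders$sires; dams <- breeders$dams
  # mating: each dam once; sires used at most ceiling(n_dams/n_sires) times
  n_off <- length(dams) * cfg$offspring_per_dam
  sire_pool <- rep(sires, length.out = max(n_off, length(sires)))
  sire_draw <- sample(sire_pool)[seq_len(n_off)]
  dam_draw <- rep(dams, each = cfg$offspring_per_dam)
  sexes <- ifelse(stats::runif(n_off) < cfg$sex_ratio, "M", "F")
  pop <- breed_batch(state$pop, sire_draw, dam_draw, sexes, g, state$trait)
  off <- pop$id[pop$generation == g]
  state$pop <- pop
  # pedigree kinship bookkeeping over (cohort + previous dams) -> offspring
  ai <- match(sire_draw, state$Aset)
  bi <- match(dam_draw, state$Aset)
  Foff <- 0.5 * state$A[cbind(ai, bi)]
  state$Fped <- c(state$Fped, Foff)
  A_new <- kinship_advance(state$A, state$Aset, off, sire_draw, dam_draw,
                           Foff, dams)
  state$A <- A_new$A
  state$Aset <- A_new$ids
  # metrics on the breeding population
  bpop <- c(sires, dams)
  sdG <- stats::sd(pop$tbv[cohort])
  bias <- if (sdG > 0)
    prediction_bias(gebv_cohort, pop$tbv[cohort], sdG)$mean else NA_real_
  f_ref <- mean(state$Fped[state$ref_ids])
  ne <- if (f_ref > 0) 1 / (2 * f_ref) else NA_real_
  state$metrics[[length(state$metrics) + 1]] <- data.frame(
    replicate = state$replicate, generation = g, strategy = state$strategy,
    mean_bv = mean(pop$tbv[bpop]),
    mean_het = observed_heterozygosity(marker_dosages(pop, bpop))$mean,
    mean_f = mean(state$Fped[bpop]),
    mean_bias = bias, ne = ne, ne_over_n = ne / length(state$ref_ids),
    ref_size = length(state$ref_ids))
  # advance dam bookkeeping
  uses <- state$dam_uses
  new_uses <- stats::setNames(rep(0L, length(dams)), as.character(dams))
  known <- as.character(dams)[as.character(dams) %in% names(uses)]
  new_uses[known] <- uses[known]
  state$dam_uses <- new_uses + 1L
  state$prev_dams <- dams
  state$gen <- g + 1L
  state
}

# advance the additive-relationship block from parents to (offspring + kept
# dams); parents must all be inside the tracked set
kinship_advance <- function(A, ids, off, sires, dams_of_off, Foff, kept) {
  si <- match(sires, ids); di <- match(dams_of_off, ids)
  P <- 0.5 * (A[si, , drop = FALSE] + A[di, , drop = FALSE])
  # offspring x offspring
  ki <- match(kept, ids)
  OO <- 0.5 * (P[, si, drop = FALSE] + P[, di, drop = FALSE])
  diag(OO) <- 1 + Foff
  OK <- P[, ki, drop = FALSE]
  KK <- A[ki, ki, drop = FALSE]
  Anew <- rbind(cbind(OO, OK), cbind(t(OK), KK))
  list(A = Anew, ids = c(off, kept))
}

#' Run a full multi-replicate breeding scenario
#'
#' Runs \code{n_replicates} independent replicates of the
#' \code{n_generations}-generation selection scheme under one reference
#' updating strategy and returns the tidy per-(replicate, generation)
#' metrics table.
#'
#' @param config a \code{\link{scheme_config}}.
#' @param strategy "random", "truncation" or "oc" (or a
#'   \code{\link{strategy_config}}).
#' @param seed root seed; replicate r uses a stream derived from
#'   (seed, r).
#' @param verbose print per-replicate progress.
#' @return an object of class \code{gs_scenario}: the metrics data.frame
#'   (replicate, generation, strategy, mean_bv, mean_het, mean_f, mean_bias,
#'   ne, ne_over_n, ref_size) with the config attached.
#' @export
run_scenario <- function(config = scheme_config(), strategy = "random",
                         seed = 1, verbose = FALSE) {
  if (inherits(strategy, "strategy_config")) {
    config$ref_update_size <- strategy$update_size
    config$deltaF_max <- strategy$oc$deltaF_max
    strategy <- strategy$strategy
  }
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    state <- init_scheme_state(config, strategy, replicate = r, seed = seed)
    for (g in seq_len(config$n_generations)) state <- run_generation(state)
    out[[r]] <- do.call(rbind, state$metrics)
    if (verbose)
      message(sprintf("replicate %d/%d done (final mean BV %.1f)",
                      r, config$n_replicates,
                      out[[r]]$mean_bv[nrow(out[[r]])]))
  }
  structure(list(metrics = do.call(rbind, out), config = config,
                 strategy = strategy, seed = seed),
            class = "gs_scenario")
}

#' @export
print.gs_scenario <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Genomic selection scenario: strategy '%s', %d replicates x %d generations\n",
              x$strategy, length(unique(m$replicate)),
              max(m$generation)))
  last <- m[m$generation == max(m$generation), ]
  cat(sprintf("  generation %d means: BV %.1f, het %.4f, F %.4f, bias %.3f\n",
              max(m$generation), mean(last$mean_bv), mean(last$mean_het),
              mean(last$mean_f), mean(last$mean_bias)))
  invisible(x)
}

#' @export
summary.gs_scenario <- function(object, ...) {
  tr <- estimate_trends(object$metrics)
  structure(list(strategy = object$strategy, trends = tr,
                 n_replicates = length(unique(object$metrics$replicate))),
            class = "summary.gs_scenario")
}

#' @export
print.summary.gs_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d replicates): per-generation trends\n",
              x$strategy, x$n_replicates))
  print(x$trends, row.names = FALSE)
  invisible(x)
}

#' @export
plot.gs_scenario <- function(x, metric = "mean_bv", ...) {
  m <- x$metrics
  gens <- sort(unique(m$generation))
  avg <- tapply(m[[metric]], m$generation, mean, na.rm = TRUE)
  graphics::plot(gens, avg, type = "b", xlab = "generation",
                 ylab = metric,
                 main = sprintf("strategy %s", x$strategy), ...)
  invisible(x)
}

#' Single-generation reference update experiment
#'
#' The three-cohort experiment: fit GBLUP on the initial reference A1,
#' predict the candidate cohort A2, choose an update group per strategy and
#' size, refit on the enlarged reference, predict the validation cohort V,
#' keep the top \code{top_n} by GEBV as the selected breeding group, and
#' evaluate its mean breeding value, heterozygosity, pedigree inbreeding
#' (when a pedigree is supplied) and prediction bias.  The random strategy
#' is repeated \code{n_random} times with distinct seeds.
#'
#' @param genotypes dosage matrix over all individuals (rows named by id).
#' @param phenotypes named phenotype vector covering A1 and A2.
#' @param splits list with id vectors \code{A1}, \code{A2}, \code{V}
#'   (disjoint).
#' @param bv named true/multi-record breeding values for V.
#' @param sizes update group sizes (default 100, 200, 500, 1000, 2000).
#' @param strategies subset of c("random", "truncation", "oc").
#' @param top_n size of the selected group from V (default 100).
#' @param n_random repetitions of the random strategy (default 100).
#' @param weights named record weights (default 1).
#' @param ped optional pedigree data.frame for inbreeding of the selected
#'   group.
#' @param sigma2_g,sigma2_e fixed variance components.
#' @param oc_par \code{\link{oc_params}} for the oc strategy.
#' @param ridge GBLUP ridge.
#' @param seed root seed.
#' @return data.frame (strategy, size, rep, mean_bv, mean_bias, mean_het,
#'   mean_f).
#' @export
run_update_experiment <- function(genotypes, phenotypes, splits, bv,
                                  sizes = c(100, 200, 500, 1000, 2000),
                                  strategies = c("random", "truncation", "oc"),
                                  top_n = 100, n_random = 100,
                                  weights = NULL, ped = NULL,
                                  sigma2_g = 423390, sigma2_e = 987910,
                                  oc_par = oc_params(), ridge = 1e-2,
                                  seed = 1) {
  ids <- rownames(genotypes)
  A1 <- as.character(splits$A1); A2 <- as.character(splits$A2)
  V <- as.character(splits$V)
  if (length(intersect(A1, A2)) || length(intersect(A1, V)) ||
      length(intersect(A2, V)))
    stop("run_update_experiment: A1/A2/V must be disjoint", call. = FALSE)
  stopifnot(all(c(A1, A2, V) %in% ids))
  if (any(sizes > length(A2)))
    stop("run_update_experiment: update size exceeds candidate count",
         call. = FALSE)
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(phenotypes)), names(phenotypes))
  G <- vanraden_grm(genotypes)
  Gsim_A2 <- similarity_grm(genotypes[A2, , drop = FALSE])
  f_all <- if (!is.null(ped)) pedigree_inbreeding(ped) else NULL
  fit1 <- fit_gblup(G[A1, A1], phenotypes[A1], weights[A1],
                    sigma2_g, sigma2_e, ridge)
  gebv_A2 <- predict_candidates(fit1, G[A2, A1, drop = FALSE])
  eval_one <- function(strategy, size, rep_i, rng_seed) {
    set.seed(rng_seed)
    newref <- update_reference(A1, A2, gebv_A2, Gsim_A2,
                               strategy = strategy, update_size = size,
                               oc_par = oc_par)
    fit2 <- fit_gblup(G[newref, newref], phenotypes[newref],
                      weights[newref], sigma2_g, sigma2_e, ridge)
    gebv_V <- predict_candidates(fit2, G[V, newref, drop = FALSE])
    vsel <- V[order(-gebv_V, seq_along(V))][seq_len(min(top_n, length(V)))]
    sdG <- stats::sd(bv[vsel])
    data.frame(
      strategy = strategy, size = size, rep = rep_i,
      mean_bv = mean(bv[vsel]),
      mean_bias = if (is.finite(sdG) && sdG > 0)
        prediction_bias(gebv_V[vsel], bv[vsel], sdG)$mean else NA_real_,
      mean_het = observed_heterozygosity(
        genotypes[vsel, , drop = FALSE])$mean,
      mean_f = if (!is.null(f_all)) mean(f_all[vsel]) else NA_real_)
  }
  rows <- list()
  for (size in sizes) for (strategy in strategies) {
    reps <- if (strategy == "random") seq_len(n_random) else 1L
    for (r in reps)
      rows[[length(rows) + 1]] <- eval_one(strategy, size, r,
                                           derive_seed(seed, size, r,
                                                       match(strategy,
                                                             strategies)))
  }
  do.call(rbind, rows)
}
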