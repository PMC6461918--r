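# Forward-in-time breeding simulation: founder construction, meiosis,
# two-trait QTL architecture, phenotype generation, GBLUP prediction, and the
# competing multi-trait breeding strategies.

#' Simulation configuration
#'
#' Defaults reproduce the simulation design of the comparison study: two fully
#' inbred complementary founders, 1000 SNPs on each of 3 chromosomes of 1
#' Morgan, a population of size N carried through 100 generations of random
#' mating, two traits controlled by 200 QTL per chromosome of which 100 have
#' their trait-2 sign forced opposite to trait-1 (yielding negatively
#' correlated traits), heritability 0.5 per trait held constant across cycles,
#' a base population built by 10 rounds of phenotypic tandem selection at 50%
#' intensity, and 16 genomic (10 phenotypic) selection cycles.
#'
#' @param pop_size population size N (>= 4; the study used 100-400).
#' @param n_markers_per_chrom,n_chrom,n_qtl_per_chrom,n_opposite_sign marker
#'   and QTL architecture counts.
#' @param h2 per-trait heritability maintained each cycle.
#' @param burnin_random_mating random-mating generations after founding.
#' @param base_tandem_rounds,base_selection_intensity base-population build.
#' @param n_cycles_gs,n_cycles_ps selection cycles for genomic / phenotypic
#'   strategies.
#' @param chrom_length_morgans genetic length of each chromosome.
#' @return List of class \code{SimulationConfig}.
#' @export
sim_config <- function(pop_size = 100, n_markers_per_chrom = 1000, n_chrom = 3,
                       n_qtl_per_chrom = 200, n_opposite_sign = 100, h2 = 0.5,
                       burnin_random_mating = 100, base_tandem_rounds = 10,
                       base_selection_intensity = 0.5, n_cycles_gs = 16,
                       n_cycles_ps = 10, chrom_length_morgans = 1) {
  cfg <- list(pop_size = pop_size, n_markers_per_chrom = n_markers_per_chrom,
              n_chrom = n_chrom, n_qtl_per_chrom = n_qtl_per_chrom,
              n_opposite_sign = n_opposite_sign, h2 = h2,
              burnin_random_mating = burnin_random_mating,
              base_tandem_rounds = base_tandem_rounds,
              base_selection_intensity = base_selection_intensity,
              n_cycles_gs = n_cycles_gs, n_cycles_ps = n_cycles_ps,
              chrom_length_morgans = chrom_length_morgans)
  if (cfg$pop_size < 4) .stopf("pop_size must be at least 4")
  if (cfg$n_opposite_sign > cfg$n_qtl_per_chrom)
    .stopf("n_opposite_sign cannot exceed n_qtl_per_chrom")
  if (!(cfg$h2 > 0 && cfg$h2 < 1)) .stopf("h2 must be in (0, 1)")
  if (!(cfg$base_selection_intensity > 0 && cfg$base_selection_intensity <= 1))
    .stopf("base_selection_intensity must be in (0, 1]")
  structure(cfg, class = "SimulationConfig")
}

#' Breeding strategy configuration
#'
#' @param strategy one of \code{"tandem"}, \code{"culling"}, \code{"index"},
#'   \code{"nondominated"}, \code{"moob_pp_eq1"}, \code{"moob_pp_eq2"},
#'   \code{"genomic_mating"}.
#' @param genomic logical; use GEBVs (genomic selection) rather than
#'   phenotypes as the selection criterion. Required TRUE for the
#'   multi-objective strategies. Phenotypic variants of tandem/culling/index
#'   use no genotypic information.
#' @param index_weights trait weights for index selection (default equal 0.5).
#' @param culling_quantiles per-trait culling threshold quantiles (default
#'   0.4; thresholds are jointly relaxed until at least 2 survivors remain).
#' @param decision_weights global-criterion weights over the frontier
#'   objectives in objective order (k gains, then co-ancestry). Default
#'   places 0.95 on co-ancestry and 0.025 on each gain for populations up to
#'   200 (0.9 / 0.05 / 0.05 for larger populations), matching the simulation
#'   protocol.
#' @param selection_fraction truncation fraction for the classical strategies.
#' @param frontier_resolution lattice resolution for [trace_frontier()] inside
#'   the simulator (default 11; see the methods vignette).
#' @param n_crosses crosses per plan for the genomic-mating strategy (default
#'   pop_size / 5, set at run time when NULL).
#' @param gm_opts search options for [search_mating_frontier()].
#' @return List of class \code{StrategyConfig}.
#' @export
strategy_config <- function(strategy = c("tandem", "culling", "index",
                                         "nondominated", "moob_pp_eq1",
                                         "moob_pp_eq2", "genomic_mating"),
                            genomic = TRUE, index_weights = NULL,
                            culling_quantiles = 0.4, decision_weights = NULL,
                            selection_fraction = 0.5,
                            frontier_resolution = 11, n_crosses = NULL,
                            gm_opts = list(pop_size = 40, generations = 40)) {
  strategy <- match.arg(strategy)
  needs_genomic <- strategy %in% c("nondominated", "moob_pp_eq1",
                                   "moob_pp_eq2", "genomic_mating")
  if (needs_genomic && !genomic)
    .stopf("strategy '%s' requires genomic = TRUE", strategy)
  structure(list(strategy = strategy, genomic = genomic,
                 index_weights = index_weights,
                 culling_quantiles = culling_quantiles,
                 decision_weights = decision_weights,
                 selection_fraction = selection_fraction,
                 frontier_resolution = frontier_resolution,
                 n_crosses = n_crosses, gm_opts = gm_opts),
            class = "StrategyConfig")
}

# ---- meiosis -----------------------------------------------------------

# precompute chromosome geometry from a map data frame
.map_geometry <- function(map) {
  chroms <- unique(map$chrom)
  idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  pos <- lapply(idx, function(ii) map$pos[ii])
  len <- vapply(pos, function(p) max(p), 0)
  list(chroms = chroms, idx = idx, pos = pos, len = len, n = nrow(map))
}

# one gamete from a parent's two haplotype vectors: Poisson crossovers
# (no interference), uniform positions, random starting haplotype
.make_gamete <- function(h1, h2, geo) {
  g <- h1
  for (c in seq_along(geo$idx)) {
    ii <- geo$idx[[c]]
    L <- geo$len[c]
    start <- rbinom(1L, 1L, 0.5)
    k <- if (L > 0) rpois(1L, L) else 0L
    if (k == 0L) {
      if (start == 1L) g[ii] <- h2[ii]
    } else {
      seg <- findInterval(geo$pos[[c]], sort(runif(k, 0, L)))
      use2 <- (seg + start) %% 2L == 1L
      gi <- h1[ii]
      gi[use2] <- h2[ii][use2]
      g[ii] <- gi
    }
  }
  g
}

#' Simulate meiosis and form an offspring genome
#'
#' Produces one offspring from two parents: one recombinant gamete per parent,
#' with crossover counts Poisson-distributed with mean equal to the
#' chromosome's genetic length in Morgans, crossover positions uniform, and no
#' interference (Haldane model).
#'
#' @param parent_a,parent_b parental genomes: lists with haplotype vectors
#'   \code{h1}, \code{h2} (0/1 allele codes over all markers).
#' @param map data frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   (Morgans).
#' @param seed optional integer seed.
#' @return Offspring genome: list with \code{h1} (gamete from parent a) and
#'   \code{h2} (gamete from parent b).
#' @export
meiosis <- function(parent_a, parent_b, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geo <- .map_geometry(as.data.frame(map))
  list(h1 = .make_gamete(parent_a$h1, parent_a$h2, geo),
       h2 = .make_gamete(parent_b$h1, parent_b$h2, geo))
}

# population container: h1, h2 are m x n 0/1 matrices
.pop_dosages <- function(pop) pop$h1 + pop$h2

# produce N offspring given per-offspring parent index pairs
.offspring <- function(pop, geo, pa, pb) {
  n <- ncol(pop$h1)
  N <- length(pa)
  h1 <- matrix(0, N, n); h2 <- matrix(0, N, n)
  for (i in seq_len(N)) {
    h1[i, ] <- .make_gamete(pop$h1[pa[i], ], pop$h2[pa[i], ], geo)
    h2[i, ] <- .make_gamete(pop$h1[pb[i], ], pop$h2[pb[i], ], geo)
  }
  list(h1 = h1, h2 = h2)
}

# ---- founders and state ------------------------------------------------

.state_tbv <- function(pop, arch) {
  (pop$h1[, arch$qtl, drop = FALSE] + pop$h2[, arch$qtl, drop = FALSE]) %*% arch$beta
}

# recompute true values and phenotypes, recalibrating environmental noise so
# the realized heritability stays at h2
.state_refresh <- function(state) {
  state$tbv <- .state_tbv(state$pop, state$arch)
  vg <- apply(state$tbv, 2, var)
  sd_e <- sqrt(pmax(vg, 0) * (1 - state$h2) / state$h2)
  state$arch$environmental_sd <- sd_e
  N <- nrow(state$tbv)
  state$phenotypes <- state$tbv +
    sapply(seq_along(sd_e), function(t) rnorm(N, 0, sd_e[t]))
  state
}

.state_genotypes <- function(state) {
  genotype_matrix(`rownames<-`(.pop_dosages(state$pop),
                               paste0("ind", seq_len(nrow(state$pop$h1)))),
                  map = state$map)
}

# mean inbreeding relative to the reference (base) allele frequencies
.state_inbreeding <- function(state) {
  if (is.null(state$ref_freq)) return(NA_real_)
  Z <- sweep(.pop_dosages(state$pop), 2, 2 * state$ref_freq, "-")
  mean(rowSums(Z^2) / state$ref_denom) - 1
}

.state_stats <- function(state, cycle) {
  vg <- apply(state$tbv, 2, var)
  vp <- apply(state$phenotypes, 2, var)
  data.frame(cycle = cycle,
             mean_trait1 = mean(state$tbv[, 1]), mean_trait2 = mean(state$tbv[, 2]),
             var_trait1 = vg[1], var_trait2 = vg[2],
             h2_trait1 = ifelse(vp[1] > 0, vg[1] / vp[1], NA),
             h2_trait2 = ifelse(vp[2] > 0, vg[2] / vp[2], NA),
             inbreeding = .state_inbreeding(state))
}

#' Build the founder population
#'
#' Starting from two fully inbred, complementary founder genotypes, forms a
#' population of N genotypes (initially all F1) and carries it through the
#' configured number of random-mating generations. Two-trait QTL effects are
#' then attached: per-trait effects are standard normal at the sampled QTL,
#' and at the designated subset of loci per chromosome the trait-2 effect sign
#' is forced opposite to trait-1's, making the traits negatively correlated.
#' Environmental noise is calibrated so each trait's realized heritability is
#' h2 (noise variance equal to the genotypic variance when h2 = 0.5).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return Object of class \code{BreedingState}: population haplotypes, map,
#'   trait architecture, true breeding values, phenotypes.
#' @export
make_founders <- function(cfg = sim_config(), seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_markers_per_chrom * cfg$n_chrom
  map <- data.frame(
    marker = paste0("m", seq_len(n)),
    chrom = rep(seq_len(cfg$n_chrom), each = cfg$n_markers_per_chrom),
    pos = as.numeric(vapply(seq_len(cfg$n_chrom), function(i)
      sort(runif(cfg$n_markers_per_chrom, 0, cfg$chrom_length_morgans)),
      numeric(cfg$n_markers_per_chrom))))
  geo <- .map_geometry(map)
  N <- cfg$pop_size
  pop <- list(h1 = matrix(0, N, n), h2 = matrix(1, N, n))
  for (g in seq_len(cfg$burnin_random_mating)) {
    pa <- sample.int(N, N, replace = TRUE)
    pb <- sample.int(N, N, replace = TRUE)
    pop <- .offspring(pop, geo, pa, pb)
  }
  # trait architecture: per-chromosome QTL with partially antagonistic effects
  qtl <- integer(0); opp <- integer(0)
  for (c in seq_len(cfg$n_chrom)) {
    loci <- sort(sample(geo$idx[[c]], cfg$n_qtl_per_chrom))
    qtl <- c(qtl, loci)
    opp <- c(opp, sample(loci, cfg$n_opposite_sign))
  }
  b1 <- rnorm(length(qtl))
  b2 <- rnorm(length(qtl))
  flip <- qtl %in% opp
  b2[flip] <- -sign(b1[flip]) * abs(b2[flip])
  arch <- list(qtl = qtl, opposite = sort(opp),
               beta = cbind(trait1 = b1, trait2 = b2))
  state <- structure(list(pop = pop, map = map, geo = geo, arch = arch,
                          h2 = cfg$h2, cycle = 0L,
                          ref_freq = NULL, ref_denom = NULL),
                     class = "BreedingState")
  .state_refresh(state)
}

#' @export
print.BreedingState <- function(x, ...) {
  cat(sprintf("BreedingState: %d individuals, %d markers, %d QTL, cycle %d\n",
              nrow(x$pop$h1), ncol(x$pop$h1), length(x$arch$qtl), x$cycle))
  invisible(x)
}

#' Build the base breeding population
#'
#' Applies the configured rounds of phenotypic tandem selection (alternating
#' traits, truncation at the configured intensity) to a founder state, then
#' freezes the base allele frequencies used as the reference for inbreeding
#' tracking.
#'
#' @param state a [make_founders()] state.
#' @param cfg the [sim_config()] used to create it.
#' @return A \code{BreedingState}.
#' @export
make_base_population <- function(state, cfg) {
  N <- nrow(state$pop$h1)
  for (r in seq_len(cfg$base_tandem_rounds)) {
    trait <- (r - 1L) %% ncol(state$phenotypes) + 1L
    cvec <- .truncation_weights(state$phenotypes[, trait],
                                cfg$base_selection_intensity)
    pa <- sample.int(N, N, replace = TRUE, prob = cvec)
    pb <- sample.int(N, N, replace = TRUE, prob = cvec)
    state$pop <- .offspring(state$pop, state$geo, pa, pb)
    state <- .state_refresh(state)
  }
  p <- colMeans(.pop_dosages(state$pop)) / 2
  state$ref_freq <- p
  state$ref_denom <- 2 * sum(p * (1 - p))
  state$cycle <- 0L
  state
}

# uniform weights on the top fraction by criterion (ties broken by order)
.truncation_weights <- function(crit, fraction) {
  m <- length(crit)
  n_sel <- max(2L, floor(m * fraction + 1e-9))
  sel <- order(crit, decreasing = TRUE)[seq_len(n_sel)]
  w <- numeric(m); w[sel] <- 1 / n_sel
  w
}

# ---- genomic prediction ------------------------------------------------

#' GBLUP prediction of breeding values
#'
#' Per-trait genomic BLUP on the current population: with genomic relationship
#' matrix K and shrinkage lambda = (1 - h2)/h2, GEBVs are
#' K (K + lambda I)^{-1} (y - ybar) + ybar-centering removed (values are
#' returned centered on the training mean as deviations). The fitted model is
#' attached as attribute \code{"model"}; [predict_gebv_new()] applies it to
#' new genotypes through the cross-relationship matrix (so even-numbered
#' cycles can be predicted from the model trained at the previous odd cycle).
#' The genetic correlation between traits is re-estimated from the GEBVs
#' (moment estimator) and attached as attribute \code{"psi"}.
#'
#' @param training a \code{BreedingState} (or a list with \code{dosages} and
#'   \code{phenotypes} matrices).
#' @param h2_assumed assumed heritability controlling shrinkage.
#' @return A [breeding_values()] object for the training individuals, with
#'   attributes \code{"model"} and \code{"psi"}.
#' @export
predict_gebv <- function(training, h2_assumed = 0.5) {
  if (inherits(training, "BreedingState")) {
    M <- .pop_dosages(training$pop); Y <- training$phenotypes
  } else {
    M <- training$dosages; Y <- training$phenotypes
  }
  if (is.null(Y)) .stopf("phenotypes are required to train the predictor")
  h2 <- min(max(h2_assumed, 1e-6), 1 - 1e-9)
  lambda <- (1 - h2) / h2
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) .stopf("all markers monomorphic in the training set")
  Z <- sweep(M, 2, 2 * p, "-")
  K <- tcrossprod(Z) / denom
  m <- nrow(K)
  LHS <- K + diag(lambda + 1e-8, m)
  ymean <- colMeans(Y)
  alpha <- solve(LHS, sweep(Y, 2, ymean, "-"))
  gebv <- K %*% alpha
  colnames(gebv) <- colnames(Y) %||% paste0("trait", seq_len(ncol(Y)))
  sds <- apply(gebv, 2, sd)
  psi <- if (all(sds > 0)) cor(gebv) else diag(ncol(gebv))
  model <- list(Z = Z, p = p, denom = denom, alpha = alpha, ymean = ymean,
                lambda = lambda)
  out <- breeding_values(gebv, standardized = FALSE)
  attr(out, "model") <- model
  attr(out, "psi") <- psi
  out
}

#' Predict GEBVs of new genotypes from a trained GBLUP model
#'
#' @param model the \code{"model"} attribute of a [predict_gebv()] fit.
#' @param M_new dosage matrix of the new individuals (same markers).
#' @return Matrix of predicted breeding values (deviations from the training
#'   mean).
#' @export
predict_gebv_new <- function(model, M_new) {
  Zn <- sweep(M_new, 2, 2 * model$p, "-")
  Kc <- tcrossprod(Zn, model$Z) / model$denom
  Kc %*% model$alpha
}

# marker effects implied by the GBLUP fit (ridge-regression equivalence)
.model_marker_effects <- function(model) {
  t(model$Z) %*% model$alpha / model$denom
}

# ---- strategies --------------------------------------------------------

# z-score columns, mapping zero-variance columns to 0 (selection criteria
# only; the exported standardize() errors instead)
.safe_standardize <- function(V) {
  apply(V, 2, function(x) { s <- sd(x); if (s > 0) (x - mean(x)) / s else x * 0 })
}

#' Apply a breeding strategy to the current population
#'
#' Turns the current selection criterion values (GEBVs for genomic strategies,
#' phenotypes for phenotypic ones) into either a parental contribution vector
#' or, for the genomic-mating strategy, a mating plan.
#'
#' Strategies: \code{tandem} truncates on the trait indexed by cycle parity;
#' \code{culling} keeps individuals above every per-trait threshold quantile
#' (thresholds relaxed jointly until at least 2 survive), uniform weights;
#' \code{index} truncates on the weighted sum of standardized values;
#' \code{nondominated} applies [dominance_weights()] to the non-dominated
#' sort of the values; \code{moob_pp_eq1}/\code{moob_pp_eq2} trace the
#' contribution frontier and pick a solution by the weighted global criterion;
#' \code{genomic_mating} searches the mating-plan frontier and picks by the
#' global criterion.
#'
#' @param values numeric matrix of selection criterion values (individuals x
#'   traits).
#' @param scfg a [strategy_config()].
#' @param cycle 1-based cycle index (drives tandem's trait alternation).
#' @param A relationship matrix of the candidates (required for the
#'   multi-objective strategies).
#' @param psi genetic correlation estimate (for \code{moob_pp_eq2}).
#' @param effects [marker_effects()] estimate (for \code{genomic_mating}).
#' @param G [genotype_matrix()] of candidates (for \code{genomic_mating}).
#' @param haplotypes phased haplotypes (for \code{genomic_mating} with
#'   heterozygous candidates).
#' @return A [contribution_vector()] or a [mating_plan()].
#' @export
apply_strategy <- function(values, scfg, cycle = 1L, A = NULL, psi = NULL,
                           effects = NULL, G = NULL, haplotypes = NULL) {
  stopifnot(inherits(scfg, "StrategyConfig"))
  values <- as.matrix(values)
  m <- nrow(values); k <- ncol(values)
  frac <- scfg$selection_fraction
  switch(scfg$strategy,
    tandem = {
      trait <- (cycle - 1L) %% k + 1L
      contribution_vector(.truncation_weights(values[, trait], frac))
    },
    culling = {
      q <- rep_len(scfg$culling_quantiles, k)
      repeat {
        thr <- vapply(seq_len(k), function(t) quantile(values[, t], q[t]), 0)
        alive <- rowSums(sweep(values, 2, thr, ">=")) == k
        if (sum(alive) >= 2 || all(q <= 0)) break
        q <- pmax(q - 0.05, 0)
      }
      if (sum(alive) < 2) alive <- rep(TRUE, m)
      contribution_vector(alive / sum(alive))
    },
    index = {
      w <- scfg$index_weights %||% rep(1 / k, k)
      score <- as.numeric(.safe_standardize(values) %*% w)
      contribution_vector(.truncation_weights(score, frac))
    },
    nondominated = {
      srt <- nondominated_sort(values, maximize = TRUE)
      dominance_weights(srt, frac)
    },
    moob_pp_eq1 = ,
    moob_pp_eq2 = {
      if (is.null(A)) .stopf("relationship matrix required for %s", scfg$strategy)
      bv <- breeding_values(.safe_standardize(values))
      variant <- if (scfg$strategy == "moob_pp_eq2") "eq2" else "eq1"
      if (variant == "eq2") {
        psi <- psi %||% tryCatch(estimate_genetic_correlations(bv),
                                 error = function(e) diag(k))
        fac <- k - 2 * sum(psi[upper.tri(psi)])
        if (fac <= 0) variant <- "eq1"  # documented fallback
      }
      F <- trace_frontier(bv, A, variant = variant,
                          resolution = scfg$frontier_resolution,
                          psi = if (variant == "eq2") psi else NULL)
      w <- scfg$decision_weights %||%
        if (m <= 200) c(rep(0.025, k), 0.95) else c(rep(0.05, k), 0.9)
      select_by_global_criterion(F, w)$contribution
    },
    genomic_mating = {
      if (is.null(A) || is.null(effects) || is.null(G))
        .stopf("genotypes, marker effects and A are required for genomic mating")
      nc <- scfg$n_crosses %||% max(2L, round(m / 5))
      F <- search_mating_frontier(G, effects, A, n_crosses = nc,
                                  search_opts = c(scfg$gm_opts,
                                                  list(haplotypes = haplotypes)),
                                  seed = sample.int(.Machine$integer.max, 1))
      n_obj <- length(F$solutions[[1]]$objectives$values)
      w <- c(rep(0.05 / (n_obj - 1), n_obj - 1), 0.95)
      select_by_global_criterion(F, w)$plan
    })
}

# ---- breeding loop -----------------------------------------------------

#' Run one breeding program
#'
#' Runs the configured number of selection cycles from a base population. For
#' genomic strategies, GEBVs are trained by GBLUP on the current cycle's
#' phenotypes at odd-numbered cycles and, at even-numbered cycles, predicted
#' for the new genotypes from the model stored at the previous odd cycle
#' (genetic-correlation estimates are carried forward the same way). The next
#' generation is produced by sampling parent pairs proportional to the
#' contribution vector (or by allocating offspring equally across the crosses
#' of a mating plan) and applying the meiosis model. Heritability is held
#' constant by recalibrating the environmental noise each cycle.
#'
#' @param base a base \code{BreedingState} (see [make_base_population()]).
#' @param cfg a [sim_config()].
#' @param scfg a [strategy_config()].
#' @param seed integer seed.
#' @param n_cycles override for the number of cycles (defaults to
#'   \code{cfg$n_cycles_gs} or \code{cfg$n_cycles_ps} by strategy type).
#' @return Data frame trajectory with one row per completed cycle plus the
#'   base state (cycle 0): per-trait mean true breeding value, genetic
#'   variance, realized heritability, and mean inbreeding.
#' @export
run_breeding <- function(base, cfg, scfg, seed = 1L, n_cycles = NULL) {
  stopifnot(inherits(base, "BreedingState"), inherits(scfg, "StrategyConfig"))
  if (!is.null(seed)) set.seed(seed)
  n_cycles <- n_cycles %||% (if (scfg$genomic) cfg$n_cycles_gs else cfg$n_cycles_ps)
  state <- base
  traj <- .state_stats(state, 0L)
  model <- NULL; psi <- NULL
  needs_A <- scfg$strategy %in% c("moob_pp_eq1", "moob_pp_eq2", "genomic_mating")
  N <- nrow(state$pop$h1)
  for (cycle in seq_len(n_cycles)) {
    if (scfg$genomic) {
      if (cycle %% 2L == 1L || is.null(model)) {
        fit <- predict_gebv(state, h2_assumed = state$h2)
        model <- attr(fit, "model"); psi <- attr(fit, "psi")
        values <- fit$values
      } else {
        values <- predict_gebv_new(model, .pop_dosages(state$pop))
      }
    } else {
      values <- state$phenotypes
    }
    A <- if (needs_A) compute_relationship(.state_genotypes(state))$A else NULL
    eff <- if (scfg$strategy == "genomic_mating")
      marker_effects(.model_marker_effects(model)) else NULL
    act <- apply_strategy(values, scfg, cycle = cycle, A = A, psi = psi,
                          effects = eff,
                          G = if (scfg$strategy == "genomic_mating")
                            .state_genotypes(state) else NULL,
                          haplotypes = if (scfg$strategy == "genomic_mating")
                            state$pop else NULL)
    if (inherits(act, "MatingPlan")) {
      cr <- act$crosses
      reps <- rep(seq_len(nrow(cr)), cr$n)
      pick <- reps[(seq_len(N) - 1L) %% length(reps) + 1L]
      pa <- cr$parent_i[pick]; pb <- cr$parent_j[pick]
    } else {
      w <- act$c
      pa <- sample.int(N, N, replace = TRUE, prob = w)
      pb <- sample.int(N, N, replace = TRUE, prob = w)
    }
    state$pop <- .offspring(state$pop, state$geo, pa, pb)
    state <- .state_refresh(state)
    state$cycle <- cycle
    traj <- rbind(traj, .state_stats(state, cycle))
  }
  rownames(traj) <- NULL
  traj
}

#' Run a replicated strategy-comparison experiment
#'
#' For each replicate, builds an independent founder + base population and
#' runs every strategy from that identical base (each strategy with its own
#' derived seed). Reports per-strategy trajectory ensembles and final-cycle
#' standardized gains: per trait, (final mean true breeding value - base
#' mean) / base genetic standard deviation, and their sum ("combined gain").
#'
#' @param cfg a [sim_config()].
#' @param strategies character vector of strategy names, or a named list of
#'   [strategy_config()]s.
#' @param n_reps number of replicates.
#' @param seed master seed; all replicate and strategy seeds derive from it.
#' @return Object of class \code{BreedingExperiment}: \code{trajectories}
#'   (rep -> strategy -> data frame), \code{gains} (long data frame),
#'   \code{summary} (per strategy: mean and sd over reps of the combined and
#'   per-trait gains).
#' @export
run_experiment <- function(cfg, strategies, n_reps = 10, seed = 1L) {
  if (!is.list(strategies)) {
    strategies <- setNames(lapply(strategies, strategy_config), strategies)
  }
  if (is.null(names(strategies)))
    names(strategies) <- vapply(strategies, `[[`, "", "strategy")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, n_reps * (length(strategies) + 1)),
                  nrow = n_reps)
  trajectories <- vector("list", n_reps)
  gains <- NULL
  for (rep in seq_len(n_reps)) {
    founders <- make_founders(cfg, seed = seeds[rep, 1])
    base <- make_base_population(founders, cfg)
    base_mean <- colMeans(base$tbv)
    base_sd <- apply(base$tbv, 2, sd)
    trajectories[[rep]] <- list()
    for (s in seq_along(strategies)) {
      scfg <- strategies[[s]]
      traj <- run_breeding(base, cfg, scfg, seed = seeds[rep, s + 1])
      trajectories[[rep]][[names(strategies)[s]]] <- traj
      fin <- traj[nrow(traj), ]
      g1 <- (fin$mean_trait1 - base_mean[1]) / base_sd[1]
      g2 <- (fin$mean_trait2 - base_mean[2]) / base_sd[2]
      gains <- rbind(gains, data.frame(strategy = names(strategies)[s],
                                       rep = rep, gain_trait1 = g1,
                                       gain_trait2 = g2, combined = g1 + g2))
    }
  }
  agg <- do.call(rbind, lapply(split(gains, gains$strategy), function(d)
    data.frame(strategy = d$strategy[1],
               combined_mean = mean(d$combined), combined_sd = sd(d$combined),
               gain1_mean = mean(d$gain_trait1), gain2_mean = mean(d$gain_trait2),
               n_reps = nrow(d))))
  rownames(agg) <- NULL
  structure(list(trajectories = trajectories, gains = gains, summary = agg,
                 cfg = cfg, seed = seed),
            class = "BreedingExperiment")
}

#' @export
print.BreedingExperiment <- function(x, ...) {
  cat(sprintf("BreedingExperiment: %d strategies x %d reps (N = %d)\n",
              nrow(x$summary), max(x$gains$rep), x$cfg$pop_size))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Relative advantage of a strategy over the best competitor
#'
#' Percentage by which a focal strategy's mean final-cycle combined
#' standardized gain exceeds the best mean among the competitor strategies.
#'
#' @param experiment a [run_experiment()] result.
#' @param focal focal strategy name.
#' @param competitors competitor strategy names.
#' @return Scalar percentage margin (positive = focal ahead), with the
#'   competitor table attached as attribute \code{"details"}.
#' @export
strategy_margin <- function(experiment, focal,
                            competitors = c("tandem", "culling", "index",
                                            "nondominated")) {
  s <- experiment$summary
  foc <- s$combined_mean[s$strategy == focal]
  if (!length(foc)) .stopf("strategy '%s' not in experiment", focal)
  comp <- s[s$strategy %in% competitors, ]
  if (!nrow(comp)) .stopf("no competitor strategies found")
  best <- max(comp$combined_mean)
  margin <- 100 * (foc - best) / abs(best)
  attr(margin, "details") <- comp
  margin
}
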