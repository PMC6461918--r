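# Meiosis, founder construction, GBLUP, strategies, and the breeding loop.
# Tests run on scaled-down configurations (small populations, short burn-in);
# the full study-scale conditions are exercised in test-acceptance.R.

test_that("meiosis conserves parental alleles and respects trivial maps", {
  n <- 20
  map <- uniform_map(n)
  # identical fully inbred parents: offspring identical to them
  hap <- rep(c(0, 1), n / 2)
  off <- meiosis(list(h1 = hap, h2 = hap), list(h1 = hap, h2 = hap), map, seed = 1)
  expect_identical(off$h1, hap)
  expect_identical(off$h2, hap)
  # 0-Morgan chromosome: gamete is an intact parental haplotype
  map0 <- uniform_map(n); map0$pos <- 0
  pa <- list(h1 = rep(0, n), h2 = rep(1, n))
  for (s in 1:5) {
    off0 <- meiosis(pa, pa, map0, seed = s)
    expect_true(all(off0$h1 == 0) || all(off0$h1 == 1))
  }
  # allele provenance: every gamete allele equals one of the parent's alleles
  pa2 <- list(h1 = seq_len(n) * 10, h2 = seq_len(n) * 10 + 1)
  off2 <- meiosis(pa2, pa2, map, seed = 3)
  expect_true(all(off2$h1 == pa2$h1 | off2$h1 == pa2$h2))
})

test_that("recombination fraction at 10 cM follows the Haldane map function", {
  set.seed(14)
  n_gam <- 10000
  map <- data.frame(marker = c("a", "b"), chrom = 1, pos = c(0.45, 0.55))
  pa <- list(h1 = c(0, 0), h2 = c(1, 1))
  rec <- 0
  for (i in seq_len(n_gam)) {
    g <- moob:::.make_gamete(pa$h1, pa$h2, moob:::.map_geometry(map))
    rec <- rec + (g[1] != g[2])
  }
  r_hat <- rec / n_gam
  r_exp <- (1 - exp(-2 * 0.1)) / 2
  se <- sqrt(r_exp * (1 - r_exp) / n_gam)
  expect_lt(abs(r_hat - r_exp), 3 * se)
})

test_that("founders derive from two haplotypes, with h2 near 0.5 and negative trait correlation", {
  cfg <- small_sim_config()
  st0 <- make_founders(sim_config(pop_size = 10, n_markers_per_chrom = 30,
                                  n_qtl_per_chrom = 10, n_opposite_sign = 5,
                                  burnin_random_mating = 0), seed = 1)
  # before burn-in every individual is the F1 of the two founders
  expect_true(all(st0$pop$h1 == 0) && all(st0$pop$h2 == 1))
  cfg <- small_sim_config(pop_size = 100)
  h2s <- NULL; cors <- NULL
  for (s in 1:8) {
    st <- make_founders(cfg, seed = s)
    vg <- apply(st$tbv, 2, var); vp <- apply(st$phenotypes, 2, var)
    h2s <- c(h2s, vg / vp)
    cors <- c(cors, cor(st$tbv)[1, 2])
  }
  expect_equal(mean(h2s), 0.5, tolerance = 0.06)
  expect_lt(mean(cors), 0)
  expect_lt(mean(cors > 0), 0.5)  # negative in the clear majority of seeds
})

test_that("GBLUP recovers true values in the noiseless limit and shrinks with low h2", {
  set.seed(24)
  cfg <- small_sim_config(pop_size = 60)
  st <- make_founders(cfg, seed = 3)
  noiseless <- list(dosages = moob:::.pop_dosages(st$pop), phenotypes = st$tbv)
  fit <- predict_gebv(noiseless, h2_assumed = 0.999)
  expect_gt(cor(fit$values[, 1], st$tbv[, 1]), 0.99)
  expect_gt(cor(fit$values[, 2], st$tbv[, 2]), 0.99)
  shrunk <- predict_gebv(noiseless, h2_assumed = 1e-5)
  expect_lt(var(shrunk$values[, 1]) / var(fit$values[, 1]), 0.01)
  # out-of-sample accuracy positive under the default noise level
  train <- list(dosages = moob:::.pop_dosages(st$pop)[1:30, ],
                phenotypes = st$phenotypes[1:30, ])
  f2 <- predict_gebv(train, h2_assumed = 0.5)
  pred <- predict_gebv_new(attr(f2, "model"),
                           moob:::.pop_dosages(st$pop)[31:60, ])
  expect_gt(cor(pred[, 1], st$tbv[31:60, 1]), 0)
  # estimated genetic correlation of the GEBVs is carried as "psi"
  expect_equal(dim(attr(fit, "psi")), c(2L, 2L))
})

test_that("strategy rules reduce to their degenerate equivalents", {
  set.seed(34)
  V <- matrix(rnorm(40), 20, 2)
  # index with weight all on trait 1 selects the same set as tandem on trait 1
  sel_index <- which(apply_strategy(V, strategy_config("index", index_weights = c(1, 0)))$c > 0)
  sel_tandem <- which(apply_strategy(V, strategy_config("tandem"), cycle = 1)$c > 0)
  expect_identical(sel_index, sel_tandem)
  # tandem alternates traits by cycle parity
  sel_t2 <- which(apply_strategy(V, strategy_config("tandem"), cycle = 2)$c > 0)
  expect_identical(sel_t2, sort(order(V[, 2], decreasing = TRUE)[1:10]))
  # culling with thresholds at the minimum keeps everyone, uniformly
  w <- apply_strategy(V, strategy_config("culling", culling_quantiles = 0))
  expect_equal(w$c, rep(1 / 20, 20))
  # nondominated weights follow the dominance sort
  wn <- apply_strategy(V, strategy_config("nondominated"), cycle = 1)
  expect_equal(sum(wn$c), 1)
})

test_that("the global-criterion pick with full weight on co-ancestry is the minimum-co-ancestry solution", {
  set.seed(44)
  m <- 12
  G <- rand_genotypes(m, 60)
  A <- compute_relationship(G)
  V <- matrix(rnorm(m * 2), m, 2)
  w <- apply_strategy(V, strategy_config("moob_pp_eq1",
                                         decision_weights = c(0, 0, 1),
                                         frontier_resolution = 11),
                      A = A$A)
  F <- trace_frontier(breeding_values(moob:::.safe_standardize(V)), A,
                      resolution = 11)
  cos <- vapply(F$solutions, function(s) s$objectives$values[3], 0)
  expect_equal(coancestry(w, A$A), min(cos), tolerance = 1e-9)
})

test_that("no selection means drift only; truncation yields positive response", {
  cfg <- small_sim_config(pop_size = 50)
  deltas_none <- NULL; deltas_sel <- NULL
  for (s in 1:8) {
    st <- make_founders(cfg, seed = 100 + s)
    base <- make_base_population(st, cfg)
    none <- run_breeding(base, cfg, strategy_config("index", genomic = FALSE,
                                                    selection_fraction = 1),
                         seed = s, n_cycles = 1)
    trait <- run_breeding(base, cfg, strategy_config("tandem", genomic = FALSE),
                          seed = s, n_cycles = 1)
    sd0 <- sqrt(none$var_trait1[1])
    deltas_none <- c(deltas_none, (none$mean_trait1[2] - none$mean_trait1[1]) / sd0)
    deltas_sel <- c(deltas_sel, (trait$mean_trait1[2] - trait$mean_trait1[1]) / sd0)
  }
  se_none <- sd(deltas_none) / sqrt(length(deltas_none))
  expect_lt(abs(mean(deltas_none)), 3 * se_none)
  se_sel <- sd(deltas_sel) / sqrt(length(deltas_sel))
  expect_gt(mean(deltas_sel), 3 * se_sel)
})

test_that("breeding runs are reproducible per seed, and heritability stays calibrated", {
  cfg <- small_sim_config()
  st <- make_founders(cfg, seed = 5)
  base <- make_base_population(st, cfg)
  t1 <- run_breeding(base, cfg, strategy_config("moob_pp_eq1", frontier_resolution = 6),
                     seed = 9, n_cycles = 3)
  t2 <- run_breeding(base, cfg, strategy_config("moob_pp_eq1", frontier_resolution = 6),
                     seed = 9, n_cycles = 3)
  expect_identical(t1, t2)
  t3 <- run_breeding(base, cfg, strategy_config("moob_pp_eq1", frontier_resolution = 6),
                     seed = 10, n_cycles = 3)
  expect_false(identical(t1, t3))
  expect_equal(nrow(t1), 4L)  # base + 3 cycles
  # noise is recalibrated each cycle: realized h2 stays near 0.5 on average
  expect_equal(mean(c(t1$h2_trait1, t1$h2_trait2)), 0.5, tolerance = 0.2)
})

test_that("genetic variance erodes faster under truncation than under optimized contributions", {
  cfg <- small_sim_config(pop_size = 50)
  v_trunc <- NULL; v_moob <- NULL
  for (s in 1:5) {
    st <- make_founders(cfg, seed = 200 + s)
    base <- make_base_population(st, cfg)
    tr_t <- run_breeding(base, cfg, strategy_config("index", selection_fraction = 0.2),
                         seed = s, n_cycles = 4)
    tr_m <- run_breeding(base, cfg, strategy_config("moob_pp_eq1",
                                                    frontier_resolution = 6),
                         seed = s, n_cycles = 4)
    last <- 5
    v_trunc <- c(v_trunc, (tr_t$var_trait1[last] + tr_t$var_trait2[last]) /
                   (tr_t$var_trait1[1] + tr_t$var_trait2[1]))
    v_moob <- c(v_moob, (tr_m$var_trait1[last] + tr_m$var_trait2[last]) /
                  (tr_m$var_trait1[1] + tr_m$var_trait2[1]))
  }
  expect_lt(mean(v_trunc), mean(v_moob))
})

test_that("the genomic-mating strategy produces an executable plan", {
  cfg <- small_sim_config(pop_size = 20)
  st <- make_founders(cfg, seed = 7)
  base <- make_base_population(st, cfg)
  scfg <- strategy_config("genomic_mating", n_crosses = 4,
                          gm_opts = list(pop_size = 16, generations = 8))
  tr <- run_breeding(base, cfg, scfg, seed = 3, n_cycles = 2)
  expect_equal(nrow(tr), 3L)
  expect_true(all(is.finite(tr$mean_trait1)))
})
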