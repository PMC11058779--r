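test_that("generators are deterministic given the seed", {
  cfg <- scenario_config(seed = 7)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$chem, b2$chem)
  expect_identical(b1$abund, b2$abund)
  expect_identical(b1$anomalies, b2$anomalies)
  expect_identical(b1$covariates, b2$covariates)
  b3 <- simulate_bundle(scenario_config(seed = 8))
  expect_false(identical(b1$abund, b3$abund))
})

test_that("chemistry follows the planted gradient with the right signs", {
  cfg <- scenario_config(seed = 1)
  # noiseless link: ranks follow the gradient exactly
  cfg0 <- cfg
  cfg0$chem_links$sd <- rep(1e-12, nrow(cfg0$chem_links))
  g0 <- simulate_gradient_chemistry(cfg0)
  expect_equal(cor(g0$chem$TP, g0$gradient, method = "spearman"), 1)
  expect_equal(cor(g0$chem$TN_TP, g0$gradient, method = "spearman"), -1)
  # default noise: log TP strongly tracks the gradient
  g1 <- simulate_gradient_chemistry(cfg)
  expect_gte(cor(log10(g1$chem$TP), g1$gradient), 0.8)
  # TN:TP consistency invariant (TP converted to mg/L)
  expect_equal(g1$chem$TN_TP, g1$chem$TN / (g1$chem$TP / 1000))
  expect_true(all(as.matrix(g1$chem[streamhealth:::CHEM_VARS]) > 0))
})

test_that("simulated marginals stay inside the configured target ranges", {
  cfg <- scenario_config()
  li <- cfg$chem_links
  mins <- maxs <- matrix(NA_real_, 20, nrow(li), dimnames = list(NULL, li$var))
  for (s in 1:20) {
    g <- simulate_gradient_chemistry(scenario_config(seed = 100 + s))
    for (v in li$var) {
      mins[s, v] <- min(g$chem[[v]]); maxs[s, v] <- max(g$chem[[v]])
    }
  }
  for (v in li$var) {
    tmin <- li$target_min[li$var == v]; tmax <- li$target_max[li$var == v]
    expect_gte(min(mins[, v]), tmin * 0.5)
    expect_lte(max(mins[, v]), tmin * 1.5 + 0.05 * (tmax - tmin))
    expect_lte(max(maxs[, v]), tmax * 1.5)
    expect_gte(min(maxs[, v]), tmax * 0.5)
  }
})

test_that("the default guild plan realises the published entity structure", {
  cfg <- scenario_config()
  g <- simulate_guild_table(cfg)
  expect_equal(nrow(g), 50)
  cat <- build_entities(g)
  expect_equal(nrow(cat), 19)
  expect_equal(cat$n_species,
               c(8, 6, 5, 4, 3, 3, 3, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1))
  # required guild archetypes are present
  expect_true(any(cat$trophic == "Omn" & cat$habitat == "RB-WC" &
                    cat$tolerance == "IS"))
  expect_true(any(cat$trophic == "Ins" & cat$habitat == "RB" &
                    cat$tolerance == "SS"))
  expect_equal(sum(!g$native), cfg$n_nonnative)
  # one-triple plan gives one entity; infeasible plans error
  plan1 <- data.frame(trophic = "Omn", habitat = "WC", tolerance = "IS",
                      n_species = 3)
  cfg1 <- scenario_config(n_species = 3, guild_plan = plan1)
  expect_equal(nrow(build_entities(simulate_guild_table(cfg1))), 1)
  expect_error(scenario_config(n_species = 10, guild_plan = plan1), "sum")
  # random plans: entity count equals distinct planned triples
  set.seed(99)
  plan_r <- default_guild_plan()[sample(19, 6), ]
  cfg_r <- scenario_config(n_species = sum(plan_r$n_species),
                           guild_plan = plan_r)
  expect_equal(nrow(build_entities(simulate_guild_table(cfg_r))), 6)
})

test_that("expected abundances are monotone with the configured signs", {
  cfg <- scenario_config()
  gc_ <- simulate_gradient_chemistry(cfg)
  guilds <- simulate_guild_table(cfg)
  mu <- expected_abundance(cfg, gc_$gradient, guilds)
  cat <- build_entities(guilds)
  em_mu <- sapply(cat$members, function(m) rowSums(mu[, m, drop = FALSE]))
  ra_mu <- 100 * em_mu / rowSums(em_mu)
  for (i in seq_len(nrow(cat))) {
    rho <- cor(ra_mu[, i], gc_$gradient, method = "spearman")
    if (cat$tolerance[i] == "SS") expect_lt(rho, 0)
    if (cat$tolerance[i] == "TS" && cat$trophic[i] == "Omn") expect_gt(rho, 0)
  }
})

test_that("sampled abundances carry the planted community signal", {
  cfg <- scenario_config(seed = 1)
  gc_ <- simulate_gradient_chemistry(cfg)
  guilds <- simulate_guild_table(cfg)
  ab <- simulate_abundances(cfg, gc_$gradient, guilds)
  expect_true(all(ab$anomalies <= ab$abund))
  expect_true(all(ab$abund >= 0))
  sens <- guilds$species_id[guilds$tolerance == "SS"]
  rho <- cor(rowSums(ab$abund[, sens]), gc_$gradient, method = "spearman")
  expect_lte(rho, -0.5)
  # anomaly prevalence rises along the gradient
  ano_rate <- rowSums(ab$anomalies) / pmax(rowSums(ab$abund), 1)
  expect_gt(cor(ano_rate, gc_$gradient, method = "spearman"), 0)
  # same seed twice: identical
  ab2 <- simulate_abundances(cfg, gc_$gradient, guilds)
  expect_identical(ab$abund, ab2$abund)
})

test_that("covariates respect the gradient and the land-use budget", {
  cfg <- scenario_config(seed = 2)
  g <- simulate_gradient_chemistry(cfg)$gradient
  cov <- simulate_covariates(cfg, g)
  expect_lt(cor(cov$Elev, g), -0.9)
  expect_true(all(cov$pAgr + cov$pUrb + cov$pFor <= 100 + 1e-9))
  expect_true(all(cov$SO %in% 2:6))
  expect_true(all(cov[c("pAgr", "pUrb", "pFor")] >= 0))
})

test_that("noiseless chemistry clusters are contiguous gradient segments", {
  cfg <- scenario_config(seed = 1)
  cfg$chem_links$sd <- rep(1e-6, nrow(cfg$chem_links))
  b <- simulate_bundle(cfg)
  lc <- log_transform_chem(b$chem, vars = streamhealth:::CHEM_VARS)
  cl <- cut_tree(ward_cluster(dist(lc)), 3)
  # with zero noise every variable is an exact linear function of the
  # gradient, so Ward clusters must be contiguous intervals along it
  runs <- rle(as.integer(cl[order(b$gradient)]))
  expect_equal(length(runs$lengths), 3)
  terc <- cut(b$gradient, quantile(b$gradient, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  expect_gt(mclust::adjustedRandIndex(cl, terc), 0.3)
})
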