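#' Default guild composition plan
#'
#' Nineteen guild triples with member counts summing to 50 species, the
#' entity structure observed in a regional survey of 41 wadable stream
#' sites: sizes 8,6,5,4,3,3,3,2,2,2,2,2,2,1,1,1,1,1,1, including the
#' ubiquitous generalist entity (Omn, RB-WC, IS) and sensitive riffle
#' insectivores (Ins, RB, SS).
#'
#' @return data.frame `trophic, habitat, tolerance, n_species`.
#' @export
default_guild_plan <- function() {
  data.frame(
    trophic   = c("Omn", "Omn", "Ins", "Omn", "Ins", "Ins", "Ins", "Ins",
                  "Ins", "Car", "Car", "Car", "Car", "Omn", "Omn", "Ins",
                  "Omn", "Car", "Ins"),
    habitat   = c("WC", "WC", "WC", "BT", "RB", "WC", "RB", "RB-WC", "BT",
                  "WC", "BT", "BT", "BT", "RB", "RB", "RB-WC", "RB-WC",
                  "RB-WC", "BT"),
    tolerance = c("IS", "TS", "IS", "TS", "SS", "TS", "IS", "IS", "IS",
                  "TS", "TS", "IS", "SS", "IS", "SS", "SS", "IS", "TS",
                  "TS"),
    n_species = c(8, 6, 5, 4, 3, 3, 3, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

# per-variable log10-linear links to the pollution gradient g in [0,1]:
# value = 10^(log10(baseline) + slope * g + N(0, sd^2)).
# target_min/target_max document the marginal range each variable is meant
# to span across sites (used by range diagnostics, not by the draw itself).
default_chem_links <- function() {
  links <- data.frame(
    var = c("WT", "DO", "EC", "TSS", "TOC", "BOD", "TN", "NH4_N", "NO3_N",
            "TP", "PO4_P", "Chl_a"),
    baseline = c(22, 11, 120, 1.1, 1.5, 0.5, 1.5, 0.015, 1.0, 9, 0.5, 1.0),
    slope = c(0.10, -0.13, 0.65, 1.10, 0.75, 0.85, 0.15, 1.70, 0.45,
              1.25, 1.95, 2.00),
    sd = c(0.015, 0.02, 0.05, 0.08, 0.07, 0.08, 0.15, 0.10, 0.10,
           0.08, 0.12, 0.12),
    target_min = c(20.6, 7.5, 113, 0.9, 1.3, 0.4, 1.0, 0.01, 0.6,
                   6.7, 0.3, 0.5),
    target_max = c(28.8, 12.0, 607, 17.6, 11.1, 4.5, 6.0, 1.03, 4.6,
                   208, 70.7, 143),
    stringsAsFactors = FALSE
  )
  links
}

#' Synthetic-scenario configuration
#'
#' Bundles every tunable of the generator: the number of sites on the
#' planted pollution gradient, the species pool and its guild plan, the
#' per-variable chemistry links, entity-level abundance response slopes,
#' negative-binomial dispersion, and the anomaly-rate link. Defaults
#' emulate a survey of 41 wadable stream sites with 50 species in 19
#' entities, pollutant concentrations rising log-linearly along the
#' gradient within published monitoring ranges, sensitive/riffle taxa
#' declining and tolerant omnivores increasing downstream.
#'
#' @param n_sites number of sites (>= 6; default 41).
#' @param n_species species-pool size (default 50, must match the plan).
#' @param seed integer seed (default 1).
#' @param guild_plan data.frame of triples + `n_species` per entity.
#' @param chem_links per-variable baseline/slope/sd table.
#' @param slopes named list of entity response slopes (natural-log scale
#'   per unit gradient): `sensitive`, `riffle`, `tolerant_omnivore`,
#'   `tolerant_other`, `generalist`, `other`.
#' @param dispersion negative-binomial size parameter (`Inf` = Poisson).
#' @param slope_jitter_sd species-level jitter sd around the entity slope.
#' @param base_mean,generalist_mean expected per-site counts per species at
#'   mid-gradient for ordinary and generalist species.
#' @param anomaly_base,anomaly_slope anomaly probability `base + slope*g`.
#' @param n_nonnative number of species flagged non-native (placed in the
#'   largest tolerant entity).
#' @return list of class `sh_scenario`.
#' @export
scenario_config <- function(n_sites = 41, n_species = 50, seed = 1,
                            guild_plan = default_guild_plan(),
                            chem_links = default_chem_links(),
                            slopes = list(sensitive = -3.0, riffle = -2.0,
                                          tolerant_omnivore = 2.5,
                                          tolerant_other = 1.5,
                                          generalist = 0.0, other = -0.5),
                            dispersion = 4,
                            slope_jitter_sd = 0.2,
                            base_mean = 7, generalist_mean = 45,
                            anomaly_base = 0.002, anomaly_slope = 0.03,
                            n_nonnative = 2) {
  assert_that(n_sites >= 6, "need at least 6 sites")
  assert_that(sum(guild_plan$n_species) == n_species,
              "guild plan member counts must sum to n_species")
  key <- paste(guild_plan$trophic, guild_plan$habitat, guild_plan$tolerance)
  assert_that(!anyDuplicated(key), "guild plan triples must be distinct")
  assert_that(all(chem_links$sd > 0), "chemistry noise sds must be positive")
  structure(list(n_sites = n_sites, n_species = n_species, seed = seed,
                 guild_plan = guild_plan, chem_links = chem_links,
                 slopes = slopes, dispersion = dispersion,
                 slope_jitter_sd = slope_jitter_sd,
                 base_mean = base_mean, generalist_mean = generalist_mean,
                 anomaly_base = anomaly_base, anomaly_slope = anomaly_slope,
                 n_nonnative = n_nonnative),
            class = "sh_scenario")
}

#' Simulate chemistry along the planted pollution gradient
#'
#' Sites are placed evenly on a gradient `g` in `[0, 1]`. Each variable
#' follows `10^(log10(baseline) + slope * g + noise)` with Gaussian noise
#' on the log scale (lognormal multiplicative noise); TN:TP is computed
#' from the simulated TN and TP (TP converted to mg/L), so it decreases as
#' phosphorus accumulates downstream while WT, DO and TN stay near-flat.
#'
#' @param cfg an [scenario_config()].
#' @return list: `gradient` (named per site) and `chem` data.frame
#'   (`site_id` + the 13 indicator columns).
#' @export
simulate_gradient_chemistry <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_sites
  g <- seq(0, 1, length.out = n)
  sites <- sprintf("S%02d", seq_len(n))
  names(g) <- sites
  li <- cfg$chem_links
  chem <- data.frame(site_id = sites)
  for (i in seq_len(nrow(li))) {
    noise <- stats::rnorm(n, 0, li$sd[i])
    chem[[li$var[i]]] <- 10^(log10(li$baseline[i]) + li$slope[i] * g + noise)
  }
  chem$TN_TP <- chem$TN / (chem$TP / 1000)
  chem <- chem[c("site_id", CHEM_VARS)]
  list(gradient = g, chem = chem)
}

#' Simulate a guild-assignment table from a composition plan
#'
#' Species `sp01 ... spNN` realise the planned triples in plan order. The
#' first `n_nonnative` species of the largest tolerant entity are flagged
#' non-native; all others are native.
#'
#' @param cfg an [scenario_config()].
#' @return guild-assignment data.frame.
#' @export
simulate_guild_table <- function(cfg) {
  plan <- cfg$guild_plan
  assert_that(sum(plan$n_species) == cfg$n_species,
              "infeasible plan: counts do not sum to n_species")
  idx <- rep(seq_len(nrow(plan)), plan$n_species)
  g <- data.frame(
    species_id = sprintf("sp%02d", seq_len(cfg$n_species)),
    trophic = plan$trophic[idx],
    habitat = plan$habitat[idx],
    tolerance = plan$tolerance[idx],
    native = TRUE,
    stringsAsFactors = FALSE
  )
  if (cfg$n_nonnative > 0) {
    ts_rows <- which(g$tolerance == "TS")
    if (length(ts_rows) > 0) {
      take <- utils::head(ts_rows, cfg$n_nonnative)
      g$native[take] <- FALSE
    }
  }
  validate_guild_table(g)
}

# entity-level response slope by guild rules (natural-log scale)
entity_slope <- function(trophic, habitat, tolerance, slopes) {
  if (trophic == "Omn" && habitat == "RB-WC" && tolerance == "IS") {
    slopes$generalist
  } else if (tolerance == "SS") {
    slopes$sensitive
  } else if (tolerance == "TS" && trophic == "Omn") {
    slopes$tolerant_omnivore
  } else if (tolerance == "TS") {
    slopes$tolerant_other
  } else if (habitat == "RB") {
    slopes$riffle
  } else {
    slopes$other
  }
}

#' Expected species abundance under a scenario
#'
#' The noiseless negative-binomial means: `mu0 * exp(slope * (g - 0.5))`,
#' where `mu0` is the per-species baseline and `slope` the entity response
#' slope (without species jitter). Useful for construction checks.
#'
#' @param cfg an [scenario_config()].
#' @param gradient per-site gradient values.
#' @param guilds guild table from [simulate_guild_table()].
#' @return site x species matrix of expected counts.
#' @export
expected_abundance <- function(cfg, gradient, guilds) {
  mu0 <- ifelse(guilds$trophic == "Omn" & guilds$habitat == "RB-WC" &
                  guilds$tolerance == "IS",
                cfg$generalist_mean, cfg$base_mean)
  sl <- vapply(seq_len(nrow(guilds)), function(i) {
    entity_slope(guilds$trophic[i], guilds$habitat[i], guilds$tolerance[i],
                 cfg$slopes)
  }, 0)
  mu <- outer(gradient - 0.5, sl, function(g, s) exp(g * s))
  mu <- sweep(mu, 2, mu0, "*")
  dimnames(mu) <- list(names(gradient), guilds$species_id)
  mu
}

#' Simulate species abundances along the gradient
#'
#' Counts are negative-binomial with log-mean linear in the gradient:
#' sensitive (SS) and riffle-benthic entities decline, tolerant omnivores
#' increase, the ubiquitous generalist stays flat. Member species share
#' their entity's slope with small Gaussian jitter. Anomaly counts are
#' binomial per cell with a rate increasing in the gradient (so anomalies
#' never exceed counts).
#'
#' @param cfg an [scenario_config()].
#' @param gradient per-site gradient from [simulate_gradient_chemistry()].
#' @param guilds guild table covering the species pool.
#' @return list: `abund` and `anomalies`, site x species integer matrices.
#' @export
simulate_abundances <- function(cfg, gradient, guilds) {
  set.seed(cfg$seed + 1L)
  n <- length(gradient)
  mu0 <- ifelse(guilds$trophic == "Omn" & guilds$habitat == "RB-WC" &
                  guilds$tolerance == "IS",
                cfg$generalist_mean, cfg$base_mean)
  sl <- vapply(seq_len(nrow(guilds)), function(i) {
    entity_slope(guilds$trophic[i], guilds$habitat[i], guilds$tolerance[i],
                 cfg$slopes)
  }, 0)
  sl <- sl + stats::rnorm(length(sl), 0, cfg$slope_jitter_sd)
  abund <- matrix(0L, n, nrow(guilds),
                  dimnames = list(names(gradient), guilds$species_id))
  for (j in seq_len(nrow(guilds))) {
    mu <- mu0[j] * exp(sl[j] * (gradient - 0.5))
    abund[, j] <- if (is.finite(cfg$dispersion)) {
      stats::rnbinom(n, size = cfg$dispersion, mu = mu)
    } else {
      stats::rpois(n, lambda = mu)
    }
  }
  p_ano <- pmin(pmax(cfg$anomaly_base + cfg$anomaly_slope * gradient, 0), 1)
  anomalies <- matrix(stats::rbinom(length(abund), size = as.vector(abund),
                                    prob = rep(p_ano, ncol(abund))),
                      n, ncol(abund), dimnames = dimnames(abund))
  list(abund = abund, anomalies = anomalies)
}

#' Simulate site covariates
#'
#' Elevation decreases monotonically with the gradient plus noise (upstream
#' sites are high and clean); stream order increases downstream; forest
#' cover declines while urban and agricultural cover rise, rescaled so the
#' three proportions never exceed 100.
#'
#' @param cfg an [scenario_config()].
#' @param gradient per-site gradient values.
#' @return data.frame `site_id, Elev, SO, pAgr, pUrb, pFor`.
#' @export
simulate_covariates <- function(cfg, gradient) {
  set.seed(cfg$seed + 2L)
  n <- length(gradient)
  elev <- pmax(15 + 345 * (1 - gradient) + stats::rnorm(n, 0, 12), 5)
  so <- pmin(pmax(round(2 + 4 * gradient + stats::rnorm(n, 0, 0.5)), 2), 6)
  for_ <- pmax(59 * (1 - gradient) + stats::rnorm(n, 0, 3), 0)
  urb <- pmax(2 + 70 * gradient + stats::rnorm(n, 0, 3), 0)
  agr <- pmax(8 + 25 * gradient + stats::rnorm(n, 0, 4), 0)
  tot <- for_ + urb + agr
  over <- tot > 100
  if (any(over)) {
    scl <- 100 / tot[over]
    for_[over] <- for_[over] * scl
    urb[over] <- urb[over] * scl
    agr[over] <- agr[over] * scl
  }
  data.frame(site_id = names(gradient), Elev = elev, SO = so,
             pAgr = agr, pUrb = urb, pFor = for_)
}

#' Generate a full synthetic survey bundle
#'
#' Chemistry, guilds, abundances (+anomalies) and covariates for one
#' scenario, all deterministic given `cfg$seed`.
#'
#' @param cfg an [scenario_config()].
#' @return list of class `sh_bundle`: `gradient`, `chem`, `guilds`,
#'   `abund`, `anomalies`, `covariates`, `config`.
#' @export
simulate_bundle <- function(cfg = scenario_config()) {
  gc_ <- simulate_gradient_chemistry(cfg)
  guilds <- simulate_guild_table(cfg)
  ab <- simulate_abundances(cfg, gc_$gradient, guilds)
  cov <- simulate_covariates(cfg, gc_$gradient)
  structure(list(gradient = gc_$gradient, chem = gc_$chem, guilds = guilds,
                 abund = ab$abund, anomalies = ab$anomalies,
                 covariates = cov, config = cfg),
            class = "sh_bundle")
}

#' End-to-end gradient-recovery report
#'
#' Runs the full analysis chain on a synthetic bundle and measures how well
#' it recovers the planted pollution gradient: the Pearson correlation of
#' NMDS1 site scores (entity relative abundances, Bray-Curtis) with the
#' gradient, the R-squared of NMDS1 on log10 TP, and the adjusted Rand
#' agreement between k=3 chemistry clusters and gradient terciles.
#'
#' @param cfg an [scenario_config()].
#' @param n_starts,max_iter NMDS effort (defaults 10 / 200).
#' @return list: `r_nmds1_gradient`, `p_nmds1_gradient`, `r2_nmds1_logTP`,
#'   `ari_cluster_tercile`, `stress`, `converged`, `n_sites`.
#' @export
end_to_end_recovery <- function(cfg = scenario_config(), n_starts = 10,
                                max_iter = 200) {
  b <- simulate_bundle(cfg)
  catalog <- build_entities(b$guilds)
  em <- entity_abundance(b$abund, catalog)
  ra <- relative_abundance(em, scope = "per_site", digits = NULL)
  dm <- bray_curtis(ra)
  ord <- nmds(dm, k = 2, n_starts = n_starts, max_iter = max_iter,
              seed = cfg$seed)
  pc <- pearson(ord$points[, 1], b$gradient)
  reg <- ols_simple(log10(b$chem$TP), ord$points[, 1],
                    predictor = "log10_TP", response = "NMDS1")
  lchem <- log_transform_chem(b$chem, vars = CHEM_VARS)
  hc <- ward_cluster(stats::dist(lchem))
  cl <- cut_tree(hc, k = 3)
  terc <- cut(b$gradient, breaks = stats::quantile(b$gradient, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  ari <- mclust::adjustedRandIndex(cl, terc)
  list(r_nmds1_gradient = pc$r, p_nmds1_gradient = pc$p,
       r2_nmds1_logTP = reg$r_squared, ari_cluster_tercile = ari,
       stress = ord$stress, converged = ord$converged,
       n_sites = cfg$n_sites)
}
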