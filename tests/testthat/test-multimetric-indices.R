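test_that("biological metrics match hand counts on simple communities", {
  # one native tolerant omnivorous water-column species, 10 individuals
  g <- data.frame(species_id = "a", trophic = "Omn", habitat = "WC",
                  tolerance = "TS", native = TRUE)
  m <- matrix(10, 1, 1, dimnames = list("s1", "a"))
  v <- compute_biological_metrics(m, g, "s1")
  expect_equal(unname(v[c("M1_NS", "M2_RB", "M3_SS")]), c(1, 0, 0))
  expect_equal(unname(v[c("M4_pTS", "M5_pOmn", "M6_pNIns")]), c(100, 100, 0))
  expect_equal(unname(v[c("M7_NSI", "M8_pAno")]), c(10, 0))

  # one anomaly among 50 individuals -> 2%
  g2 <- data.frame(species_id = c("a", "b"),
                   trophic = c("Ins", "Omn"), habitat = c("RB", "WC"),
                   tolerance = c("SS", "IS"), native = c(TRUE, FALSE))
  m2 <- matrix(c(20, 30), 1, 2, dimnames = list("s1", c("a", "b")))
  an <- matrix(c(1, 0), 1, 2, dimnames = dimnames(m2))
  v2 <- compute_biological_metrics(m2, g2, "s1", anomalies = an)
  expect_equal(unname(v2["M8_pAno"]), 2.0)
  expect_equal(unname(v2["M1_NS"]), 1)        # b is non-native
  expect_equal(unname(v2["M6_pNIns"]), 40)    # native insectivores = a
  expect_equal(unname(v2["M7_NSI"]), 20)
})

test_that("metrics equal a per-individual enumeration oracle on random data", {
  for (seed in c(2, 7)) {
    g <- random_guild_table(15, seed = seed)
    m <- random_abundance(5, g$species_id, seed = seed)
    set.seed(seed)
    an <- matrix(rbinom(length(m), m, 0.05), nrow(m), dimnames = dimnames(m))
    site <- rownames(m)[2]
    v <- compute_biological_metrics(m, g, site, anomalies = an)
    # enumeration: expand to one row per individual carrying its guild labels
    x <- m[site, ]
    ind <- g[rep(seq_len(nrow(g)), x), ]
    expect_equal(unname(v["M1_NS"]), length(unique(ind$species_id[ind$native])))
    expect_equal(unname(v["M2_RB"]),
                 length(unique(ind$species_id[ind$habitat == "RB"])))
    expect_equal(unname(v["M3_SS"]),
                 length(unique(ind$species_id[ind$tolerance == "SS"])))
    expect_equal(unname(v["M4_pTS"]), 100 * mean(ind$tolerance == "TS"))
    expect_equal(unname(v["M5_pOmn"]), 100 * mean(ind$trophic == "Omn"))
    expect_equal(unname(v["M6_pNIns"]),
                 100 * mean(ind$native & ind$trophic == "Ins"))
    expect_equal(unname(v["M7_NSI"]), sum(ind$native))
    expect_equal(unname(v["M8_pAno"]), 100 * sum(an[site, ]) / sum(x))
  }
})

test_that("zero-individual sites raise an undefined-metrics condition", {
  g <- random_guild_table(4, seed = 1)
  m <- random_abundance(2, g$species_id, seed = 1)
  m[1, ] <- 0
  expect_error(compute_biological_metrics(m, g, rownames(m)[1]),
               class = "streamhealth_zero_site")
  expect_warning(tab <- mibif_table(m, g), "zero-individual")
  expect_equal(attr(tab, "excluded"), rownames(m)[1])
  expect_equal(tab$site_id, rownames(m)[2])
})

test_that("5/3/1 scoring matches interval membership with better-score ties", {
  lo <- metric_criterion("lower_is_better", 2, 5)
  hi <- metric_criterion("higher_is_better", 5, 2)
  sweep_vals <- seq(-1, 8, by = 0.25)
  oracle_lo <- ifelse(sweep_vals <= 2, 5, ifelse(sweep_vals <= 5, 3, 1))
  oracle_hi <- ifelse(sweep_vals >= 5, 5, ifelse(sweep_vals >= 2, 3, 1))
  expect_equal(score_metric(sweep_vals, lo), oracle_lo)
  expect_equal(score_metric(sweep_vals, hi), oracle_hi)
  # boundaries take the better score
  expect_equal(score_metric(2, lo), 5L)
  expect_equal(score_metric(5, lo), 3L)
  expect_equal(score_metric(5, hi), 5L)
  expect_error(score_metric(NA_real_, lo), "finite")
  expect_error(metric_criterion("lower_is_better", 5, 2), "cut1 < cut2")
})

test_that("index totals are additive and bounded for any record", {
  crit <- default_mwpi_criteria()
  set.seed(42)
  for (i in 1:25) {
    rec <- as.list(stats::setNames(runif(7, 0, 500), names(crit)))
    res <- mwpi_score(rec)
    expect_equal(res$total, sum(res$scores))
    expect_gte(res$total, 7); expect_lte(res$total, 35)
  }
  bcrit <- default_mibif_criteria()
  for (i in 1:25) {
    met <- as.list(stats::setNames(runif(8, 0, 150), names(bcrit)))
    res <- mibif_score(met)
    expect_equal(res$total, sum(res$scores))
    expect_gte(res$total, 8); expect_lte(res$total, 40)
  }
  # missing metric named in the error
  expect_error(mwpi_score(list(TN = 1)), "TP")
})

test_that("improving any single metric never decreases the total", {
  crit <- default_mwpi_criteria()
  set.seed(13)
  for (i in 1:10) {
    rec <- stats::setNames(runif(7, 0, 300), names(crit))
    base <- mwpi_score(as.list(rec))$total
    for (mname in names(crit)) {
      better <- rec
      dirn <- crit[[mname]]$direction
      better[mname] <- if (dirn == "lower_is_better") rec[mname] * 0.5
                       else rec[mname] * 2
      expect_gte(mwpi_score(as.list(better))$total, base)
    }
  }
})

test_that("health classes are monotone in the total and bands must tile", {
  bands <- default_mwpi_bands()
  cls <- classify_health(7:35, bands)
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_equal(as.character(classify_health(35, bands)), "excellent")
  expect_equal(as.character(classify_health(7, bands)), "very poor")
  expect_error(classify_health(36, bands), "outside")
  expect_error(health_bands(data.frame(lo = c(7, 15), hi = c(13, 20),
                                       label = c("a", "b"))),
               class = "streamhealth_validation_error")
  # random contiguous bands against interval lookup
  set.seed(5)
  for (i in 1:5) {
    cuts <- sort(sample(8:34, 4))
    b <- health_bands(data.frame(
      lo = c(7, cuts + 1), hi = c(cuts, 35),
      label = c("very poor", "poor", "fair", "good", "excellent")))
    totals <- 7:35
    oracle <- cut(totals, c(6, cuts, 35),
                  labels = c("very poor", "poor", "fair", "good", "excellent"))
    expect_equal(as.character(classify_health(totals, b)), as.character(oracle))
  }
})

test_that("criteria configuration round-trips through JSON with validation", {
  path <- withr::local_tempfile(fileext = ".json")
  write_criteria(default_mwpi_criteria(), default_mwpi_bands(), path)
  back <- read_criteria(path)
  expect_equal(back$criteria, default_mwpi_criteria())
  expect_equal(back$bands$lo, default_mwpi_bands()$lo)
  rec <- list(TN = 1, TP = 20, TN_TP = 150, BOD = 0.5, TSS = 2, EC = 150,
              Chl_a = 3)
  expect_equal(mwpi_score(rec, back$criteria, back$bands)$total,
               mwpi_score(rec)$total)
})
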