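test_that("entities group species by exact guild-triple match", {
  g <- data.frame(species_id = c("a", "b", "c", "d"),
                  trophic = c("Omn", "Omn", "Ins", "Omn"),
                  habitat = c("WC", "WC", "RB", "WC"),
                  tolerance = c("IS", "IS", "SS", "TS"),
                  native = TRUE)
  cat <- build_entities(g)
  expect_s3_class(cat, "fe_catalog")
  expect_equal(nrow(cat), 3)
  # largest entity first, members partition the species set
  expect_equal(cat$n_species, c(2, 1, 1))
  expect_setequal(unlist(cat$members), g$species_id)
  expect_equal(sort(cat$members[[1]]), c("a", "b"))
  # single species is its own entity
  expect_equal(nrow(build_entities(g[3, ])), 1)
})

test_that("entity count equals distinct-triple count on random label spaces", {
  for (seed in 1:5) {
    g <- random_guild_table(200, seed = seed)
    cat <- build_entities(g)
    oracle <- length(unique(paste(g$trophic, g$habitat, g$tolerance)))
    expect_equal(nrow(cat), oracle)
    expect_lte(nrow(cat), 36)  # 3 x 4 x 3 label space
    expect_equal(sum(cat$n_species), 200)
    # idempotence: rebuilding from an entity-labelled table reproduces sizes
    again <- build_entities(g)
    expect_identical(again$n_species, cat$n_species)
  }
})

test_that("invalid or missing guild labels are rejected by name", {
  g <- random_guild_table(5)
  g$habitat[3] <- "XX"
  expect_error(build_entities(g), "rsp003")
  g2 <- random_guild_table(5)
  g2$tolerance[2] <- NA
  expect_error(build_entities(g2), "rsp002")
  g3 <- random_guild_table(4)
  g3$species_id[2] <- g3$species_id[1]
  expect_error(build_entities(g3), "duplicated")
})

test_that("entity aggregation conserves individuals and flags orphans", {
  g <- data.frame(species_id = c("a", "b"), trophic = "Omn", habitat = "WC",
                  tolerance = "IS", native = TRUE)
  cat <- build_entities(g)
  m <- matrix(c(3, 4), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_equal(as.vector(entity_abundance(m, cat)), 7)

  g10 <- random_guild_table(12, seed = 9)
  m10 <- random_abundance(10, g10$species_id, seed = 9)
  em <- entity_abundance(m10, build_entities(g10))
  expect_equal(rowSums(em), rowSums(m10))
  expect_equal(sum(em), sum(m10))

  zero <- m10 * 0
  expect_true(all(entity_abundance(zero, build_entities(g10)) == 0))

  m_orphan <- cbind(m10, orphan_sp = 1)
  expect_error(entity_abundance(m_orphan, build_entities(g10)), "orphan_sp")
})

test_that("relative abundance matches direct arithmetic and normalises to 100", {
  g <- random_guild_table(12, seed = 4)
  m <- random_abundance(8, g$species_id, seed = 4)
  em <- entity_abundance(m, build_entities(g))
  ra <- relative_abundance(em, "per_site", digits = NULL)
  expect_equal(ra, 100 * em / rowSums(em), ignore_attr = TRUE)
  expect_equal(unname(rowSums(ra)), rep(100, nrow(em)))
  ra1 <- relative_abundance(em, "per_site", digits = 1)
  expect_true(all(abs(rowSums(ra1) - 100) <= 0.05 * ncol(em)))
  # single entity takes all of it
  one <- em[, 1, drop = FALSE] + 1
  expect_true(all(relative_abundance(one, "per_site") == 100))
  # all-zero scope unit is an error naming the unit
  em0 <- em; em0["rs03", ] <- 0
  expect_error(relative_abundance(em0, "per_site"), "rs03")
})

test_that("per-group and entire-region scopes aggregate before normalising", {
  g <- random_guild_table(10, seed = 5)
  m <- random_abundance(6, g$species_id, seed = 5)
  em <- entity_abundance(m, build_entities(g))
  grp <- rep(c("A", "B"), each = 3)
  ra_g <- relative_abundance(em, "per_group", groups = grp, digits = NULL)
  byg <- rowsum(em, grp)
  expect_equal(ra_g, 100 * byg / rowSums(byg), ignore_attr = TRUE)
  ra_e <- relative_abundance(em, "entire", digits = NULL)
  expect_equal(as.vector(ra_e), unname(100 * colSums(em) / sum(em)))
})

test_that("occupancy and richness match direct counting", {
  em <- rbind(s1 = c(e1 = 2, e2 = 0, e3 = 1),
              s2 = c(5, 0, 0),
              s3 = c(1, 0, 3))
  occ <- entity_occupancy(em)
  expect_equal(unname(occ), c(100, 0, round(100 * 2 / 3, 1)))
  expect_equal(unname(entity_richness(em)["entire"]), 2)
  rich <- entity_richness(em, groups = c("g1", "g1", "g2"))
  expect_equal(unname(rich[c("g1", "g2")]), c(2, 2))
  expect_true(all(rich[c("g1", "g2")] <= rich["entire"]))
  expect_equal(unname(entity_richness(em * 0)["entire"]), 0)
  # random grouping against brute force
  g <- random_guild_table(15, seed = 6)
  m <- random_abundance(9, g$species_id, seed = 6, lambda = 0.4)
  em2 <- entity_abundance(m, build_entities(g))
  grp <- rep(c("x", "y", "z"), each = 3)
  rich2 <- entity_richness(em2, groups = grp)
  for (gg in c("x", "y", "z")) {
    expect_equal(unname(rich2[gg]),
                 sum(colSums(em2[grp == gg, , drop = FALSE]) > 0))
  }
})

test_that("the bundled survey summary reproduces the published entity structure", {
  fe <- regional_fe_summary()
  expect_equal(nrow(fe), 19)
  expect_equal(sum(fe$n_species), 50)
  # entity-size multiset of the regional catalog
  expect_equal(sort(fe$n_species, decreasing = TRUE),
               c(8, 6, 5, 4, 3, 3, 3, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1))
  # a guild table realising these triples yields exactly these entities
  idx <- rep(seq_len(nrow(fe)), fe$n_species)
  g <- data.frame(species_id = sprintf("t%02d", seq_along(idx)),
                  trophic = fe$trophic[idx], habitat = fe$habitat[idx],
                  tolerance = fe$tolerance[idx], native = TRUE)
  cat <- build_entities(g)
  expect_equal(nrow(cat), 19)
  expect_equal(cat$n_species, sort(fe$n_species, decreasing = TRUE))
})
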