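#' Validate a species guild-assignment table
#'
#' Checks that every species carries a complete trophic / habitat / tolerance
#' guild triple drawn from the recognised label sets, plus a logical native
#' flag. The three guild labels define fish ecological entities (FEs):
#' species whose triples match exactly belong to the same entity.
#'
#' @param guilds data.frame with columns `species_id`, `trophic`
#'   (`Omn`/`Ins`/`Car`), `habitat` (`BT`/`RB`/`RB-WC`/`WC`), `tolerance`
#'   (`SS`/`IS`/`TS`) and `native` (logical).
#' @return The validated table, invisibly coerced to character/logical types.
#' @export
validate_guild_table <- function(guilds) {
  assert_that(is.data.frame(guilds) && nrow(guilds) > 0,
              "guild table must be a non-empty data.frame")
  need <- c("species_id", "trophic", "habitat", "tolerance", "native")
  missing_cols <- setdiff(need, names(guilds))
  assert_that(length(missing_cols) == 0,
              "guild table missing columns: ", paste(missing_cols, collapse = ", "))
  guilds$species_id <- as.character(guilds$species_id)
  assert_that(!anyDuplicated(guilds$species_id),
              "duplicated species_id: ",
              paste(unique(guilds$species_id[duplicated(guilds$species_id)]),
                    collapse = ", "))
  for (fld in c("trophic", "habitat", "tolerance")) {
    lv <- switch(fld, trophic = TROPHIC_LEVELS, habitat = HABITAT_LEVELS,
                 tolerance = TOLERANCE_LEVELS)
    val <- as.character(guilds[[fld]])
    bad <- is.na(val) | !(val %in% lv)
    if (any(bad)) {
      stop_sh("invalid ", fld, " label for species ",
              paste(guilds$species_id[bad], collapse = ", "),
              " (allowed: ", paste(lv, collapse = ", "), ")",
              class = "streamhealth_validation_error")
    }
    guilds[[fld]] <- val
  }
  guilds$native <- as.logical(guilds$native)
  assert_that(!anyNA(guilds$native), "native flag must be TRUE/FALSE for every species")
  invisible(guilds)
}

#' Build fish ecological entities from guild assignments
#'
#' Groups species whose (trophic, habitat, tolerance) guild triples match
#' exactly into fish ecological entities (FEs). Entities are numbered
#' `FE-1 ... FE-k` by descending member count, ties broken by the
#' lexicographic order of the triple, so numbering is deterministic.
#'
#' @param guilds guild-assignment table (see [validate_guild_table()]).
#' @return A data.frame of class `fe_catalog` with columns `entity_id`,
#'   `trophic`, `habitat`, `tolerance`, `n_species`, and a list-column
#'   `members` of species ids.
#' @examples
#' g <- data.frame(species_id = c("a", "b", "c"),
#'                 trophic = c("Omn", "Omn", "Ins"),
#'                 habitat = c("WC", "WC", "RB"),
#'                 tolerance = c("IS", "IS", "SS"),
#'                 native = TRUE)
#' build_entities(g)
#' @export
build_entities <- function(guilds) {
  guilds <- validate_guild_table(guilds)
  key <- paste(guilds$trophic, guilds$habitat, guilds$tolerance, sep = "|")
  members <- split(guilds$species_id, key)
  triples <- do.call(rbind, strsplit(names(members), "|", fixed = TRUE))
  n_sp <- lengths(members)
  ord <- order(-n_sp, triples[, 1L], triples[, 2L], triples[, 3L],
               method = "radix")
  cat <- data.frame(
    entity_id = paste0("FE-", seq_along(ord)),
    trophic = triples[ord, 1L],
    habitat = triples[ord, 2L],
    tolerance = triples[ord, 3L],
    n_species = unname(n_sp[ord]),
    stringsAsFactors = FALSE
  )
  cat$members <- unname(members[ord])
  class(cat) <- c("fe_catalog", "data.frame")
  cat
}

#' @export
print.fe_catalog <- function(x, ...) {
  cat("Fish ecological entity catalog:", nrow(x), "entities,",
      sum(x$n_species), "species\n")
  show <- x
  show$members <- vapply(x$members, paste, "", collapse = ";")
  print.data.frame(show, row.names = FALSE, ...)
  invisible(x)
}

#' Validate a site x species abundance matrix
#'
#' @param abund numeric matrix, sites in rows (rownames = site ids), species
#'   in columns (colnames = species ids); non-negative integer counts.
#' @param anomalies optional matrix of the same shape counting individuals
#'   with external anomalies; must satisfy `anomalies <= abund` elementwise.
#' @return invisibly, the abundance matrix.
#' @export
validate_abundance <- function(abund, anomalies = NULL) {
  assert_that(is.matrix(abund) && is.numeric(abund), "abundance must be a numeric matrix")
  assert_that(!is.null(rownames(abund)) && !is.null(colnames(abund)),
              "abundance matrix needs site rownames and species colnames")
  assert_that(all(abund >= 0) && all(abund == floor(abund)),
              "abundance counts must be non-negative integers")
  if (!is.null(anomalies)) {
    assert_that(identical(dim(anomalies), dim(abund)),
                "anomalies matrix must match abundance shape")
    assert_that(all(anomalies >= 0) && all(anomalies <= abund),
                "anomalies must satisfy 0 <= anomalies <= counts")
  }
  invisible(abund)
}

#' Aggregate species abundances to entity abundances
#'
#' Sums member-species counts within each entity, per site. Individuals are
#' conserved: row totals of the result equal row totals of the input.
#'
#' @param abund site x species count matrix.
#' @param catalog an `fe_catalog` from [build_entities()].
#' @return site x entity count matrix with the catalog attached as
#'   attribute `catalog`.
#' @export
entity_abundance <- function(abund, catalog) {
  validate_abundance(abund)
  all_members <- unlist(catalog$members, use.names = FALSE)
  orphans <- setdiff(colnames(abund), all_members)
  if (length(orphans) > 0) {
    stop_sh("species absent from entity catalog: ",
            paste(orphans, collapse = ", "),
            class = "streamhealth_validation_error")
  }
  em <- vapply(catalog$members, function(m) {
    m <- intersect(m, colnames(abund))
    if (length(m) == 0) numeric(nrow(abund))
    else rowSums(abund[, m, drop = FALSE])
  }, numeric(nrow(abund)))
  em <- matrix(em, nrow = nrow(abund),
               dimnames = list(rownames(abund), catalog$entity_id))
  stopifnot(sum(em) == sum(abund))   # conservation, cheap internal check
  attr(em, "catalog") <- catalog
  em
}

#' Relative abundance of entities
#'
#' Percentage of individuals belonging to each entity within a scope unit:
#' each site, each site group (e.g. spatial chemical cluster), or the
#' entire region. Reported to one decimal, half-up.
#'
#' @param em site x entity count matrix.
#' @param scope `"per_site"`, `"per_group"` or `"entire"`.
#' @param groups for `per_group`, a vector of group labels, one per site.
#' @param digits decimals to round to (half-up); `NULL` for unrounded.
#' @return matrix of percentages: scope units in rows, entities in columns.
#' @export
relative_abundance <- function(em, scope = c("per_site", "per_group", "entire"),
                               groups = NULL, digits = 1) {
  scope <- match.arg(scope)
  unit_counts <- switch(scope,
    per_site = em,
    per_group = {
      assert_that(!is.null(groups) && length(groups) == nrow(em),
                  "per_group scope needs one group label per site")
      rowsum(em, group = as.character(groups))
    },
    entire = matrix(colSums(em), nrow = 1,
                    dimnames = list("entire", colnames(em)))
  )
  tot <- rowSums(unit_counts)
  zero <- tot == 0
  if (any(zero)) {
    stop_sh("relative abundance undefined for all-zero scope unit(s): ",
            paste(rownames(unit_counts)[zero], collapse = ", "),
            class = "streamhealth_validation_error")
  }
  ra <- 100 * sweep(unit_counts, 1, tot, "/")
  if (!is.null(digits)) ra <- round_half_up(ra, digits)
  ra
}

#' Entity occupancy
#'
#' Percentage of sites at which each entity was observed (count > 0).
#'
#' @inheritParams relative_abundance
#' @param digits decimals (half-up).
#' @return named numeric vector, one value per entity, in `[0, 100]`.
#' @export
entity_occupancy <- function(em, digits = 1) {
  assert_that(nrow(em) >= 1, "occupancy needs at least one site")
  round_half_up(100 * colMeans(em > 0), digits)
}

#' Entity richness
#'
#' Number of entities with a positive total count, regionally or within
#' groups of sites.
#'
#' @inheritParams relative_abundance
#' @param groups optional site group labels; when given, richness is
#'   returned per group (plus the regional pool under `"entire"`).
#' @return named integer vector of richness values.
#' @export
entity_richness <- function(em, groups = NULL) {
  regional <- sum(colSums(em) > 0)
  if (is.null(groups)) {
    return(c(entire = regional))
  }
  assert_that(length(groups) == nrow(em),
              "grouping must label every site")
  by_grp <- rowsum(em, group = as.character(groups))
  c(apply(by_grp > 0, 1, sum), entire = regional)
}
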