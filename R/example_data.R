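#' Bundled regional survey summary
#'
#' Published summary of a regional fish survey of 41 wadable stream sites:
#' 19 fish ecological entities built from 50 species, with per-entity total
#' numbers of individuals (TNI), region-wide relative abundance (`ra_pct`),
#' and site occupancy (`obs_pct`), plus per-spatial-cluster TNI totals and
#' entity richness. These printed totals serve as worked-example inputs for
#' [relative_abundance()]-style arithmetic and as the reference entity-size
#' multiset for [default_guild_plan()].
#'
#' @return `regional_fe_summary()`: data.frame of 19 entities;
#'   `regional_cluster_tni()`: data.frame of 5 spatial clusters.
#' @export
regional_fe_summary <- function() {
  utils::read.csv(system.file("extdata", "regional_fe_summary.csv",
                              package = "streamhealth"),
                  stringsAsFactors = FALSE)
}

#' @rdname regional_fe_summary
#' @export
regional_cluster_tni <- function() {
  utils::read.csv(system.file("extdata", "regional_cluster_tni.csv",
                              package = "streamhealth"),
                  stringsAsFactors = FALSE)
}
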