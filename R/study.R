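# Desk-scale reconstruction of the study's delimitation inputs from its
# printed tables: per-clade specimen counts (marker-coverage table), the
# method/marker partitions described in the results, and the evidence the
# reconciliation argued from (shared nuclear haplotypes, COI divergences,
# indel support). Specimen ids are synthetic placeholders ("<k>_<clade>");
# what matters for the consensus is block structure and counts.

study_clade_counts <- function() {
  path <- system.file("extdata", "terebellides_marker_coverage.csv",
                      package = "haplodelim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

study_specimen_ids <- function() {
  counts <- study_clade_counts()
  ids <- list()
  k <- 0L
  for (i in seq_len(nrow(counts))) {
    cl <- as.character(counts$clade[i])
    n <- counts$n_specimens[i]
    ids[[cl]] <- sprintf("%d_%s", k + seq_len(n), cl)
    k <- k + n
  }
  ids
}

#' Reference partition: the 28 mitochondrial haplotype networks
#'
#' One block per clade, sized by the study's per-clade specimen counts
#' (placeholder specimen ids).
#'
#' @return A `species_partition` with 28 blocks named "1".."28".
#' @export
study_reference_partition <- function() {
  species_partition(study_specimen_ids(), method = "TCS", marker = "COI")
}

merge_blocks <- function(ids, groups) {
  out <- ids
  for (g in groups) {
    out[[paste(g, collapse = "/")]] <- unlist(ids[g], use.names = FALSE)
    out[g] <- NULL
  }
  out
}

#' The other method/marker partitions reported by the study
#'
#' Encodes the disagreements the results describe: the nuclear analyses merge
#' 5+16, 20+28 and 4+26+27 (the salsa-aligned nuclear network additionally
#' merges 12+13, and its GMYC connects 21 with 20/28), and the mitochondrial
#' GMYC splits clade 8 while merging 20 with 28.
#'
#' @return Named list of `species_partition`s.
#' @export
study_other_partitions <- function() {
  ids <- study_specimen_ids()
  split8 <- ids[["8"]][seq(length(ids[["8"]]) - 5L, length(ids[["8"]]))]
  gmyc_coi <- ids
  gmyc_coi[["8"]] <- setdiff(ids[["8"]], split8)
  gmyc_coi[["8b"]] <- split8
  gmyc_coi <- merge_blocks(gmyc_coi, list(c("20", "28")))
  list(
    gmyc_coi = species_partition(gmyc_coi, "GMYC", "COI"),
    tcs_its2x = species_partition(
      merge_blocks(ids, list(c("5", "16"), c("20", "28"),
                             c("4", "26", "27"))), "TCS", "ITS2x"),
    tcs_its2s = species_partition(
      merge_blocks(ids, list(c("5", "16"), c("20", "28"),
                             c("4", "26", "27"), c("12", "13"))),
      "TCS", "ITS2s"),
    gmyc_its2x = species_partition(
      merge_blocks(ids, list(c("5", "16"), c("20", "28"),
                             c("4", "26", "27"))), "GMYC", "ITS2x"),
    gmyc_its2s = species_partition(
      merge_blocks(ids, list(c("20", "28", "21"), c("4", "26", "27"))),
      "GMYC", "ITS2s"))
}

#' Evidence table for the study's candidate lumps
#'
#' One row per pair of reference clades merged by at least one analysis, with
#' the printed evidence: shared nuclear haplotypes, minimum interspecific COI
#' distance (percent), indel support, and specimen counts (for a lineage that
#' an earlier rule lumps, the pooled count).
#'
#' @return data.frame in the layout [reconcile()] expects.
#' @export
study_evidence <- function() {
  counts <- study_clade_counts()
  n_of <- stats::setNames(counts$n_specimens, counts$clade)
  ev <- rbind(
    # clades 20 and 28: shared ITS2 haplotype, 16 COI steps over 621 sites
    data.frame(a = "20", b = "28", shares_nuclear_haplotype = TRUE,
               coi_min_inter = 100 * 16 / 621, indel_support = FALSE,
               n_a = n_of[["20"]], n_b = n_of[["28"]]),
    data.frame(a = "12", b = "13", shares_nuclear_haplotype = FALSE,
               coi_min_inter = 8.2, indel_support = TRUE,
               n_a = n_of[["12"]], n_b = n_of[["13"]]),
    data.frame(a = "5", b = "16", shares_nuclear_haplotype = FALSE,
               coi_min_inter = 12.3, indel_support = TRUE,
               n_a = n_of[["5"]], n_b = n_of[["16"]]),
    # 21 versus the (already pooled) species 20/28
    data.frame(a = "21", b = "20", shares_nuclear_haplotype = FALSE,
               coi_min_inter = 12.1, indel_support = TRUE,
               n_a = n_of[["21"]], n_b = n_of[["20"]] + n_of[["28"]]),
    data.frame(a = "4", b = "26", shares_nuclear_haplotype = FALSE,
               coi_min_inter = 9.9, indel_support = FALSE,
               n_a = n_of[["4"]], n_b = n_of[["26"]]),
    data.frame(a = "4", b = "27", shares_nuclear_haplotype = FALSE,
               coi_min_inter = 11.1, indel_support = FALSE,
               n_a = n_of[["4"]], n_b = n_of[["27"]]),
    data.frame(a = "26", b = "27", shares_nuclear_haplotype = FALSE,
               coi_min_inter = 13.3, indel_support = FALSE,
               n_a = n_of[["26"]], n_b = n_of[["27"]]))
  rownames(ev) <- NULL
  ev
}

#' Split evidence for the study (the mitochondrial GMYC split of clade 8)
#' @return data.frame in the layout [reconcile()] expects.
#' @export
study_split_evidence <- function() {
  data.frame(block = "8", n_methods_splitting = 1L, steps = 7L,
             connection_limit = connection_limit(658),
             nuclear_support = FALSE, stringsAsFactors = FALSE)
}

#' Run the full consensus on the study's printed-table evidence
#'
#' @param rules rule thresholds (defaults reproduce the published outcome).
#' @return A `consensus_result` (27 species, bounds 25-27 under defaults).
#' @export
study_consensus <- function(rules = reconciliation_rules()) {
  reconcile(study_reference_partition(), study_other_partitions(),
            study_evidence(), study_split_evidence(), rules)
}
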