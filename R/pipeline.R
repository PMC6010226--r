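#' Run the full delimitation pipeline
#'
#' Orchestrates the stages end to end on a data bundle: registry accounting
#' over the site table; haplotype collapsing per marker; uncorrected distance
#' summaries and barcode gap; statistical-parsimony networks (mitochondrial
#' networks are the reference species hypotheses); single-threshold GMYC on a
#' UPGMA clock tree of the unique mitochondrial haplotypes; and the
#' rule-based consensus of all partitions, with evidence (shared nuclear
#' haplotypes, COI divergence, sample sizes) computed from the data.
#'
#' @param data a `synthetic_dataset`, or a list with elements `alignments`
#'   (list with `coi`, `its2` `marker_alignment`s) and `sites` (site table).
#' @param connection_probability parsimony confidence (default 0.95).
#' @param support_cutoff GMYC ensemble support cutoff (default 0.9).
#' @param rules consensus thresholds from [reconciliation_rules()].
#' @param out_dir optional directory; when given, stage tables are persisted
#'   as TSV/JSON and networks as GraphML.
#' @return A `pipeline_report` list with per-stage summaries.
#' @export
run_pipeline <- function(data, connection_probability = 0.95,
                         support_cutoff = 0.9,
                         rules = reconciliation_rules(),
                         out_dir = NULL) {
  if (is.null(data$sites)) stop("pipeline input needs a site table")
  aln_coi <- data$alignments$coi
  aln_its2 <- data$alignments$its2
  sites <- data$sites

  imap <- identity_merge_map(unique(unlist(sites$clades)))
  registry <- list(totals = registry_totals(sites),
                   regional = regional_summary(sites, imap),
                   cooccurrence = cooccurrence_stats(sites, imap),
                   depth = depth_profile(sites, imap))
  if (is.null(aln_coi)) {
    # biogeographic section alone: complete without any sequence data
    report <- structure(list(registry = registry, n_species = NULL),
                        class = "pipeline_report")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      reg <- registry$regional
      reg$species <- vapply(reg$species, paste, character(1), collapse = ",")
      utils::write.table(reg, file.path(out_dir, "regional_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    return(report)
  }

  haps_coi <- collapse_identical(aln_coi)
  haps_its2 <- if (!is.null(aln_its2)) collapse_identical(aln_its2) else NULL

  clades <- sort(unique(id_clade(aln_coi$ids)))
  dist_coi <- if (length(clades) >= 2L) summarize_distances(aln_coi) else NULL
  gap <- if (!is.null(dist_coi)) barcode_gap(dist_coi) else NULL

  net_coi <- build_networks(haps_coi, connection_probability)
  ref <- networks_to_partition(net_coi)
  names(ref$blocks) <- make.unique(vapply(ref$blocks, function(b) {
    cl <- sort(unique(id_clade(b)))
    paste(cl, collapse = "&")
  }, character(1)), sep = "_")
  ref$method <- "TCS"; ref$marker <- "COI"

  others <- list()
  net_its2 <- NULL
  if (!is.null(haps_its2)) {
    net_its2 <- build_networks(haps_its2, connection_probability)
    p <- networks_to_partition(net_its2)
    p$method <- "TCS"; p$marker <- "ITS2"
    others$tcs_its2 <- p
  }
  upgma <- upgma_tree(p_distance_matrix(haps_coi$representatives))
  gmyc <- gmyc_fit(upgma)
  gmyc_part <- expand_haplotype_partition(gmyc$entities, haps_coi)
  gmyc_part$method <- "GMYC"; gmyc_part$marker <- "COI"
  others$gmyc_coi <- gmyc_part
  support <- gmyc_support(upgma, cutoff = support_cutoff)

  evidence <- pair_evidence(ref, others, aln_coi, aln_its2)
  consensus <- reconcile(ref, others, evidence, rules = rules)

  report <- structure(list(
    registry = registry,
    haplotypes = list(coi = n_haplotypes(haps_coi),
                      its2 = if (!is.null(haps_its2)) n_haplotypes(haps_its2)),
    distances = dist_coi, barcode_gap = gap,
    networks = list(coi = net_coi, its2 = net_its2),
    gmyc = gmyc, gmyc_support = support,
    reference_partition = ref, other_partitions = others,
    evidence = evidence, consensus = consensus,
    n_species = consensus$n_species), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  if (is.null(x$n_species)) {
    cat("<pipeline_report> biogeographic section only:",
        x$registry$totals$n_sites, "sites,",
        x$registry$totals$n_specimens, "specimens\n")
    return(invisible(x))
  }
  cat("<pipeline_report>", n_networks(x$networks$coi),
      "mitochondrial networks;", x$gmyc$n_entities, "GMYC entities;",
      "consensus:", x$n_species, "species (bounds",
      x$consensus$lower_bound, "-", x$consensus$upper_bound, ")\n")
  invisible(x)
}

# lift a partition of haplotype representatives to a specimen partition
expand_haplotype_partition <- function(rep_blocks, haps) {
  rep_ids <- haps$representatives$ids
  blocks <- lapply(rep_blocks, function(b)
    sort(unlist(haps$members[match(b, rep_ids)])))
  species_partition(blocks)
}

# evidence rows for every pair of reference blocks merged by another method
pair_evidence <- function(ref, others, aln_coi, aln_its2) {
  rb <- block_of(ref)
  cand <- list()
  for (p in others) {
    shared <- intersect(ref$universe, p$universe)
    for (b in p$blocks) {
      refs <- unique(rb[intersect(b, shared)])
      if (length(refs) >= 2L) {
        prs <- utils::combn(sort(refs), 2L)
        for (k in seq_len(ncol(prs)))
          cand[[paste(prs[, k], collapse = "+")]] <- prs[, k]
      }
    }
  }
  if (!length(cand))
    return(data.frame(a = character(0), b = character(0),
                      shares_nuclear_haplotype = logical(0),
                      coi_min_inter = numeric(0), indel_support = logical(0),
                      n_a = integer(0), n_b = integer(0)))
  d <- p_distance_matrix(aln_coi)
  its2_str <- if (!is.null(aln_its2))
    stats::setNames(apply(aln_its2$mat, 1, paste, collapse = ""),
                    aln_its2$ids)
  do.call(rbind, lapply(cand, function(pr) {
    ia <- ref$blocks[[pr[1]]]; ib <- ref$blocks[[pr[2]]]
    ca <- intersect(ia, rownames(d)); cb <- intersect(ib, rownames(d))
    dmin <- if (length(ca) && length(cb))
      min(d[ca, cb, drop = FALSE], na.rm = TRUE) * 100 else NA_real_
    shares <- FALSE
    if (!is.null(its2_str)) {
      sa <- its2_str[intersect(ia, names(its2_str))]
      sb <- its2_str[intersect(ib, names(its2_str))]
      shares <- length(intersect(sa, sb)) > 0L
    }
    data.frame(a = pr[1], b = pr[2], shares_nuclear_haplotype = shares,
               coi_min_inter = dmin, indel_support = FALSE,
               n_a = length(ia), n_b = length(ib),
               stringsAsFactors = FALSE)
  }))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  reg <- report$registry$regional
  reg$species <- vapply(reg$species, paste, character(1), collapse = ",")
  tsv(reg, "regional_summary.tsv")
  if (!is.null(report$distances))
    tsv(report$distances$per_clade, "distance_summary.tsv")
  tsv(report$consensus$decisions, "consensus_decisions.tsv")
  export_network(report$networks$coi, file.path(out_dir, "coi_networks.graphml"))
  jsonlite::write_json(list(
    n_species = report$n_species,
    lower_bound = report$consensus$lower_bound,
    upper_bound = report$consensus$upper_bound,
    blocks = report$consensus$final_partition$blocks),
    file.path(out_dir, "consensus.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Figures for the biogeographic and bathymetric accounting
#'
#' Writes (when ggplot2 is available) a log-scale depth-distribution chart,
#' per-region rarefaction curves, and a per-region species-composition table;
#' always returns the underlying numbers so they can be cross-checked against
#' the stage outputs.
#'
#' @param sites a site table.
#' @param out_dir output directory for plot files.
#' @param merge clade-to-species merge map (default merges 20/28).
#' @return List with `depth` (per-site depth data), `rarefaction` (per-region
#'   curves), `composition` (per-region species tallies) and `files`.
#' @export
make_figures <- function(sites, out_dir = NULL, merge = NULL) {
  spec <- expand_specimens(sites, merge)
  comp <- as.data.frame(table(region = spec$region, species = spec$species),
                        stringsAsFactors = FALSE)
  comp <- comp[comp$Freq > 0, ]
  rar <- do.call(rbind, lapply(split(spec$species, spec$region),
    function(v) {
      rc <- rarefaction_curve(v)
      rc$region <- NULL
      rc
    }))
  rar$region <- rep(names(split(spec$species, spec$region)),
                    vapply(split(spec$species, spec$region), length,
                           integer(1)))
  files <- character(0)
  if (!is.null(out_dir) && requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    g1 <- ggplot2::ggplot(sites, ggplot2::aes(x = region, y = depth_min)) +
      ggplot2::geom_point(ggplot2::aes(size = sample_size), alpha = 0.6) +
      ggplot2::scale_y_log10() + ggplot2::coord_flip() +
      ggplot2::labs(y = "depth (m, log scale)", x = NULL)
    f1 <- file.path(out_dir, "depth_distribution.pdf")
    ggplot2::ggsave(f1, g1, width = 7, height = 5)
    g2 <- ggplot2::ggplot(rar, ggplot2::aes(n, expected_species,
                                            colour = region)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "specimens sampled", y = "expected species")
    f2 <- file.path(out_dir, "rarefaction.pdf")
    ggplot2::ggsave(f2, g2, width = 7, height = 5)
    files <- c(f1, f2)
  }
  list(depth = sites[, c("site_id", "region", "depth_min", "depth_max",
                         "sample_size")],
       rarefaction = rar, composition = comp, files = files)
}
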