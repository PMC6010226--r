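#' Construct a species partition
#'
#' A partition of specimen ids into disjoint blocks, tagged with the method
#' and marker that produced it.
#'
#' @param blocks named (or unnamed) list of character vectors; blocks must be
#'   disjoint and nonempty.
#' @param method e.g. "TCS", "GMYC", "STACEY-posterior", "consensus".
#' @param marker e.g. "COI", "ITS2x", "ITS2s", "combined".
#' @return A `species_partition`.
#' @export
species_partition <- function(blocks, method = "unknown", marker = "unknown") {
  blocks <- lapply(blocks, function(b) sort(unname(as.character(b))))
  if (any(lengths(blocks) == 0L)) stop("empty block")
  ids <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(ids)) stop("blocks are not disjoint")
  if (is.null(names(blocks)))
    names(blocks) <- paste0("b", seq_along(blocks))
  structure(list(blocks = blocks, method = method, marker = marker,
                 universe = sort(ids)), class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("<species_partition>", x$method, "/", x$marker, ":",
      length(x$blocks), "blocks,", length(x$universe), "specimens\n")
  invisible(x)
}

#' Number of blocks in a partition
#' @param p a `species_partition`.
#' @return Integer count.
#' @export
n_blocks <- function(p) length(p$blocks)

restrict_partition <- function(p, ids) {
  blocks <- lapply(p$blocks, intersect, ids)
  blocks <- blocks[lengths(blocks) > 0L]
  species_partition(blocks, p$method, p$marker)
}

block_of <- function(p) {
  lab <- rep(names(p$blocks), lengths(p$blocks))
  stats::setNames(lab, unlist(p$blocks))
}

#' Fig 5-style agreement coding against a reference partition
#'
#' For every block of the reference partition (restricted to the shared
#' specimen universe): `identical` if the block is also a block of the other
#' partition, `finer` if the other partition splits it, `coarser` if the
#' other partition merges it with material from other reference blocks
#' (splitting and merging at once also codes `coarser`, the more inclusive
#' reading).
#'
#' @param reference,other `species_partition`s.
#' @return data.frame with columns `block` and `code`.
#' @export
agreement_code <- function(reference, other) {
  shared <- intersect(reference$universe, other$universe)
  if (!length(shared)) stop("no shared specimens between partitions")
  ref <- restrict_partition(reference, shared)
  oth <- restrict_partition(other, shared)
  ob <- block_of(oth)
  codes <- vapply(names(ref$blocks), function(bn) {
    b <- ref$blocks[[bn]]
    hit <- unique(ob[b])
    merged <- any(vapply(oth$blocks[hit],
                         function(x) length(setdiff(x, b)) > 0, logical(1)))
    if (merged) "coarser" else if (length(hit) > 1L) "finer" else "identical"
  }, character(1))
  data.frame(block = names(ref$blocks), code = unname(codes),
             stringsAsFactors = FALSE)
}

canonical_partition_key <- function(blocks) {
  paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = ","),
                    character(1))), collapse = "|")
}

#' Frequencies of distinct partitions in a posterior sample
#'
#' Canonicalizes each sampled partition (block order and within-block order
#' are irrelevant) and tabulates relative frequencies. Used to summarize
#' posterior samples of species partitions from Bayesian multispecies
#' coalescent analyses.
#'
#' @param samples list of partitions; each either a `species_partition` or a
#'   bare list of id vectors.
#' @return data.frame with `partition` (canonical key), `n_blocks`, `count`,
#'   `frequency` (summing to 1), ordered by decreasing frequency.
#' @export
posterior_partition_frequencies <- function(samples) {
  if (!length(samples)) stop("no samples")
  keys <- vapply(samples, function(s) {
    blocks <- if (inherits(s, "species_partition")) s$blocks else s
    canonical_partition_key(blocks)
  }, character(1))
  tb <- table(keys)
  out <- data.frame(partition = names(tb),
                    n_blocks = lengths(strsplit(names(tb), "|", fixed = TRUE)),
                    count = as.integer(tb),
                    frequency = as.numeric(tb) / length(samples),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$partition), , drop = FALSE]
}

#' Read a posterior species-partition log
#'
#' Simple whitespace/CSV dialect: one sample per row, one column per specimen
#' (header row of specimen ids), each cell an arbitrary species label; labels
#' only matter within a row.
#'
#' @param path log file.
#' @return List of partitions suitable for
#'   [posterior_partition_frequencies()].
#' @export
read_partition_log <- function(path) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  lapply(seq_len(nrow(x)), function(i)
    split(colnames(x), as.character(unlist(x[i, ]))))
}

#' Default reconciliation rule thresholds
#'
#' The defaults are anchored in the study's printed distance tables: the
#' largest pooled intraspecific COI distance observed is 3.4% and the
#' smallest interspecific 8.2%, so pairs below 4% COI divergence with shared
#' nuclear haplotypes are lumpable and pairs at or above 8% are kept apart.
#'
#' @param well_sampled_n specimens needed to call a lineage well sampled
#'   (default 10).
#' @param lump_if_shared_nuclear_and_coi_below percent (default 4).
#' @param keep_separate_if_coi_above percent (default 8).
#' @param undersampled_flag_n flag lineages with fewer specimens (default 3).
#' @return List of thresholds.
#' @export
reconciliation_rules <- function(well_sampled_n = 10,
                                 lump_if_shared_nuclear_and_coi_below = 4,
                                 keep_separate_if_coi_above = 8,
                                 undersampled_flag_n = 3) {
  if (lump_if_shared_nuclear_and_coi_below >= keep_separate_if_coi_above)
    stop("lump threshold must be below keep-separate threshold")
  list(well_sampled_n = well_sampled_n,
       lump_if_shared_nuclear_and_coi_below = lump_if_shared_nuclear_and_coi_below,
       keep_separate_if_coi_above = keep_separate_if_coi_above,
       undersampled_flag_n = undersampled_flag_n)
}

#' Reconcile method/marker partitions into final species hypotheses
#'
#' Starts from the reference (mitochondrial-network) partition and applies an
#' ordered, auditable rule set to every disagreement raised by the other
#' partitions:
#' \describe{
#'   \item{R1}{accept every reference block as a species hypothesis.}
#'   \item{R2}{lump a pair of reference blocks when they share a nuclear
#'     haplotype, both are under-sampled (below `well_sampled_n`), and their
#'     COI divergence is within pooled intraspecific variation (below the
#'     lump threshold).}
#'   \item{R3}{reject a within-block split proposed by a single method with
#'     no nuclear support.}
#'   \item{R4}{keep a merged pair separate when the blocks share no nuclear
#'     haplotype and both are well sampled, or when COI divergence is at or
#'     above the keep-separate threshold, or when indels support them.}
#'   \item{R5}{flag pairs with an under-sampled side (below
#'     `undersampled_flag_n`) as uncertain; flagged pairs do not change the
#'     partition but widen the species-count bounds.}
#' }
#'
#' @param reference `species_partition` (blocks named by clade label).
#' @param others list of `species_partition`s from other methods/markers.
#' @param evidence data.frame with one row per candidate pair: columns `a`,
#'   `b` (reference block names), `shares_nuclear_haplotype` (logical),
#'   `coi_min_inter` (percent), `indel_support` (logical), `n_a`, `n_b`
#'   (specimen counts), and optionally `n_methods_merging`.
#' @param split_evidence optional data.frame for proposed splits: columns
#'   `block`, `n_methods_splitting`, `steps` (mutational steps between the
#'   split groups), `connection_limit`, `nuclear_support` (logical).
#' @param rules output of [reconciliation_rules()].
#' @return A `consensus_result`: list with `final_partition`, `n_species`,
#'   `lower_bound`, `upper_bound`, `decisions` (audit trail data.frame) and
#'   `flagged_pairs`.
#' @export
reconcile <- function(reference, others, evidence,
                      split_evidence = NULL,
                      rules = reconciliation_rules()) {
  blocks <- reference$blocks
  decisions <- list()
  note <- function(pair, action, rule, why)
    decisions[[length(decisions) + 1L]] <<- data.frame(
      pair = pair, action = action, rule = rule, evidence = why,
      stringsAsFactors = FALSE)
  # R1: every reference block is accepted up front
  note("(all reference blocks)", "accept", "R1",
       sprintf("%d mitochondrial networks accepted as starting hypotheses",
               length(blocks)))
  # candidate merges: pairs merged by at least one other partition
  merged_into <- stats::setNames(names(blocks), names(blocks))
  flagged <- list()
  for (i in seq_len(nrow(evidence))) {
    e <- evidence[i, ]
    pair <- paste0(e$a, "+", e$b)
    lumped <- FALSE
    if (isTRUE(e$shares_nuclear_haplotype) &&
        e$n_a < rules$well_sampled_n && e$n_b < rules$well_sampled_n &&
        e$coi_min_inter < rules$lump_if_shared_nuclear_and_coi_below) {
      note(pair, "lump", "R2", sprintf(
        "shared nuclear haplotype; n=%d and %d below %d; COI %.1f%% within pooled intraspecific variation",
        e$n_a, e$n_b, rules$well_sampled_n, e$coi_min_inter))
      merged_into[merged_into == merged_into[e$b]] <- merged_into[e$a]
      lumped <- TRUE
    } else if (!isTRUE(e$shares_nuclear_haplotype) &&
               e$n_a >= rules$well_sampled_n && e$n_b >= rules$well_sampled_n) {
      note(pair, "keep", "R4", sprintf(
        "no shared nuclear haplotypes; both well sampled (n=%d, %d)%s",
        e$n_a, e$n_b,
        if (isTRUE(e$indel_support)) "; indel events support separation" else ""))
    } else if (e$coi_min_inter >= rules$keep_separate_if_coi_above ||
               isTRUE(e$indel_support)) {
      note(pair, "keep", "R4", sprintf(
        "COI divergence %.1f%% at/above %.1f%%%s", e$coi_min_inter,
        rules$keep_separate_if_coi_above,
        if (isTRUE(e$indel_support)) "; indel support" else ""))
    } else {
      note(pair, "keep", "R4", "no lump rule fired; reference retained")
    }
    if (!lumped &&
        (e$n_a < rules$undersampled_flag_n || e$n_b < rules$undersampled_flag_n)) {
      note(pair, "flag-uncertain", "R5", sprintf(
        "under-sampled side (n=%d, %d below %d); species status uncertain",
        e$n_a, e$n_b, rules$undersampled_flag_n))
      flagged[[length(flagged) + 1L]] <- c(e$a, e$b)
    }
  }
  # R3: splits proposed within reference blocks
  if (!is.null(split_evidence)) for (i in seq_len(nrow(split_evidence))) {
    s <- split_evidence[i, ]
    if (s$n_methods_splitting <= 1L && !isTRUE(s$nuclear_support) &&
        s$steps <= s$connection_limit) {
      note(s$block, "reject-split", "R3", sprintf(
        "split proposed by a single method; %d steps within the %d-step connection limit; no nuclear support",
        s$steps, s$connection_limit))
    } else {
      note(s$block, "flag-uncertain", "R3", "split retained as uncertain")
      flagged[[length(flagged) + 1L]] <- c(s$block, paste0(s$block, "-split"))
    }
  }
  # assemble final partition from the merge map
  groups <- split(names(blocks), merged_into[names(blocks)])
  final_blocks <- lapply(groups, function(g) unlist(blocks[g], use.names = FALSE))
  names(final_blocks) <- vapply(groups, paste, character(1), collapse = "/")
  ord <- order(match(vapply(groups, `[`, character(1), 1), names(blocks)))
  final_blocks <- final_blocks[ord]
  final <- species_partition(final_blocks, method = "consensus",
                             marker = "combined")
  n_sp <- n_blocks(final)
  # bounds: flagged pairs could collapse (connected components of flag graph)
  reduction <- 0L
  if (length(flagged)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, flagged), directed = FALSE)
    reduction <- sum(igraph::components(g)$csize - 1L)
  }
  structure(list(final_partition = final, n_species = n_sp,
                 lower_bound = n_sp - reduction, upper_bound = n_sp,
                 decisions = do.call(rbind, decisions),
                 flagged_pairs = flagged),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>", x$n_species, "species (bounds",
      x$lower_bound, "-", x$upper_bound, ");",
      nrow(x$decisions), "logged decisions\n")
  invisible(x)
}

#' Replay a consensus audit trail
#'
#' Reconstructs the final partition from the reference partition and the
#' decision log alone, verifying audit completeness: every departure from the
#' reference must be recoverable from the logged decisions.
#'
#' @param reference the reference `species_partition`.
#' @param decisions the `decisions` data.frame of a `consensus_result`.
#' @return A `species_partition`.
#' @export
replay_decisions <- function(reference, decisions) {
  merged_into <- stats::setNames(names(reference$blocks),
                                 names(reference$blocks))
  lumps <- decisions[decisions$action == "lump", , drop = FALSE]
  for (p in lumps$pair) {
    ab <- strsplit(p, "+", fixed = TRUE)[[1]]
    merged_into[merged_into == merged_into[ab[2]]] <- merged_into[ab[1]]
  }
  groups <- split(names(reference$blocks), merged_into[names(reference$blocks)])
  blocks <- lapply(groups, function(g)
    unlist(reference$blocks[g], use.names = FALSE))
  names(blocks) <- vapply(groups, paste, character(1), collapse = "/")
  ord <- order(match(vapply(groups, `[`, character(1), 1),
                     names(reference$blocks)))
  species_partition(blocks[ord], method = "consensus", marker = "combined")
}
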