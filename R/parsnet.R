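#' Statistical-parsimony connection probability
#'
#' Probability that a chain of `j` mutational steps between two haplotypes is
#' parsimonious, i.e. that none of the `j` substitutions is superimposed on a
#' previously mutated site. Substitutions are modelled as landing uniformly on
#' the `2 * length` site-lineage slots of the diverging pair, so the i-th
#' substitution is superimposed with probability `(i - 1) / (2 * length)`:
#' \deqn{P_j = \prod_{i=1}^{j} \left(1 - \frac{i-1}{2m}\right).}
#' This sequential-superimposition estimator follows the statistical-parsimony
#' logic of the TCS approach and reproduces published 95% limits at typical
#' marker lengths (about 9 steps near 420 bp); `fixed_limit` in
#' [connection_limit()] replays a published limit exactly.
#'
#' @param j number of mutational steps.
#' @param length alignment length in sites.
#' @return Probability in (0, 1].
#' @export
parsimony_probability <- function(j, length) {
  stopifnot(j >= 0, length >= 1)
  i <- seq_len(j)
  prod(pmax(0, 1 - (i - 1) / (2 * length)))
}

#' Connection limit at a given parsimony confidence
#'
#' Largest number of mutational steps whose connection probability is at
#' least `connection_probability` (the classic 95% connection limit).
#'
#' @param alignment_length alignment length in sites.
#' @param connection_probability required parsimony probability
#'   (default 0.95).
#' @param fixed_limit optional integer overriding the computed limit, to
#'   replay a published limit exactly.
#' @return Integer step limit (>= 1).
#' @export
connection_limit <- function(alignment_length, connection_probability = 0.95,
                             fixed_limit = NULL) {
  if (!is.null(fixed_limit)) return(as.integer(fixed_limit))
  stopifnot(alignment_length >= 1,
            connection_probability > 0, connection_probability < 1)
  j <- 1L
  while (parsimony_probability(j + 1L, alignment_length) >= connection_probability)
    j <- j + 1L
  j
}

msn_reduce <- function(edges) {
  # minimum-spanning network: process edges by increasing step count; keep an
  # edge iff its endpoints are not yet connected using strictly smaller steps
  # (all ties at the connecting step count are kept - network, not tree)
  if (nrow(edges) == 0L) return(edges)
  edges <- edges[order(edges$steps, edges$from, edges$to), , drop = FALSE]
  nodes <- unique(c(edges$from, edges$to))
  comp <- stats::setNames(seq_along(nodes), nodes)
  keep <- logical(nrow(edges))
  for (s in unique(edges$steps)) {
    sel <- which(edges$steps == s)
    keep[sel] <- comp[edges$from[sel]] != comp[edges$to[sel]]
    for (k in sel[keep[sel]]) {
      ca <- comp[edges$from[k]]; cb <- comp[edges$to[k]]
      if (ca != cb) comp[comp == cb] <- ca
    }
  }
  edges[keep, , drop = FALSE]
}

#' Build statistical-parsimony haplotype networks
#'
#' Connects every pair of haplotypes whose mutational step count (mismatches
#' over pairwise-determinate columns, gaps/missing uninformative) does not
#' exceed the connection limit; the connected components of this threshold
#' graph are the separate networks (putative species). Within each component
#' the displayed edge set is reduced to a minimum-spanning network, keeping
#' all edges tied at the connecting step count.
#'
#' @param haps a `haplotype_set` from [collapse_identical()].
#' @param connection_probability parsimony confidence (default 0.95).
#' @param fixed_limit optional published limit to replay.
#' @param site_of optional named vector mapping member ids to sites/regions,
#'   recorded as node composition attributes.
#' @return A `haplo_networks` object: list with `limit`, `nodes` (data.frame
#'   of haplotype id, multiplicity, component), `edges` (from, to, steps,
#'   component; MSN-reduced) and `all_edges` (full threshold graph).
#' @export
build_networks <- function(haps, connection_probability = 0.95,
                           fixed_limit = NULL, site_of = NULL) {
  reps <- haps$representatives
  if (n_sequences(reps) == 0L) stop("empty haplotype set")
  limit <- connection_limit(alignment_length(reps), connection_probability,
                            fixed_limit)
  steps <- p_distance_matrix(reps, steps = TRUE)
  ids <- reps$ids
  n <- length(ids)
  pairs <- which(upper.tri(steps) & steps <= limit, arr.ind = TRUE)
  all_edges <- data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                          steps = steps[pairs], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(all_edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  # deterministic component numbering by first occurrence in the input
  comp <- match(comp, unique(comp))
  nodes <- data.frame(haplotype = ids,
                      multiplicity = lengths(haps$members),
                      component = comp, stringsAsFactors = FALSE)
  if (!is.null(site_of)) {
    nodes$composition <- vapply(haps$members, function(m) {
      tb <- table(site_of[m])
      paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ";")
    }, character(1))
  }
  edges <- do.call(rbind, lapply(split(all_edges,
                                       comp[all_edges$from]), msn_reduce))
  if (is.null(edges)) edges <- all_edges
  rownames(edges) <- NULL
  edges$component <- comp[edges$from]
  structure(list(limit = limit, nodes = nodes, edges = edges,
                 all_edges = all_edges, members = haps$members),
            class = "haplo_networks")
}

#' @export
print.haplo_networks <- function(x, ...) {
  cat("<haplo_networks>", max(x$nodes$component), "networks over",
      nrow(x$nodes), "haplotypes (connection limit", x$limit, "steps)\n")
  invisible(x)
}

#' Number of separate networks
#' @param net a `haplo_networks`.
#' @return Integer count of connected components.
#' @export
n_networks <- function(net) max(net$nodes$component)

#' Species partition implied by network membership
#'
#' Labels every specimen by the connected component of its haplotype.
#'
#' @param net a `haplo_networks`.
#' @return A `species_partition` (see [species_partition()]) with blocks named
#'   `"net<k>"`.
#' @export
networks_to_partition <- function(net) {
  blocks <- lapply(seq_len(n_networks(net)), function(k) {
    hap <- net$nodes$haplotype[net$nodes$component == k]
    sort(unlist(net$members[match(hap, net$nodes$haplotype)]))
  })
  names(blocks) <- paste0("net", seq_along(blocks))
  species_partition(blocks, method = "TCS")
}

#' Export a haplotype network to GraphML or GML
#'
#' Nodes carry multiplicity (and composition when present), edges carry step
#' counts; readable back with `igraph::read_graph`.
#'
#' @param net a `haplo_networks`.
#' @param path output file.
#' @param format `"graphml"` or `"gml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to", "steps")],
                                     directed = FALSE, vertices = net$nodes)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
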