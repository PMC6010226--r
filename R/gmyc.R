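#' Read and validate an ultrametric tree
#'
#' Accepts newick or NEXUS. The tree must be rooted; polytomies are resolved
#' arbitrarily with zero-length branches (with a warning). Tip heights must
#' agree within `tolerance` (relative to tree height) unless `smooth = TRUE`,
#' in which case branch lengths are minimally adjusted by extending terminal
#' branches to the common height.
#'
#' @param path tree file.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (by extension).
#' @param tolerance relative ultrametricity tolerance (default 1e-6).
#' @param smooth stretch terminal branches to equal height (off by default).
#' @return An `ape::phylo` tree, binary and ultrametric.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus"),
                      tolerance = 1e-6, smooth = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus", "nxs", "tre", "trees")) "nexus" else "newick"
    if (format == "nexus") {
      first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
      if (!startsWith(first, "#NEXUS")) format <- "newick"
    }
  }
  tree <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_ultrametric(tree, tolerance, smooth)
}

validate_ultrametric <- function(tree, tolerance = 1e-6, smooth = FALSE) {
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree)
  }
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_len(ape::Ntip(tree))]
  H <- max(tipd)
  if (H <= 0) stop("tree has zero height")
  if (max(tipd) - min(tipd) > tolerance * H) {
    if (!smooth) stop("tree is not ultrametric within tolerance")
    term <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
    tree$edge.length[term] <- tree$edge.length[term] + (H - tipd)
  }
  tree
}

#' Node times (before present) of an ultrametric tree
#' @param tree an ultrametric `phylo`.
#' @return Numeric vector over all nodes (tips then internals), time before
#'   the present (tips ~ 0, root = tree height).
#' @export
node_times <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' UPGMA clock tree from a distance matrix
#'
#' Internal clock-tree substitute for externally inferred chronograms: heights
#' are half the merge distance, so two taxa at distance d sit at height d/2.
#'
#' @param d symmetric, zero-diagonal distance matrix (or `dist`).
#' @return Ultrametric `phylo`.
#' @export
upgma_tree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix not symmetric")
    if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
    d <- stats::as.dist(d)
  }
  tree <- phangorn::upgma(d)
  ape::multi2di(tree)
}

# interval table shared by all model variants: for each inter-event interval
# (sorted node times, root first), its length, total lineage count, and the
# per-entity lineage counts for every threshold candidate.
gmyc_tableau <- function(tree) {
  nt <- ape::Ntip(tree)
  times <- node_times(tree)
  internal <- (nt + 1L):(nt + tree$Nnode)
  # order by age, ties broken by topological depth so a parent always ranks
  # above its (possibly equally old) child
  topo_depth <- integer(nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    topo_depth[tree$edge[e, 2]] <- topo_depth[tree$edge[e, 1]] + 1L
  o <- order(-times[internal], topo_depth[internal])
  ts <- times[internal][o]                         # t_(1) root ... t_(n-1)
  ord_nodes <- internal[o]
  bounds <- c(ts, 0)
  k <- length(ts)                                   # n - 1 intervals
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  # crossing[e, j]: edge e spans interval j (the interval directly below the
  # j-th oldest internal node). Computed ordinally from node ranks so exactly
  # tied node heights (UPGMA trees) cannot break the lineage counts: an edge
  # is present in interval j iff its parent is among the j oldest internal
  # nodes and its child is a tip or ranks below them.
  rank_of <- integer(nt + tree$Nnode)
  rank_of[ord_nodes] <- seq_len(k)
  rank_of[seq_len(nt)] <- k + 1L                    # tips below everything
  rp <- rank_of[parent]; rc <- rank_of[child]
  crossing <- outer(rp, seq_len(k), "<=") & outer(rc, seq_len(k), ">")
  list(ntip = nt, times = times, sorted = ts, ord_nodes = ord_nodes,
       bounds = bounds, dt = bounds[-length(bounds)] - bounds[-1L],
       lineages = seq_len(k) + 1L, crossing = crossing,
       parent = parent, child = child)
}

# entity id per tree node for a candidate c (the c oldest internal nodes are
# speciation nodes); entities are the subtrees cut below speciation nodes.
# assumes the tree is in cladewise order (parents precede children in edge).
entity_assignment <- function(tree, tb, spec_nodes) {
  nt <- tb$ntip
  nn <- nt + tree$Nnode
  ent <- integer(nn)
  root <- nt + 1L
  next_id <- 1L
  ent[root] <- next_id
  for (e in seq_along(tb$parent)) {
    p <- tb$parent[e]; ch <- tb$child[e]
    if (p %in% spec_nodes) { next_id <- next_id + 1L; ent[ch] <- next_id }
    else ent[ch] <- ent[p]
  }
  # renumber by first tip occurrence for determinism
  tip_ent <- ent[seq_len(nt)]
  ent_map <- stats::setNames(seq_along(unique(tip_ent)), unique(tip_ent))
  list(node_entity = ent, tip_entity = unname(ent_map[as.character(tip_ent)]))
}

# profile log-likelihood of one exponential rate class: events with
# "sizes" x_e, intervals with sizes x_j and lengths dt_j, rate = lambda * x^p.
# lambda is profiled in closed form; returns max over p in p_range (or at
# fixed p). Contributes 0 when the class has no events.
class_profile_lnl <- function(x_event, x_int, dt_int, p = NULL,
                              p_range = c(0, 2)) {
  m <- length(x_event)
  if (m == 0L) return(list(lnl = 0, lambda = 0, p = if (is.null(p)) 1 else p))
  keep <- x_int > 0            # size-0 intervals carry no risk for this class
  x_int <- x_int[keep]; dt_int <- dt_int[keep]
  lnl_at <- function(pp) {
    W <- sum(x_int^pp * dt_int)
    if (W <= 0) return(-Inf)
    m * log(m / W) + pp * sum(log(x_event)) - m
  }
  if (!is.null(p)) {
    best_p <- p
  } else {
    op <- stats::optimize(lnl_at, interval = p_range, maximum = TRUE,
                          tol = 1e-9)
    best_p <- op$maximum
    for (pp in c(0, 1)) if (lnl_at(pp) > lnl_at(best_p)) best_p <- pp
  }
  W <- sum(x_int^best_p * dt_int)
  list(lnl = lnl_at(best_p), lambda = m / W, p = best_p)
}

# likelihood of one threshold candidate under a model variant.
#
# boundaries b_j are the sorted internal node times (b_1 = root, conditioned
# on); interval j lies directly below b_j. A Yule (speciation) event b_j pairs
# with the interval above it (j - 1 intervals have j lineages), a coalescent
# event b_j pairs with the interval below it, where the coalescing pair of
# lineages exists - so its class size is always positive.
gmyc_candidate_lnl <- function(tree, tb, c_spec, p_fixed = FALSE,
                               separate_lambda = FALSE) {
  k <- length(tb$sorted)                 # number of intervals
  spec_nodes <- if (c_spec > 0) tb$ord_nodes[seq_len(c_spec)] else integer(0)
  ea <- entity_assignment(tree, tb, spec_nodes)
  ent_of_edge <- ea$node_entity[tb$child]
  pfix <- if (p_fixed) 1 else NULL
  # yule class: events b_2..b_c, survival over intervals 1..c-1
  yule_int <- if (c_spec >= 2L) seq_len(c_spec - 1L) else integer(0)
  yule_x_ev <- if (c_spec >= 2L) seq(2L, c_spec) else numeric(0)
  yule <- class_profile_lnl(yule_x_ev, tb$lineages[yule_int],
                            tb$dt[yule_int], p = pfix)
  # coalescent class: survival over intervals c..k (1..k when c = 0);
  # events b_j for j in max(c+1, 2)..k, each paired with interval j
  coal_int <- if (c_spec == 0L) seq_len(k) else
              if (c_spec <= k) seq(c_spec, k) else integer(0)
  j_ev <- if (max(c_spec + 1L, 2L) <= k) seq(max(c_spec + 1L, 2L), k)
          else integer(0)
  n_ent <- max(ea$node_entity)
  lnl_coal <- 0
  coal_pars <- list()
  if (length(coal_int)) {
    counts <- vapply(coal_int, function(j)
      tabulate(ent_of_edge[tb$crossing[, j]], nbins = n_ent),
      integer(n_ent))
    counts <- matrix(counts, nrow = n_ent)
    S <- counts * (counts - 1L)
    pos <- match(j_ev, coal_int)
    if (separate_lambda) {
      ev_entity <- ea$node_entity[tb$ord_nodes[j_ev]]
      for (i in seq_len(n_ent)) {
        sel <- pos[ev_entity == i]
        cl <- class_profile_lnl(S[i, sel], S[i, ], tb$dt[coal_int], p = pfix)
        lnl_coal <- lnl_coal + cl$lnl
        coal_pars[[i]] <- cl
      }
    } else {
      Stot <- colSums(S)
      cl <- class_profile_lnl(Stot[pos], Stot, tb$dt[coal_int], p = pfix)
      lnl_coal <- cl$lnl
      coal_pars[[1]] <- cl
    }
  }
  list(lnl = yule$lnl + lnl_coal, yule = yule, coal = coal_pars,
       n_entities = max(ea$tip_entity), tip_entity = ea$tip_entity,
       spec_nodes = spec_nodes)
}

#' Fit the single-threshold general mixed Yule-coalescent model
#'
#' The null model treats the whole ultrametric tree as a single coalescent
#' class: waiting times between branching events are exponential with rate
#' \eqn{\lambda (\sum_i n_i(n_i-1))^p}. The alternative places a threshold
#' time T on the tree: branching events older than T follow a Yule class with
#' rate \eqn{\lambda_y k^{p_y}} (k = lineages), events younger than T follow
#' coalescent classes within the putative species (the subtrees crossing T),
#' with rate \eqn{\lambda_c (\sum_i n_i(n_i-1))^{p_c}}. Rate parameters are
#' profiled in closed form, exponents maximized by bounded one-dimensional
#' optimization, and T by exhaustive scan over the observed node heights. The
#' likelihood-ratio test uses a chi-squared reference with `df` degrees of
#' freedom (threshold plus the extra rate/exponent pair).
#'
#' @param tree ultrametric `phylo`, at least 3 tips; identical-haplotype
#'   duplicates (zero-length cherries) are collapsed before fitting.
#' @param df degrees of freedom for the likelihood-ratio test (default 3).
#' @param p_fixed fix both exponents at 1 instead of estimating them.
#' @param separate_lambda give each coalescent class its own rate.
#' @return A `gmyc_fit`: list with `lnl_null`, `lnl_alt`, `LR`, `p_value`,
#'   `threshold_time`, `n_entities`, `entities` (list of tip-label vectors),
#'   `support_nodes` (internal node ids on the speciation side), parameter
#'   estimates, and the scanned profile (`candidates`).
#' @export
gmyc_fit <- function(tree, df = 3, p_fixed = FALSE, separate_lambda = FALSE) {
  tree <- collapse_zero_cherries(tree)
  nt <- ape::Ntip(tree)
  if (nt < 3L) stop("need at least 3 distinct tips")
  tree <- validate_ultrametric(tree)
  tree <- ape::reorder.phylo(tree)       # cladewise: parents precede children
  tb <- gmyc_tableau(tree)
  k <- length(tb$sorted)
  null_fit <- gmyc_candidate_lnl(tree, tb, 0L, p_fixed = p_fixed,
                                 separate_lambda = FALSE)
  cand <- lapply(0:k, function(cc)
    gmyc_candidate_lnl(tree, tb, cc, p_fixed = p_fixed,
                       separate_lambda = separate_lambda))
  lnls <- vapply(cand, `[[`, numeric(1), "lnl")
  best <- which.max(lnls)
  alt <- cand[[best]]
  lnl_alt <- max(lnls)
  lnl_null <- null_fit$lnl
  LR <- max(0, 2 * (lnl_alt - lnl_null))
  ents <- split(tree$tip.label, alt$tip_entity)
  thr <- if (best == 1L) max(tb$sorted) else tb$sorted[best - 1L]
  structure(list(
    lnl_null = lnl_null, lnl_alt = lnl_alt, LR = LR,
    p_value = stats::pchisq(LR, df = df, lower.tail = FALSE),
    threshold_time = thr, n_entities = alt$n_entities,
    entities = unname(ents), tip_entity = alt$tip_entity,
    support_nodes = alt$spec_nodes,
    yule = alt$yule, coal = alt$coal,
    candidates = data.frame(n_speciation_nodes = 0:k, lnl = lnls),
    tree = tree), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("<gmyc_fit>", x$n_entities, "entities; lnL null", round(x$lnl_null, 3),
      "alt", round(x$lnl_alt, 3), "LR", round(x$LR, 3),
      "p", signif(x$p_value, 3), "\n")
  invisible(x)
}

collapse_zero_cherries <- function(tree, tol = 1e-12) {
  repeat {
    times <- node_times(tree)
    nt <- ape::Ntip(tree)
    H <- max(times)
    drop <- integer(0)
    for (node in (nt + 1L):(nt + tree$Nnode)) {
      if (times[node] > tol * max(H, 1)) next
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      tips <- kids[kids <= nt]
      if (length(tips) >= 2L) drop <- c(drop, tips[-1L])
    }
    if (!length(drop)) return(tree)
    if (ape::Ntip(tree) - length(drop) < 2L) return(tree)
    tree <- ape::drop.tip(tree, drop)
  }
}

#' Model-ensemble node support for GMYC delimitation
#'
#' Fits a configurable set of single-threshold variants (exponents free or
#' fixed at 1; shared or per-species coalescent rates), weights them by
#' Akaike weights, and scores each internal node by the weighted fraction of
#' variants whose maximum-likelihood delimitation places a speciation event
#' on it. Entities are then re-formed by cutting the tree only at nodes with
#' support at or above `cutoff`, so raising the cutoff can only merge
#' entities.
#'
#' @param tree ultrametric `phylo`.
#' @param cutoff support cutoff in (0, 1] (study default 0.9).
#' @param variants data.frame with logical columns `p_fixed`,
#'   `separate_lambda`; default is the four combinations.
#' @return List with `support` (data.frame: node, time, support),
#'   `n_entities`, `entities`, `weights`, and the per-variant fits.
#' @export
gmyc_support <- function(tree, cutoff = 0.9, variants = NULL) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (is.null(variants))
    variants <- expand.grid(p_fixed = c(FALSE, TRUE),
                            separate_lambda = c(FALSE, TRUE))
  if (nrow(variants) < 2L) stop("need >= 2 model variants")
  fits <- lapply(seq_len(nrow(variants)), function(i)
    gmyc_fit(tree, p_fixed = variants$p_fixed[i],
             separate_lambda = variants$separate_lambda[i]))
  tree <- fits[[1]]$tree
  npar <- vapply(seq_len(nrow(variants)), function(i) {
    f <- fits[[i]]
    base <- 1 + (if (variants$p_fixed[i]) 1 else 2)   # threshold + yule pars
    coal <- if (variants$separate_lambda[i]) length(f$coal) else 1
    base + coal + (if (variants$p_fixed[i]) 0 else 1)
  }, numeric(1))
  aic <- 2 * npar - 2 * vapply(fits, `[[`, numeric(1), "lnl_alt")
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)
  nt <- ape::Ntip(tree)
  nodes <- (nt + 1L):(nt + tree$Nnode)
  support <- vapply(nodes, function(nd)
    sum(w[vapply(fits, function(f) nd %in% f$support_nodes, logical(1))]),
    numeric(1))
  times <- node_times(tree)
  sup_nodes <- nodes[support >= cutoff]
  tb <- gmyc_tableau(tree)
  ea <- entity_assignment(tree, tb, sup_nodes)
  list(support = data.frame(node = nodes, time = times[nodes],
                            support = support),
       n_entities = max(ea$tip_entity),
       entities = unname(split(tree$tip.label, ea$tip_entity)),
       weights = w, fits = fits)
}
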