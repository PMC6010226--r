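#' Simulation configuration for the multi-species synthesizer
#'
#' Defaults emulate the statistical structure of the study system: a handful
#' of species under a Yule diversification process, deep mitochondrial
#' divergences (several percent) with shallow within-species coalescent
#' variation (about 1% for the mitochondrial marker), a 658-site indel-free
#' mitochondrial-like marker and a 290-420-site indel-bearing nuclear-like
#' marker, a strict clock of 2.2% divergence per My between lineages, ten
#' biogeographic regions with overlapping species-specific sampling weights,
#' and site depths spanning 8-4380 m.
#'
#' @param K number of species.
#' @param yule_rate speciation rate per lineage per My.
#' @param min_stem minimum My separating every speciation from the present
#'   (default 3.5, about 8% mitochondrial divergence under the default
#'   clock - the depth structure of the study system).
#' @param theta nuclear per-site coalescent diversity; the haploid
#'   mitochondrial marker uses `theta * mito_factor`.
#' @param mito_factor effective-size ratio of the mitochondrial marker
#'   (default 1/4).
#' @param n_per_species specimens sampled per species (recycled to K).
#' @param coi_length,its2_length marker lengths in sites; `its2_length` may
#'   be a range from which one length is drawn.
#' @param clock_rate substitutions/site/My per lineage (2.2% pairwise
#'   divergence per My = 0.011 per lineage).
#' @param indel_rate nuclear indel events per site per substitution unit.
#' @param indel_mean_length mean deletion length (geometric).
#' @param n_sites_per_region collecting sites available per region.
#' @param seed integer seed driving every random draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(K = 5, yule_rate = 0.12, min_stem = 3.5,
                       theta = 0.04, mito_factor = 0.25, n_per_species = 16,
                       coi_length = 658, its2_length = c(290, 420),
                       clock_rate = 0.011, indel_rate = 0.15,
                       indel_mean_length = 3, n_sites_per_region = 2,
                       seed = 1L) {
  stopifnot(K >= 1, theta > 0, coi_length > 0, all(its2_length > 0),
            yule_rate > 0, clock_rate > 0)
  structure(list(K = K, yule_rate = yule_rate, min_stem = min_stem,
                 theta = theta,
                 mito_factor = mito_factor,
                 n_per_species = rep_len(n_per_species, K),
                 coi_length = coi_length, its2_length = its2_length,
                 clock_rate = clock_rate, indel_rate = indel_rate,
                 indel_mean_length = indel_mean_length,
                 n_sites_per_region = n_sites_per_region,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a Yule species tree
#'
#' Forward pure-birth construction: with i lineages the waiting time to the
#' next speciation is exponential with rate `i * yule_rate`; the splitting
#' lineage is uniform. The present is placed one additional (unobserved)
#' waiting time after the K-th lineage appears. Branch lengths are in My.
#'
#' @param K number of tips (K = 1 gives a degenerate single-lineage tree).
#' @param yule_rate per-lineage speciation rate per My.
#' @param min_stem My by which every speciation predates the present; by
#'   memorylessness of the final waiting time this conditioning is exact
#'   (the present is placed `min_stem` plus an exponential stretch after the
#'   last split). Used to emulate complexes whose shallowest species pair is
#'   still deeply divergent.
#' @param seed optional seed.
#' @return Ultrametric `phylo` with tips "1".."K".
#' @export
simulate_species_tree <- function(K, yule_rate = 0.3, min_stem = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K >= 1, yule_rate > 0, min_stem >= 0)
  if (K == 1L) {
    h <- min_stem + stats::rexp(1, yule_rate)
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), edge.length = h,
               Nnode = 1L, tip.label = "1")
    class(tr) <- "phylo"
    return(tr)
  }
  rec_parent <- c(NA_integer_)          # node records: parent, birth time
  rec_birth <- c(0)
  active <- 1L
  t <- 0
  for (i in seq_len(K - 1L)) {
    t <- t + stats::rexp(1, i * yule_rate)
    j <- active[sample.int(length(active), 1L)]
    id1 <- length(rec_parent) + 1L; id2 <- id1 + 1L
    rec_parent <- c(rec_parent, j, j)
    rec_birth <- c(rec_birth, t, t)
    active <- c(setdiff(active, j), id1, id2)
  }
  present <- t + min_stem + stats::rexp(1, K * yule_rate)
  build_phylo_from_records(rec_parent, rec_birth, active, present)
}

# assemble an ape phylo from forward simulation records (internal records are
# lineages; active lineages become tips at `present`)
build_phylo_from_records <- function(parent, birth, active, present) {
  n_rec <- length(parent)
  is_tip <- seq_len(n_rec) %in% active
  K <- sum(is_tip)
  newid <- integer(n_rec)
  newid[is_tip] <- seq_len(K)
  newid[!is_tip] <- K + seq_len(n_rec - K)
  end_time <- rep(present, n_rec)
  for (r in seq_len(n_rec)) if (!is_tip[r]) {
    kid <- which(parent == r)[1]
    end_time[r] <- birth[kid]
  }
  edges <- which(!is.na(parent))
  edge <- cbind(newid[parent[edges]], newid[edges])
  edge.length <- end_time[edges] - birth[edges]
  tr <- list(edge = edge, edge.length = edge.length, Nnode = n_rec - K,
             tip.label = as.character(seq_len(K)))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr)
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Embeds a Kingman coalescent in the species tree: within each population
#' (species-tree branch) `j` gene lineages coalesce at rate
#' `j * (j - 1) / theta`, surviving lineages are handed to the parent
#' population, and the root population is run to a single lineage. With gene
#' branch lengths in the same units as the species tree, the expected
#' within-species pairwise distance is `theta` (pair coalescence time
#' `theta / 2` on each of two lineages).
#'
#' @param species_tree ultrametric `phylo` (tips = species labels).
#' @param theta per-site coalescent diversity of this marker.
#' @param n_per_species samples per species (recycled).
#' @param seed optional seed.
#' @return `phylo` gene tree; tips labelled `"g<k>_<species>"` so the clade
#'   suffix convention carries the true species.
#' @export
simulate_gene_tree <- function(species_tree, theta, n_per_species,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(theta > 0, all(n_per_species >= 1))
  K <- length(species_tree$tip.label)
  n_per_species <- rep_len(n_per_species, K)
  times <- node_times(species_tree)
  nt <- K
  # lineage = list(newick fragment, node time before present)
  counter <- 0L
  make_tips <- function(sp_label, n) {
    lapply(seq_len(n), function(i) {
      counter <<- counter + 1L
      list(nwk = sprintf("g%d_%s", counter, sp_label), time = 0)
    })
  }
  coalesce_in <- function(lins, t0, t1) {
    t <- t0
    while (length(lins) >= 2L) {
      j <- length(lins)
      w <- stats::rexp(1, j * (j - 1) / theta)
      if (t + w > t1) break
      t <- t + w
      pick <- sample.int(j, 2L)
      a <- lins[[pick[1]]]; b <- lins[[pick[2]]]
      merged <- list(nwk = sprintf("(%s:%.10f,%s:%.10f)", a$nwk, t - a$time,
                                   b$nwk, t - b$time), time = t)
      lins <- c(lins[-pick], list(merged))
    }
    lins
  }
  if (K == 1L) {
    lins <- make_tips(species_tree$tip.label[1], n_per_species[1])
    lins <- coalesce_in(lins, 0, Inf)
    if (length(lins) == 1L && n_per_species[1] == 1L)
      stop("need >= 2 samples for a single-species gene tree")
    return(ape::read.tree(text = paste0(lins[[1]]$nwk, ";")))
  }
  # postorder over species-tree nodes
  edge <- species_tree$edge
  pool <- vector("list", nt + species_tree$Nnode)
  for (i in seq_len(nt))
    pool[[i]] <- make_tips(species_tree$tip.label[i], n_per_species[i])
  ord <- order(times[unique(edge[, 1])])
  internal <- unique(edge[, 1])[ord]
  for (node in internal) {
    kids <- edge[edge[, 1] == node, 2]
    lins <- list()
    for (kid in kids)
      lins <- c(lins, coalesce_in(pool[[kid]], times[kid], times[node]))
    pool[[node]] <- lins
  }
  root <- nt + 1L
  lins <- coalesce_in(pool[[root]], times[root], Inf)
  ape::read.tree(text = paste0(lins[[1]]$nwk, ";"))
}

#' Evolve sequences along a gene tree
#'
#' Site-independent substitution simulation (JC, HKY or GTR, optionally with
#' gamma rate variation) via `phangorn::simSeq`, with an optional branch-
#' Poisson deletion process producing the gappy nuclear-like marker: each
#' event deletes a geometric-length run of sites in all descendants of the
#' branch, and the output stays a rectangular, gap-padded alignment.
#'
#' @param gene_tree `phylo` with branch lengths in substitutions/site.
#' @param length alignment columns.
#' @param model `"JC"`, `"HKY"` or `"GTR"`.
#' @param bf base frequencies (HKY/GTR).
#' @param Q rate matrix entries (GTR order, length 6).
#' @param shape optional gamma shape for rate variation.
#' @param indel_rate deletion events per site per substitution unit.
#' @param indel_mean_length mean deletion length (geometric, >= 1).
#' @param marker marker name attached to the alignment.
#' @param seed optional seed.
#' @return A `marker_alignment`.
#' @export
evolve_sequences <- function(gene_tree, length, model = c("JC", "HKY", "GTR"),
                             bf = rep(0.25, 4), Q = rep(1, 6), shape = NULL,
                             indel_rate = 0, indel_mean_length = 3,
                             marker = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model)
  if (model == "JC") { bf <- rep(0.25, 4); Q <- rep(1, 6) }
  if (model == "HKY") { Q <- c(1, 2, 1, 1, 2, 1) * Q[1] }
  args <- list(gene_tree, l = length, type = "DNA", bf = bf, Q = Q)
  if (!is.null(shape)) { args$rate <- NULL; args$k <- 4; args$shape <- shape }
  sim <- do.call(phangorn::simSeq, args)
  mat <- toupper(as.character(sim))
  rownames(mat) <- gene_tree$tip.label
  if (indel_rate > 0) {
    tot_rate <- indel_rate * length
    desc <- lapply(seq_len(nrow(gene_tree$edge)), function(e) {
      node <- gene_tree$edge[e, 2]
      if (node <= ape::Ntip(gene_tree)) gene_tree$tip.label[node]
      else ape::extract.clade(gene_tree, node)$tip.label
    })
    for (e in seq_len(nrow(gene_tree$edge))) {
      n_ev <- stats::rpois(1, tot_rate * gene_tree$edge.length[e])
      for (k in seq_len(n_ev)) {
        len <- stats::rgeom(1, 1 / indel_mean_length) + 1L
        start <- sample.int(length, 1L)
        cols <- start:min(length, start + len - 1L)
        mat[desc[[e]], cols] <- "-"
      }
    }
  }
  new_alignment(mat, marker)
}

#' Simulate a complete synthetic data set
#'
#' Produces the full bundle the pipeline consumes: a Yule species tree, one
#' independent embedded coalescent gene tree per marker (mitochondrial marker
#' at a quarter of the nuclear effective size), simulated alignments (an
#' indel-free mitochondrial-like marker and an indel-bearing nuclear-like
#' marker), a site table over the ten biogeographic regions with overlapping
#' species-specific sampling weights and log-uniform depths in 8-4380 m, and
#' the true species partition.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_dataset`: list with `config`, `species_tree` (My),
#'   `gene_trees` (substitution units), `alignments` (`coi`, `its2`),
#'   `sites` (a site table as from [load_site_table()]), `specimens`
#'   (specimen/site/species assignment) and `true_partition`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  sp <- simulate_species_tree(config$K, config$yule_rate, config$min_stem)
  subs_tree <- sp
  subs_tree$edge.length <- sp$edge.length * config$clock_rate
  gt_coi <- simulate_gene_tree(subs_tree, config$theta * config$mito_factor,
                               config$n_per_species)
  gt_its2 <- simulate_gene_tree(subs_tree, config$theta,
                                config$n_per_species)
  # shared specimen ids across markers: lineages within a species are
  # exchangeable, so specimen k of species s is "t<k>_<s>" in both trees
  relabel <- function(tree) {
    spx <- id_clade(tree$tip.label)
    for (s in unique(spx)) {
      i <- which(spx == s)
      tree$tip.label[i] <- sprintf("t%d_%s", seq_along(i), s)
    }
    tree
  }
  gt_coi <- relabel(gt_coi)
  gt_its2 <- relabel(gt_its2)
  its2_len <- if (length(config$its2_length) > 1L)
    sample(seq(config$its2_length[1], config$its2_length[2]), 1L)
  else config$its2_length
  aln_coi <- evolve_sequences(gt_coi, config$coi_length, model = "HKY",
                              bf = c(0.28, 0.2, 0.17, 0.35),
                              marker = "COI")
  aln_its2 <- evolve_sequences(gt_its2, its2_len, model = "JC",
                               indel_rate = config$indel_rate,
                               indel_mean_length = config$indel_mean_length,
                               marker = "ITS2")
  # sampling design: species-specific region weights with overlap
  regions <- biogeographic_regions()
  ids <- aln_coi$ids
  sp_of <- id_clade(ids)
  wt <- sapply(seq_len(config$K), function(s) {
    center <- 1 + ((s - 1) %% length(regions))
    w <- rep(0.03, length(regions))
    w[center] <- 0.5
    w[1 + (center %% length(regions))] <- 0.2
    w / sum(w)
  })
  region_of <- vapply(sp_of, function(s)
    sample(regions, 1L, prob = wt[, as.integer(s)]), character(1))
  site_key <- paste(region_of,
                    sample.int(config$n_sites_per_region,
                               length(ids), replace = TRUE))
  site_id <- match(site_key, unique(site_key))
  sites <- do.call(rbind, lapply(unique(site_id), function(sid) {
    i <- site_id == sid
    dmin <- round(exp(stats::runif(1, log(8), log(4000))))
    data.frame(site_id = sprintf("SYN%d", sid),
               region = region_of[which(i)[1]],
               locality = NA_character_,
               sample_size = sum(i),
               clades = I(list(sort(unique(sp_of[i])))),
               latitude = round(stats::runif(1, 50, 89), 4),
               longitude = round(stats::runif(1, -30, 60), 4),
               depth_min = dmin,
               depth_max = min(4380, dmin + round(stats::rexp(1, 1 / 30))),
               stringsAsFactors = FALSE)
  }))
  class(sites) <- c("site_table", "data.frame")
  specimens <- data.frame(specimen_id = ids, species = sp_of,
                          site_id = sprintf("SYN%d", site_id),
                          stringsAsFactors = FALSE)
  structure(list(config = config, species_tree = sp,
                 gene_trees = list(coi = gt_coi, its2 = gt_its2),
                 alignments = list(coi = aln_coi, its2 = aln_its2),
                 sites = sites, specimens = specimens,
                 true_partition = species_partition(
                   split(ids, sp_of), method = "truth", marker = "combined")),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> K =", x$config$K, ";",
      length(x$alignments$coi$ids), "specimens;",
      "markers:", paste(names(x$alignments), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic data set to disk in the real-data interchange formats
#'
#' FASTA per marker, CSV site table, newick trees, and a JSON truth file.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$alignments$coi, file.path(dir, "coi.fasta"))
  write_fasta(ds$alignments$its2, file.path(dir, "its2.fasta"))
  sites <- ds$sites
  sites$clades <- vapply(sites$clades, paste, character(1), collapse = ",")
  sites$depth <- ifelse(sites$depth_min == sites$depth_max,
                        as.character(sites$depth_min),
                        paste0(sites$depth_min, "-", sites$depth_max))
  utils::write.csv(
    sites[, c("site_id", "region", "locality", "sample_size", "clades",
              "latitude", "longitude", "depth")],
    file.path(dir, "sites.csv"), row.names = FALSE, na = "-")
  ape::write.tree(ds$species_tree, file.path(dir, "species_tree.nwk"))
  ape::write.tree(ds$gene_trees$coi, file.path(dir, "gene_tree_coi.nwk"))
  ape::write.tree(ds$gene_trees$its2, file.path(dir, "gene_tree_its2.nwk"))
  truth <- lapply(ds$true_partition$blocks, identity)
  jsonlite::write_json(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
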