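#' Biogeographic regions of the study area
#'
#' The ten oceanographically defined regions used throughout the registry:
#' Kattegat, Skagerrak, North Sea, Irish Sea/Celtic Sea, Norwegian coast and
#' shelf, Norwegian Sea, Barents Sea, Arctic Ocean, Greenland Sea and the area
#' South of Iceland. Region membership is always read from the site table,
#' never derived from coordinates, because the regions are oceanographic
#' (water-mass) divisions rather than geometric ones.
#'
#' @return Character vector of the ten region names.
#' @export
biogeographic_regions <- function() {
  c("Kattegat", "Skagerrak", "North Sea", "Irish Sea, Celtic Sea",
    "Norwegian coast and shelf", "Norwegian Sea", "Barents Sea",
    "Arctic Ocean", "Greenland Sea", "South of Iceland")
}

#' Default clade-to-species merge map
#'
#' Maps clade labels to final species labels. By default clades 20 and 28 are
#' treated as a single species "20/28" (they share a nuclear haplotype and the
#' mitochondrial difference between them is within the variation seen in
#' better-sampled clades); every other clade maps to itself.
#'
#' @param clades character vector of clade labels present in the data.
#' @param merge named character vector giving non-identity mappings; the
#'   default merges "20" and "28" into "20/28".
#' @return Named character vector: a total mapping over `clades`.
#' @export
species_merge_map <- function(clades,
                              merge = c("20" = "20/28", "28" = "20/28")) {
  clades <- as.character(clades)
  map <- stats::setNames(clades, clades)
  hit <- names(merge)[names(merge) %in% clades]
  map[hit] <- merge[hit]
  map
}

#' Identity merge map (clade-level counting)
#' @param clades character vector of clade labels.
#' @return Named character vector mapping each clade to itself.
#' @export
identity_merge_map <- function(clades) {
  species_merge_map(clades, merge = character(0))
}

parse_depth <- function(x, row_id = "?") {
  x <- gsub("–", "-", trimws(as.character(x)))
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) < 1L || length(vals) > 2L || anyNA(vals))
    stop("non-numeric depth '", x, "' at site ", row_id)
  if (length(vals) == 1L) vals <- c(vals, vals)
  if (vals[1] > vals[2]) stop("inverted depth range at site ", row_id)
  vals
}

#' Load the site/collecting table
#'
#' Reads a site metadata table (one row per collecting site) with columns
#' `site_id`, `region`, `locality`, `sample_size`, `clades` (comma-separated
#' clade labels), `latitude`, `longitude`, `depth` ("a-b" range or a single
#' value), `date`, `habitat`, `gear`. Fields recorded as "-" in the source
#' become `NA`; dates are kept as text because the source mixes granularities.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return A data.frame of site records with `depth_min`/`depth_max` in
#'   meters and a list-column `clades` of clade-label character vectors.
#' @export
load_site_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(x) == 0L) stop("no records in site table '", path, "'")
  needed <- c("site_id", "region", "sample_size", "clades",
              "latitude", "longitude", "depth")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("site table lacks columns: ", paste(missing, collapse = ", "))
  bad <- which(!x$region %in% biogeographic_regions())
  if (length(bad))
    stop("unknown region '", x$region[bad[1]], "' in row ", bad[1],
         " (site ", x$site_id[bad[1]], ")")
  if (anyDuplicated(x$site_id)) stop("duplicate site ids")
  dp <- t(mapply(parse_depth, x$depth, x$site_id))
  x$depth_min <- dp[, 1]
  x$depth_max <- dp[, 2]
  x$clades <- lapply(strsplit(as.character(x$clades), ","), trimws)
  if (any(lengths(x$clades) < 1L)) stop("site with empty clade list")
  for (col in c("locality", "habitat", "gear", "date"))
    if (col %in% names(x)) x[[col]][x[[col]] %in% c("-", "")] <- NA
  x$latitude <- as.numeric(x$latitude)
  x$longitude <- as.numeric(x$longitude)
  x$sample_size <- as.integer(x$sample_size)
  if (any(x$sample_size < 1L)) stop("sample_size must be >= 1")
  class(x) <- c("site_table", "data.frame")
  x
}

#' Path to the packaged North East Atlantic Terebellides site table
#' @return File path of the packaged site fixture (a typed transcription
#'   of the study's published collecting table).
#' @export
terebellides_sites_path <- function() {
  system.file("extdata", "terebellides_sites.csv", package = "haplodelim",
              mustWork = TRUE)
}

#' Registry-wide totals
#'
#' @param sites a site table from [load_site_table()].
#' @return List with `n_sites`, `n_specimens`, `depth_min`, `depth_max`.
#' @export
registry_totals <- function(sites) {
  stopifnot(nrow(sites) > 0L)
  list(n_sites = nrow(sites),
       n_specimens = sum(sites$sample_size),
       depth_min = min(sites$depth_min),
       depth_max = max(sites$depth_max))
}

merged_site_species <- function(sites, merge_map) {
  lapply(sites$clades, function(v) unique(unname(merge_map[v])))
}

#' Per-region specimen and species summary
#'
#' Species are counted after applying the clade-to-species merge map (the
#' final species concept); pass [identity_merge_map()] for clade-level counts.
#'
#' @param sites a site table.
#' @param merge named clade-to-species mapping; default merges 20 and 28.
#' @return data.frame with one row per region present: `region`,
#'   `n_specimens`, `n_species`, and a list-column `species`.
#' @export
regional_summary <- function(sites, merge = NULL) {
  all_clades <- unique(unlist(sites$clades))
  if (is.null(merge)) merge <- species_merge_map(all_clades)
  if (any(!all_clades %in% names(merge)))
    stop("merge map is not total over clades present")
  sp <- merged_site_species(sites, merge)
  regions <- unique(sites$region)
  out <- lapply(regions, function(r) {
    i <- sites$region == r
    spp <- sort(unique(unlist(sp[i])))
    data.frame(region = r, n_specimens = sum(sites$sample_size[i]),
               n_species = length(spp), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$species <- lapply(regions, function(r) {
    i <- sites$region == r
    sort(unique(unlist(sp[i])))
  })
  res
}

#' Species shared between two regions
#'
#' Reports how many of region A's species also occur in region B, and which
#' region is most similar to A (maximal shared fraction of A's species; ties
#' are all reported).
#'
#' @param region_a,region_b region names.
#' @param summaries output of [regional_summary()].
#' @return List with `n_shared`, `n_in_a`, `most_similar` (character vector of
#'   tied most-similar regions for A) and `shared_species`.
#' @export
shared_species <- function(region_a, region_b, summaries) {
  for (r in c(region_a, region_b))
    if (!r %in% summaries$region) stop("region absent from summary: ", r)
  sp <- function(r) summaries$species[[match(r, summaries$region)]]
  a <- sp(region_a); b <- sp(region_b)
  others <- setdiff(summaries$region, region_a)
  frac <- vapply(others, function(r) length(intersect(a, sp(r))) / length(a),
                 numeric(1))
  list(n_shared = length(intersect(a, b)),
       n_in_a = length(a),
       most_similar = others[frac == max(frac)],
       shared_species = sort(intersect(a, b)))
}

#' Site-level co-occurrence statistics
#'
#' A multi-specimen site has more than one sequenced specimen; a multi-species
#' site yields more than one (merged) species.
#'
#' @inheritParams regional_summary
#' @return List with `n_multispecimen_sites`, `n_multispecies_sites`,
#'   `max_species_per_site`.
#' @export
cooccurrence_stats <- function(sites, merge = NULL) {
  all_clades <- unique(unlist(sites$clades))
  if (is.null(merge)) merge <- species_merge_map(all_clades)
  sp <- merged_site_species(sites, merge)
  k <- lengths(sp)
  list(n_multispecimen_sites = sum(sites$sample_size > 1L),
       n_multispecies_sites = sum(k > 1L),
       max_species_per_site = max(k))
}

#' Analytic rarefaction (species accumulation) curve
#'
#' Expected number of species in a random draw of `n` specimens without
#' replacement, computed from the hypergeometric closed form
#' \deqn{E[S_n] = \sum_s \left(1 - \binom{N - N_s}{n} / \binom{N}{n}\right)}
#' where \eqn{N_s} is the number of specimens of species \eqn{s}.
#'
#' @param species_labels character vector, one entry per specimen.
#' @param sizes draw sizes; defaults to `1:N`.
#' @return data.frame with columns `n` and `expected_species`.
#' @export
rarefaction_curve <- function(species_labels, sizes = seq_along(species_labels)) {
  N <- length(species_labels)
  if (any(sizes > N)) stop("draw size exceeds number of specimens")
  if (any(sizes < 1L)) stop("draw size must be >= 1")
  counts <- table(species_labels)
  es <- vapply(sizes, function(n) {
    keep <- N - counts >= n
    miss <- numeric(length(counts))
    miss[keep] <- exp(lchoose(N - counts[keep], n) - lchoose(N, n))
    sum(1 - miss)
  }, numeric(1))
  data.frame(n = sizes, expected_species = es)
}

#' Expand a site table to one row per specimen
#'
#' Specimens at a site are split across the site's clades as evenly as the
#' sample size allows (the source table records which clades occur at a site,
#' not per-clade counts). Used for rarefaction over regions.
#'
#' @param sites a site table.
#' @param merge optional merge map applied to the labels.
#' @return data.frame with columns `site_id`, `region`, `species`.
#' @export
expand_specimens <- function(sites, merge = NULL) {
  all_clades <- unique(unlist(sites$clades))
  if (is.null(merge)) merge <- species_merge_map(all_clades)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    cl <- sites$clades[[i]]
    n <- sites$sample_size[i]
    if (n < length(cl)) cl <- cl[seq_len(n)]
    counts <- rep(n %/% length(cl), length(cl))
    extra <- n %% length(cl)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    lab <- rep(cl, counts)
    data.frame(site_id = sites$site_id[i], region = sites$region[i],
               species = unname(merge[lab]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-species bathymetric profile
#'
#' Each specimen carries the full depth range of its site (the source records
#' site-level ranges only, so no interpolation is attempted). The profile is
#' the min over `depth_min` and the max over `depth_max` of the sites where a
#' species occurs, overall and per region.
#'
#' @inheritParams regional_summary
#' @return data.frame with columns `species`, `region` (`"all"` for the
#'   overall row), `depth_min`, `depth_max`, `n_sites`.
#' @export
depth_profile <- function(sites, merge = NULL) {
  all_clades <- unique(unlist(sites$clades))
  if (is.null(merge)) merge <- species_merge_map(all_clades)
  sp <- merged_site_species(sites, merge)
  species <- sort(unique(unlist(sp)))
  one <- function(s, idx, region) {
    data.frame(species = s, region = region,
               depth_min = min(sites$depth_min[idx]),
               depth_max = max(sites$depth_max[idx]),
               n_sites = sum(idx), stringsAsFactors = FALSE)
  }
  out <- list()
  for (s in species) {
    has <- vapply(sp, function(v) s %in% v, logical(1))
    out[[length(out) + 1L]] <- one(s, has, "all")
    for (r in unique(sites$region[has]))
      out[[length(out) + 1L]] <- one(s, has & sites$region == r, r)
  }
  do.call(rbind, out)
}

#' Select specimens eligible for concatenated analysis
#'
#' Keeps specimens for which at least `min_markers` of the four markers
#' (COI, 16S, ITS2, 28S) were sequenced; the study's concatenated data set
#' used a three-of-four rule.
#'
#' @param specimens data.frame with logical (or 0/1) columns named in
#'   `marker_universe` and a `specimen_id` column.
#' @param min_markers minimum number of markers present (default 3).
#' @param marker_universe marker column names.
#' @return Character vector of eligible specimen ids.
#' @export
concat_eligible <- function(specimens, min_markers = 3L,
                            marker_universe = c("coi", "its2", "rdna16s", "rdna28s")) {
  if (min_markers < 1L || min_markers > length(marker_universe))
    stop("min_markers out of range")
  missing <- setdiff(marker_universe, names(specimens))
  if (length(missing)) stop("missing marker columns: ",
                            paste(missing, collapse = ", "))
  m <- sapply(marker_universe, function(k) as.logical(specimens[[k]]))
  specimens$specimen_id[rowSums(m) >= min_markers]
}
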