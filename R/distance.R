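#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatches over the columns where both symbols are
#' determinate nucleotides (A, C, G or T). Gaps, missing data and IUPAC
#' ambiguity codes are uninformative and excluded pairwise, matching the
#' distance convention of the study (gaps treated as uninformative).
#'
#' @param a,b equal-length character vectors (or single strings) of aligned
#'   symbols.
#' @return Fraction in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% DETERMINATE & b %in% DETERMINATE
  if (!any(ok)) stop("undefined distance: zero comparable columns")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Pairwise p-distance matrix for an alignment
#'
#' @param aln a `marker_alignment`.
#' @param steps if `TRUE`, return absolute mismatch counts (mutational steps)
#'   instead of proportions.
#' @return Symmetric numeric matrix with zero diagonal. Pairs with no
#'   comparable columns are `NA` (proportions) or `Inf` (steps).
#' @export
p_distance_matrix <- function(aln, steps = FALSE) {
  m <- aln$mat
  n <- nrow(m)
  det <- matrix(m %in% DETERMINATE, nrow = n)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- det[i, ] & det[j, ]
    nok <- sum(ok)
    mis <- sum(m[i, ok] != m[j, ok])
    v <- if (steps) { if (nok == 0L) Inf else mis }
         else { if (nok == 0L) NA_real_ else mis / nok }
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Intra/interspecific distance summary (published summary-table layout)
#'
#' Computes, on the full-species alignment (not pruned per-clade windows),
#' the within-clade distance range per clade and, per clade, the nearest
#' neighbour (the other clade minimizing the cross-pair minimum) with the
#' (min, max) range of cross-pair distances restricted to that neighbour,
#' plus the analogous farthest-clade maximum range.
#'
#' @param aln a `marker_alignment` with `_clade` id suffixes.
#' @param clades optional clade grouping as in [clade_haplotype_report()]
#'   ("a/b" pools clades).
#' @return List with `per_clade` (data.frame: clade, n, intra_min, intra_max
#'   in percent, NA for singletons, nearest, inter_min_lo, inter_min_hi,
#'   farthest, inter_max_lo, inter_max_hi) and `pairs` (data.frame of
#'   ordered-pair inter_min/inter_max in percent).
#' @export
summarize_distances <- function(aln, clades = NULL) {
  lab <- id_clade(aln$ids)
  if (is.null(clades)) {
    u <- unique(lab[!is.na(lab)])
    num <- suppressWarnings(as.numeric(u))
    clades <- u[order(num, u)]
  }
  group <- stats::setNames(rep(NA_character_, length(lab)), aln$ids)
  for (cl in clades) {
    parts <- strsplit(cl, "/", fixed = TRUE)[[1]]
    group[lab %in% parts] <- cl
  }
  if (length(unique(stats::na.omit(group))) < 2L)
    stop("need >= 2 clades for a distance summary")
  d <- p_distance_matrix(aln)
  idx <- split(seq_along(group), group)[clades]
  rng <- function(i, j) {
    v <- d[i, j, drop = FALSE]
    if (identical(i, j)) v <- v[upper.tri(v)]
    range(v, na.rm = TRUE) * 100
  }
  pairs <- expand.grid(a = clades, b = clades, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  pr <- t(apply(pairs, 1, function(p) rng(idx[[p[["a"]]]], idx[[p[["b"]]]])))
  pairs$inter_min <- pr[, 1]; pairs$inter_max <- pr[, 2]
  per <- lapply(clades, function(cl) {
    i <- idx[[cl]]
    intra <- if (length(i) < 2L) c(NA_real_, NA_real_) else rng(i, i)
    sub <- pairs[pairs$a == cl, ]
    nn <- sub$b[which.min(sub$inter_min)]
    ff <- sub$b[which.max(sub$inter_max)]
    nnr <- rng(i, idx[[nn]]); ffr <- rng(i, idx[[ff]])
    data.frame(clade = cl, n = length(i),
               intra_min = intra[1], intra_max = intra[2],
               nearest = nn, inter_min_lo = nnr[1], inter_min_hi = nnr[2],
               farthest = ff, inter_max_lo = ffr[1], inter_max_hi = ffr[2],
               stringsAsFactors = FALSE)
  })
  list(per_clade = do.call(rbind, per), pairs = pairs)
}

#' Barcode-gap assessment
#'
#' Compares the largest intraspecific distance with the smallest
#' interspecific distance across a [summarize_distances()] result.
#'
#' @param summary output of [summarize_distances()].
#' @return List with `max_intra_overall`, `min_inter_overall` (percent) and
#'   `gap_exists`.
#' @export
barcode_gap <- function(summary) {
  per <- summary$per_clade
  if (nrow(per) < 2L) stop("need >= 2 clades")
  max_intra <- suppressWarnings(max(per$intra_max, na.rm = TRUE))
  min_inter <- min(summary$pairs$inter_min)
  list(max_intra_overall = max_intra,
       min_inter_overall = min_inter,
       gap_exists = min_inter > max_intra)
}
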