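IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "?", "-")
DETERMINATE <- c("A", "C", "G", "T")

new_alignment <- function(mat, marker = NA_character_) {
  stopifnot(is.matrix(mat), nrow(mat) == 0L || !is.null(rownames(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- character(0)
  structure(list(marker = marker, ids = rownames(mat), mat = mat),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("<marker_alignment>", if (!is.na(x$marker)) x$marker else "",
      ":", nrow(x$mat), "sequences x", ncol(x$mat), "columns\n")
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln a `marker_alignment`.
#' @return Integer count.
#' @export
n_sequences <- function(aln) nrow(aln$mat)

#' @rdname n_sequences
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Build an alignment from named sequence strings
#'
#' @param seqs named character vector of equal-length sequences.
#' @param marker optional marker name.
#' @return A `marker_alignment` (uppercased, U mapped to T).
#' @export
alignment_from_strings <- function(seqs, marker = NA_character_) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment: unequal sequence lengths")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), IUPAC_OK)
  if (length(bad)) stop("non-IUPAC symbols: ", paste(bad, collapse = " "))
  new_alignment(mat, marker)
}

#' Read a multiple sequence alignment
#'
#' FASTA is parsed directly; NEXUS (sequential or interleaved DATA blocks)
#' through `ape::read.nexus.data`. Sequences are uppercased with U mapped to
#' T; ragged inputs, duplicate ids and non-IUPAC symbols are rejected.
#'
#' @param path input file.
#' @param format `"fasta"` or `"nexus"`; guessed from the extension when
#'   missing.
#' @param marker optional marker name attached to the alignment.
#' @return A `marker_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus"),
                           marker = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus", "nxs")) "nexus" else "fasta"
  }
  if (format == "nexus") {
    lst <- ape::read.nexus.data(path)
    seqs <- vapply(lst, paste, character(1), collapse = "")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines) || !startsWith(lines[[1]], ">"))
      stop("not a FASTA file: ", path)
    hdr <- grep("^>", lines)
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    starts <- hdr + 1L
    ends <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      if (starts[i] > ends[i]) "" else
        paste(lines[starts[i]:ends[i]], collapse = "")
    }, character(1))
    seqs <- gsub("\\s", "", seqs)
    names(seqs) <- ids
  }
  alignment_from_strings(seqs, marker)
}

#' Write an alignment to FASTA (80-column wrap)
#' @param aln a `marker_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$mat))) {
    s <- paste(aln$mat[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), 80), pmin(seq(1, nchar(s), 80) + 79, nchar(s)))
    writeLines(c(paste0(">", aln$ids[i]), chunks), con)
  }
  invisible(path)
}

#' Write an alignment as a simple sequential NEXUS DATA block
#' @inheritParams write_fasta
#' @export
write_nexus <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(aln$mat), ncol(aln$mat)),
               "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX"), con)
  for (i in seq_len(nrow(aln$mat)))
    writeLines(paste(aln$ids[i], paste(aln$mat[i, ], collapse = "")), con)
  writeLines(c(";", "END;"), con)
  invisible(path)
}

#' Clade label carried by a sequence id
#'
#' Ids follow the "extractionID_clade" convention (e.g. `"1203_8"` is
#' extraction 1203 in clade 8).
#'
#' @param ids character vector of sequence ids.
#' @return Character vector of clade labels (`NA` where no suffix).
#' @export
id_clade <- function(ids) {
  has <- grepl("_", ids, fixed = TRUE)
  out <- rep(NA_character_, length(ids))
  out[has] <- sub("^.*_", "", ids[has])
  out
}

#' Extract the sequences of one clade
#'
#' @param aln a `marker_alignment` whose ids carry `_clade` suffixes.
#' @param clade clade label (or several, e.g. `c("20","28")` to pool a merged
#'   species).
#' @return A `marker_alignment` with rows in input order; empty (with a
#'   warning) for an unknown clade.
#' @export
extract_clade <- function(aln, clade) {
  keep <- id_clade(aln$ids) %in% as.character(clade)
  if (!any(keep))
    warning("no sequences for clade ", paste(clade, collapse = "/"))
  new_alignment(aln$mat[keep, , drop = FALSE], aln$marker)
}

is_missing_sym <- function(m) m == "?" | m == "N" | m == "-"

#' Prune an alignment to full terminal coverage
#'
#' Replays the study's per-clade preparation: first drop the sequences listed
#' in the pruning policy, then trim leading and trailing columns in which any
#' retained sequence is indeterminate ('?', 'N', or a terminal '-' run caused
#' by incomplete sequencing), so that every retained specimen has data at the
#' first and last columns. Interior columns are never touched.
#'
#' @param aln a `marker_alignment`.
#' @param removed_ids sequence ids to drop before pruning (the published
#'   "removed sequences in haplotype analysis" policy).
#' @return Pruned `marker_alignment`.
#' @export
prune_to_full_coverage <- function(aln, removed_ids = character(0)) {
  unknown <- setdiff(removed_ids, aln$ids)
  if (length(unknown))
    stop("removed ids not in alignment: ", paste(unknown, collapse = ", "))
  mat <- aln$mat[!aln$ids %in% removed_ids, , drop = FALSE]
  if (nrow(mat) == 0L) stop("alignment empty after removals")
  # trim flanking columns until the first and last retained columns carry a
  # determinate symbol for every retained sequence; interior columns with
  # gaps or missing data are left untouched
  dirty <- colSums(matrix(is_missing_sym(mat), nrow = nrow(mat))) > 0L
  lo <- 1L
  while (lo <= ncol(mat) && dirty[lo]) lo <- lo + 1L
  hi <- ncol(mat)
  while (hi >= 1L && dirty[hi]) hi <- hi - 1L
  if (lo > hi) stop("pruning removed every column")
  new_alignment(mat[, lo:hi, drop = FALSE], aln$marker)
}

#' Collapse an alignment into unique haplotypes
#'
#' Two sequences share a haplotype iff they carry the same symbol at every
#' column; gap and missing symbols are ordinary symbols under the default
#' (exact) identity rule, matching the behaviour of the uniqhaplo script used
#' in the study. With `treat_missing_as_wildcard = TRUE`, '?'/'N' match any
#' symbol and sequences are merged greedily in input order.
#'
#' @param aln a `marker_alignment`.
#' @param treat_missing_as_wildcard wildcard identity mode (off by default).
#' @return A `haplotype_set`: list with `representatives` (a
#'   `marker_alignment` of first-seen representatives) and `members` (list of
#'   member-id vectors, parallel to the representatives).
#' @export
collapse_identical <- function(aln, treat_missing_as_wildcard = FALSE) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  if (!treat_missing_as_wildcard) {
    first <- !duplicated(seqs)
    groups <- split(aln$ids, factor(seqs, levels = unique(seqs)))
  } else {
    reps <- integer(0)
    assign <- integer(nrow(aln$mat))
    for (i in seq_len(nrow(aln$mat))) {
      hit <- 0L
      for (k in seq_along(reps)) {
        a <- aln$mat[reps[k], ]; b <- aln$mat[i, ]
        ok <- a == b | is_missing_sym(a) | is_missing_sym(b)
        if (all(ok)) { hit <- k; break }
      }
      if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
      assign[i] <- hit
    }
    first <- seq_len(nrow(aln$mat)) %in% reps
    groups <- split(aln$ids, assign)
  }
  structure(list(
    representatives = new_alignment(aln$mat[first, , drop = FALSE], aln$marker),
    members = unname(groups)), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set>", length(x$members), "haplotypes,",
      sum(lengths(x$members)), "sequences\n")
  invisible(x)
}

#' Number of unique haplotypes
#' @param haps a `haplotype_set`.
#' @return Integer count.
#' @export
n_haplotypes <- function(haps) length(haps$members)

#' Per-clade haplotype report (published summary-table layout)
#'
#' For each clade: extract its sequences, drop the listed removals, prune the
#' flanks to full coverage, and count unique haplotypes on the pruned window.
#'
#' @param aln a full-marker `marker_alignment` with `_clade` id suffixes.
#' @param clades clade labels to report (default: all present, sorted);
#'   an entry may pool several clades when written "a/b" (merged species).
#' @param removed named list: per clade label, ids to drop before pruning.
#' @return data.frame with columns `clade`, `n_specimens`, `original_length`,
#'   `pruned_length`, `n_haplotypes`.
#' @export
clade_haplotype_report <- function(aln, clades = NULL, removed = list()) {
  found <- id_clade(aln$ids)
  if (is.null(clades)) {
    u <- unique(found[!is.na(found)])
    num <- suppressWarnings(as.numeric(u))
    clades <- u[order(num, u)]
  }
  rows <- lapply(clades, function(cl) {
    parts <- strsplit(cl, "/", fixed = TRUE)[[1]]
    sub <- extract_clade(aln, parts)
    rem <- unlist(removed[parts], use.names = FALSE)
    n_spec <- n_sequences(sub)
    pr <- prune_to_full_coverage(sub, intersect(rem, sub$ids))
    data.frame(clade = cl, n_specimens = n_spec,
               original_length = alignment_length(sub),
               pruned_length = alignment_length(pr),
               n_haplotypes = n_haplotypes(collapse_identical(pr)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
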