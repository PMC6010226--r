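# shared helpers: small alignments and independent brute-force oracles

toy_alignment <- function(seqs, marker = NA_character_) {
  alignment_from_strings(seqs, marker)
}

sites_fixture <- function() load_site_table(terebellides_sites_path())

# exhaustive rarefaction oracle: average species count over all C(N, n) draws
rarefaction_enum <- function(labels, n) {
  idx <- utils::combn(length(labels), n)
  mean(apply(idx, 2, function(i) length(unique(labels[i]))))
}

# brute-force connected components of the step-threshold graph
threshold_components <- function(step_matrix, limit) {
  n <- nrow(step_matrix)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (step_matrix[i, j] <= limit && comp[j] != comp[i]) {
        old <- max(comp[i], comp[j]); new <- min(comp[i], comp[j])
        comp[comp == old] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# independent flank-pruning oracle: the window spanned by the first and the
# last column in which every sequence carries a determinate symbol
prune_oracle_length <- function(strings) {
  mat <- do.call(rbind, strsplit(strings, ""))
  clean <- apply(mat, 2, function(col) all(!col %in% c("-", "?", "N")))
  if (!any(clean)) return(0L)
  max(which(clean)) - min(which(clean)) + 1L
}
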