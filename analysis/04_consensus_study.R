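#!/usr/bin/env Rscript
# Multi-marker consensus on the study's printed-table evidence: the 28
# mitochondrial networks as reference, the nuclear/GMYC partitions from the
# results, and the distance/haplotype-sharing evidence from the summary
# tables. Writes results/study_consensus/.

suppressPackageStartupMessages(library(haplodelim))
out <- "results/study_consensus"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

res <- study_consensus()
message(sprintf("consensus: %d species, bounds %d-%d",
                res$n_species, res$lower_bound, res$upper_bound))
for (i in seq_len(nrow(res$decisions)))
  message(sprintf("  [%s] %s: %s (%s)", res$decisions$rule[i],
                  res$decisions$pair[i], res$decisions$action[i],
                  res$decisions$evidence[i]))
write.table(res$decisions, file.path(out, "decisions.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(n_species = res$n_species,
                          lower_bound = res$lower_bound,
                          upper_bound = res$upper_bound,
                          species = names(res$final_partition$blocks)),
                     file.path(out, "consensus.json"), auto_unbox = TRUE)

# agreement coding of every partition against the mitochondrial reference
ref <- study_reference_partition()
codes <- lapply(study_other_partitions(), function(p) agreement_code(ref, p))
mat <- data.frame(block = codes[[1]]$block)
for (nm in names(codes)) mat[[nm]] <- codes[[nm]]$code
write.table(mat, file.path(out, "agreement_matrix.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote decision log and agreement matrix to ", out)
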