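#!/usr/bin/env Rscript
# Biogeographic and bathymetric accounting over the packaged site table:
# totals, per-region diversity, between-region similarity, co-occurrence and
# rarefaction. Writes results/biogeography/.

suppressPackageStartupMessages(library(haplodelim))
out <- "results/biogeography"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sites <- load_site_table(terebellides_sites_path())
tot <- registry_totals(sites)
message(sprintf("%d specimens from %d sites, depth range %g-%g m",
                tot$n_specimens, tot$n_sites, tot$depth_min, tot$depth_max))

rs <- regional_summary(sites)
rs_out <- rs
rs_out$species <- vapply(rs$species, paste, character(1), collapse = ",")
write.table(rs_out, file.path(out, "regional_summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("highest regional diversity: %s (%d species / %d specimens)",
                rs$region[which.max(rs$n_species)], max(rs$n_species),
                rs$n_specimens[which.max(rs$n_species)]))

sim <- do.call(rbind, lapply(rs$region, function(r) {
  x <- shared_species(r, rs$region[1], rs)
  data.frame(region = r, n_species = x$n_in_a,
             most_similar = paste(x$most_similar, collapse = "; "))
}))
write.table(sim, file.path(out, "region_similarity.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

co <- cooccurrence_stats(sites)
message(sprintf(paste("%d of %d multi-specimen sites hold more than one",
                      "species (max %d at one site)"),
                co$n_multispecies_sites, co$n_multispecimen_sites,
                co$max_species_per_site))

dp <- depth_profile(sites)
write.table(dp, file.path(out, "depth_profile.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

spec <- expand_specimens(sites)
rar <- do.call(rbind, lapply(split(spec$species, spec$region), function(v)
  rarefaction_curve(v)))
rar$region <- rep(names(split(spec$species, spec$region)),
                  vapply(split(spec$species, spec$region), length, 1L))
write.table(rar, file.path(out, "rarefaction.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote tables to ", out)
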