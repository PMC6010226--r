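#!/usr/bin/env Rscript
# Generates the default synthetic multi-species data set (Yule species tree,
# embedded coalescent gene trees, mitochondrial- and nuclear-like markers,
# site table) and writes it in the real-data interchange formats.

suppressPackageStartupMessages(library(haplodelim))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

ds <- simulate_dataset(sim_config(seed = seed))
out <- file.path("results", sprintf("synthetic_seed%d", seed))
write_dataset(ds, out)
message(sprintf("simulated K=%d species, %d specimens; wrote %s",
                ds$config$K, length(ds$alignments$coi$ids), out))
message(sprintf("mitochondrial marker: %d x %d; nuclear marker: %d x %d (%d gap cells)",
                n_sequences(ds$alignments$coi), alignment_length(ds$alignments$coi),
                n_sequences(ds$alignments$its2), alignment_length(ds$alignments$its2),
                sum(ds$alignments$its2$mat == "-")))
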