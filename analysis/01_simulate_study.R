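#!/usr/bin/env Rscript

## Generate the synthetic study used throughout the analysis: an FBD
## tree over the 15-11 ka BP sampling window, Brownian shape traits,
## outlines, and per-locale radiocarbon dates against a synthetic
## calibration curve. Everything downstream reads the files written
## here.

library(fbdshape)

n_taxa <- 32L
seed <- 2024L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message(sprintf("simulating study: %d taxa, seed %d", n_taxa, seed))
res <- make_study_scenario(n_taxa, seed = seed)

write_outlines_csv(res$outlines, file.path(out, "outlines.csv"))
write_traits_tsv(res$traits, file.path(out, "true_traits.tsv"))
write_calcurve_csv(res$curve, file.path(out, "calcurve_synthetic.csv"))
write_dates_csv(res$c14_tables, file.path(out, "c14_dates.csv"))
writeLines(write_sa_newick(res$tree), file.path(out, "true_tree.nwk"))
write.csv(res$samples, file.path(out, "dated_samples.csv"), row.names = FALSE)

message(sprintf("  %d samples over bins: %s",
                nrow(res$samples),
                paste(names(table(res$samples$bin)),
                      table(res$samples$bin), collapse = ", ", sep = "=")))
nch <- tabulate(res$tree$parent[!is.na(res$tree$parent)],
                nbins = length(res$tree$parent))
message(sprintf("  %d sampled ancestors in the true tree",
                sum(res$tree$is_sample & nch == 1L)))
message("wrote ", out)
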