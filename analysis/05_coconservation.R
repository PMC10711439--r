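#!/usr/bin/env Rscript
# TnpA-TnpB co-conservation across simulated transposable elements.
#
# If TnpB has ridden inside the same transposon as its TnpA transposase
# since their common ancestor, TnpA-TnpA and TnpB-TnpB percent identities
# between any two elements co-vary. Shuffling the TnpB assignment destroys
# the correlation -- the control separating shared history from chance.

suppressPackageStartupMessages(library(fanzortrace))
dir.create("results", showWarnings = FALSE)
seed <- 20260923L

rows <- lapply(1:20, function(j) {
  fam <- gen_paired_families(paired_family_config(
    30, coupling = 1, shuffle_control = TRUE, seed = child_seed(seed, j)))
  cc <- paired_identities(fam$msa_a, fam$msa_b, fam$pairing)
  sh <- paired_identities(fam$msa_a, fam$msa_b, fam$shuffled_pairing)
  data.frame(seed_index = j, pearson_coupled = cc$pearson_r,
             spearman_coupled = cc$spearman_rho,
             pearson_shuffled = sh$pearson_r)
})
tab <- do.call(rbind, rows)
write_tsv(tab, "results/coconservation_correlations.tsv")

# one representative pair table + 2D histogram for plotting
fam <- gen_paired_families(paired_family_config(
  30, coupling = 1, seed = child_seed(seed, 1)))
cc <- paired_identities(fam$msa_a, fam$msa_b, fam$pairing)
write_tsv(cc$pairs, "results/coconservation_pairs.tsv")
write_tsv(as.data.frame(cc$histogram2d), "results/coconservation_hist2d.tsv")

cat(sprintf("coupled:  mean Pearson r = %.3f (range %.3f-%.3f)\n",
            mean(tab$pearson_coupled), min(tab$pearson_coupled),
            max(tab$pearson_coupled)))
cat(sprintf("shuffled: mean |r| = %.3f\n", mean(abs(tab$pearson_shuffled))))
cat("paired identities co-vary strongly under shared divergence and\n")
cat("collapse to noise under permutation, the signature of long-term\n")
cat("TnpA-TnpB co-residence.\n")
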