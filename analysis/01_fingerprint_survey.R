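#!/usr/bin/env Rscript
# Survey RuvC/ZF fingerprint prevalence in a simulated TnpB-family database.
#
# The Fanzor fingerprint (DPG at RuvC1 plus the alternative glutamate six
# residues before the zinc finger) is rare among TnpB homologs; here we
# plant a small Fanzor-like minority among canonical TnpBs and unrelated
# proteins and confirm the scan recovers the planted prevalence exactly.

suppressPackageStartupMessages(library(fanzortrace))
dir.create("results", showWarnings = FALSE)
seed <- 20260923L

fanzor <- gen_protein_family(protein_family_config(
  5, 0, "DPG", "E_alt", seed = child_seed(seed, 1)))
pro_fanzor <- gen_protein_family(protein_family_config(
  3, 0, "DPhiG", "E_alt", seed = child_seed(seed, 2)))
canonical <- gen_protein_family(protein_family_config(
  292, 0, "DPhiG", "E_can", seed = child_seed(seed, 3)))
decoys <- gen_protein_family(protein_family_config(
  0, 200, seed = child_seed(seed, 4)))

fanzor$id <- paste0("fz_", fanzor$id)
pro_fanzor$id <- paste0("pf_", pro_fanzor$id)
canonical$id <- paste0("tnpb_", canonical$id)
decoys$id <- paste0("bg_", decoys$id)
db <- rbind(fanzor, pro_fanzor, canonical, decoys)
scan <- scan_database(setNames(db$seq, db$id))

tab <- data.frame(category = names(scan$fractions),
                  fraction = as.numeric(scan$fractions),
                  truth = as.numeric(prop.table(table(factor(
                    db$class, levels = names(scan$fractions))))))
write_tsv(tab, "results/fingerprint_fractions.tsv")
write_tsv(scan$calls, "results/fingerprint_calls.tsv")

cat("database of", nrow(db), "proteins\n")
print(tab, row.names = FALSE)
cat(sprintf("\nFANZOR_LIKE prevalence: %.1f%% (planted %.1f%%) -- the\n",
            100 * tab$fraction[1], 100 * tab$truth[1]))
cat("full fingerprint singles out the planted minority; canonical TnpBs\n")
cat("and unrelated proteins never acquire it by chance here.\n")
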