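#!/usr/bin/env Rscript
# Iterative PSSM search over a nested homolog ladder.
#
# A profile built from a tight seed alignment finds close homologs easily;
# adding each round's hits back into the alignment lets later rounds reach
# rungs the seed profile missed. The per-round recall table quantifies the
# gain of five augmentation rounds at each identity rung.

suppressPackageStartupMessages(library(fanzortrace))
dir.create("results", showWarnings = FALSE)
seed <- 20260923L

lad <- gen_homolog_ladder(ladder_config(n_per_rung = 50,
                                        seed = child_seed(seed, 1)))
res <- iterative_search(lad$seed_alignment, lad$database, rounds = 5,
                        seed = child_seed(seed, 2))
print(res)

rungs <- sort(unique(lad$truth$rung[!is.na(lad$truth$rung)]),
              decreasing = TRUE)
recall <- do.call(rbind, lapply(seq_len(5), function(r) {
  hits <- res$hit_ids_by_round[[r]]
  row <- vapply(rungs, function(g)
    mean(lad$truth$id[!is.na(lad$truth$rung) &
                        lad$truth$rung == g] %in% hits), numeric(1))
  data.frame(round = r, threshold_bits = res$history$threshold[r],
             setNames(as.list(row), sprintf("recall_%d", 100 * rungs)),
             decoy_hits = sum(grepl("decoy", hits)))
}))
write_tsv(recall, "results/iterative_recall.tsv")
print(recall, row.names = FALSE)

cat(sprintf("\nrecall at the 40%% rung: %.2f (round 1) -> %.2f (round 5);\n",
            recall$recall_40[1], recall$recall_40[5]))
cat(sprintf("hit sets grow monotonically; %d of %d decoys cleared the\n",
            recall$decoy_hits[5], sum(grepl("decoy", names(lad$database)))))
cat("empirical-null threshold across all five rounds.\n")
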