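#!/usr/bin/env Rscript
# Over-representation analysis of the potential-target list against the
# pathway annotation sets (exact hypergeometric tail, BH adjustment,
# significance at adjusted p < 0.05).

library(herbnetscreen)

bundle <- read_bundle("results/bundle")
active <- jsonlite::read_json("results/active_set.json", simplifyVector = TRUE)
targets <- as.character(active$potential_targets)

background <- unique(c(unlist(bundle$pathway_sets$members), targets))
res <- run_ora(targets, bundle$pathway_sets, background = background)

flat <- res
flat$hits <- vapply(res$hits, paste, "", collapse = ";")
readr::write_tsv(flat, "results/enrichment.tsv")

cat(sprintf("%d of %d pathway sets significant at adjusted p < 0.05\n",
            nrow(res), nrow(bundle$pathway_sets)))
if (nrow(res) > 0) {
  show <- flat[c("set_id", "k", "K", "n", "N", "p_raw", "p_adj")]
  show$p_raw <- signif(show$p_raw, 3)
  show$p_adj <- signif(show$p_adj, 3)
  print.data.frame(as.data.frame(show), row.names = FALSE)
}
jsonlite::write_json(list(selected_pathways = res$set_id),
                     "results/selected_pathways.json",
                     auto_unbox = TRUE, pretty = TRUE)
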