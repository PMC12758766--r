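#!/usr/bin/env Rscript
# Step 4: prey electivity. Two synthetic diet/habitat pairs with known
# ground truth are pushed through the Kimmerer-Slaughter index and its
# Beta Monte-Carlo intervals: a null pair (no selection) and a pair with a
# 4.5-fold preference for one taxon, both at the field-survey scale of a
# few dozen counted individuals, where the power to detect selection is
# low -- and again at a 20x larger gut sample, where it is not.

suppressPackageStartupMessages(library(chaetofeed))

seed <- 20260104
taxa <- c("Acartia", "Calanus", "Euaugaptilus", "Oithona", "Temora")
habitat_probs <- c(0.25, 0.25, 0.2, 0.2, 0.1)
odds_tilt <- c(1, 1, 1, 1, 4.5)   # Temora preferred

run <- function(label, selection_odds, N_G) {
  pair <- generate_diet_pair(taxa, habitat_probs, selection_odds,
                             N_G = N_G, N_A = 40, seed = seed)
  tab <- electivity_table(pair$gut, pair$habitat, n_sims = 10000,
                          seed = seed)
  tab$scenario <- label
  tab
}

tabs <- rbind(run("null_smallN", 1, 20),
              run("tilt_smallN", odds_tilt, 20),
              run("tilt_largeN", odds_tilt, 400))
write_table(tabs, "results/electivity.csv")

for (sc in unique(tabs$scenario)) {
  d <- tabs[tabs$scenario == sc, ]
  cat(sprintf("%s: indices %s -> classified %s\n", sc,
              paste(sprintf("%.2f", d$index), collapse = " "),
              paste(d$classification, collapse = "/")))
}
cat("\nat survey scale even a 4.5-fold preference is rarely significant;\n")
cat("the large-gut-sample run shows the same tilt flagged positive.\n")
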