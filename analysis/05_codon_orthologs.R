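#!/usr/bin/env Rscript
# Codon-position GC analysis of the simulated ortholog pairing: cleans
# both CDS sets, computes GC/GC1/GC2/GC3 distributions and their
# between-species overlaps, and fits major-axis regressions between all
# position pairs and between species.

suppressMessages(library(gcmosaic))

res <- run_codon("results/sim_orthologs/cds_a.fa",
                 "results/sim_orthologs/cds_b.fa",
                 "results/sim_orthologs/pairs.tsv",
                 "results/codon")

cat("\nPer-statistic means (species A vs B) and histogram overlap:\n")
m <- reshape(res$distributions$means, idvar = "statistic",
             timevar = "species", direction = "wide")
m$overlap <- res$distributions$overlap[m$statistic]
m[-1] <- lapply(m[-1], round, 3)
print(m, row.names = FALSE)

cat("\nMajor-axis fits (within species A):\n")
wa <- res$fits[res$fits$scope == "within_a", ]
wa[4:6] <- lapply(wa[4:6], round, 3)
print(wa, row.names = FALSE)

ov3 <- res$distributions$overlap[["gc3"]]
cat(sprintf(
  "\nGC3 distributions of the two species overlap by %.3f -- the near-%s",
  ov3, "complete separation expected from a 25%-GC shift at sd 5.\n"))
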