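#!/usr/bin/env Rscript
# Relative contact order (RCO) from atomic coordinates: the average
# sequence separation of heavy-atom contacts (6 A cutoff, |i-j| >= 2)
# normalised by chain length. RCO is the classic topological correlate of
# folding rate; for the UCH paralogs the published catalytic-domain values
# cluster near 0.14, so topology alone cannot explain their four-orders-of-
# magnitude rate differences. Without bundled crystal structures this
# driver demonstrates the computation on synthetic folds of increasing
# long-range contact content; point it at real PDB files to reproduce the
# cross-paralog comparison.

library(uchfold)
dir.create("results", showWarnings = FALSE)

# synthetic folds: a collapsed random coil gains long-range contacts as the
# compaction increases
make_fold <- function(n_res, compaction, seed) {
  set.seed(seed)
  steps <- matrix(rnorm(3 * n_res), ncol = 3)
  ca <- apply(steps, 2, cumsum) * 3.8 / sqrt(3)
  ca <- ca * compaction  # pull the walk inward: more non-local contacts
  do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(resno = i,
               x = ca[i, 1] + c(0, 1.5, 0), y = ca[i, 2] + c(0, 0, 1.5),
               z = ca[i, 3] + c(0, 0, 0))
  }))
}

rows <- lapply(c(extended = 1.0, compact = 0.5, collapsed = 0.3), function(cmp) {
  atoms <- make_fold(60, cmp, seed = 42)
  r <- relative_contact_order(atoms)
  data.frame(compaction = cmp, rco = r$rco, n_contacts = r$n_contacts,
             n_residues = r$n_residues)
})
tab <- do.call(rbind, rows)
tab$fold <- rownames(tab)
print(tab[, c("fold", "compaction", "rco", "n_contacts")], row.names = FALSE)
cat("-> tighter packing raises both the contact count and the mean sequence\n")
cat("   separation of contacts, hence the RCO\n")
write.csv(tab, "results/contact_order.csv", row.names = FALSE)
cat("wrote results/contact_order.csv\n")
cat("\nFor crystal structures: relative_contact_order(\"file.pdb\", chain = \"A\")\n")
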