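#!/usr/bin/env Rscript
# Alpha/beta diversity of each layer: per-sample Shannon index, Mann-Whitney
# group comparison of alpha diversity, Bray-Curtis PCoA, and the PERMANOVA
# (Adonis) test of community structure between patients and controls.
# Reads results/sim/, writes results/diversity_*.tsv.

suppressMessages(library(momnet))

samples <- read_metadata("results/sim/metadata.tsv")
grp <- unname(samples$group)

alpha_rows <- list(); adonis_rows <- list()
for (lay in c("virome", "bacteria", "metabolite")) {
  tb <- read_abundance(file.path("results/sim", paste0(lay, ".tsv")), lay)
  H <- shannon(tb)
  wt <- suppressWarnings(wilcox.test(H[grp == "case"], H[grp == "control"]))
  d <- bray_curtis(tb)
  ord <- pcoa(d, k = 2)
  pm <- permanova(d, grp, n_perm = 999, seed = 7)
  alpha_rows[[lay]] <- data.frame(
    layer = lay, shannon_case = mean(H[grp == "case"]),
    shannon_control = mean(H[grp == "control"]), mw_p = wt$p.value)
  adonis_rows[[lay]] <- data.frame(
    layer = lay, pseudo_F = pm$pseudo_F, R2 = pm$R2, p = pm$p,
    pco1_var = ord$relative_eig[1], pco2_var = ord$relative_eig[2])
  utils::write.table(
    data.frame(sample_id = names(H), shannon = H, group = grp,
               PCo1 = ord$coordinates[, 1], PCo2 = ord$coordinates[, 2]),
    sprintf("results/diversity_%s_samples.tsv", lay),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
alpha <- do.call(rbind, alpha_rows); adonis <- do.call(rbind, adonis_rows)
utils::write.table(alpha, "results/diversity_alpha.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(adonis, "results/diversity_permanova.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Alpha diversity (Shannon, nats) and group tests:\n")
print(alpha, row.names = FALSE, digits = 3)
cat("\nPERMANOVA on Bray-Curtis distances (999 permutations):\n")
print(adonis, row.names = FALSE, digits = 3)
cat("\nThe group effect enters through the planted differential features,\n")
cat("so layers separate to the extent those features shift community structure.\n")
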