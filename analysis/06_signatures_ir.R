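#!/usr/bin/env Rscript
# Construct scFes cell-type signatures from the labeled multi-platform
# datasets, validate their specificity on the sorted compendium, and derive
# the positive / negative immune-recruitment tumor features.

suppressMessages(library(braintme))
dir.create("results", showWarnings = FALSE)

sets <- lapply(c("mb10x", "mbss", "epn10x", "epnss"), function(nm) {
  ds <- read_expression_mtx(file.path("results/data", nm))
  if (ds$platform == "droplet-count") ds <- qc_filter(ds)
  normalize_expression(ds)
})
names(sets) <- c("mb10x", "mbss", "epn10x", "epnss")

sigs <- lapply(c("Tcell", "Myeloid", "OG", "Bcell"), function(ct)
  derive_scfes(sets, ct, "common"))
names(sigs) <- vapply(sigs, function(s) s$name, character(1))
for (s in sigs) print(s)
write_signatures(sigs, "results/scfes.gmt")

# specificity on the sorted purified-cell compendium
comp_m <- utils::read.table("results/data/compendium.tsv", sep = "\t",
                            header = TRUE, check.names = FALSE)
cm <- as.matrix(comp_m[, -1]); rownames(cm) <- comp_m$gene
types <- utils::read.table("results/data/compendium_types.tsv", sep = "\t",
                           header = TRUE)$cell_type
spec <- do.call(rbind, lapply(sigs, function(s) {
  sc <- tapply(score_signature(cm, s), types, mean)
  data.frame(signature = s$name, t(round(sc, 3)))
}))
utils::write.table(spec, "results/scfes_specificity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("mean signature score per sorted cell type:\n")
print(spec, row.names = FALSE)

# immune-recruitment features from tumor pseudobulk
pb <- utils::read.table("results/data/tumor_pseudobulk.tsv", sep = "\t",
                        header = TRUE, check.names = FALSE)
pm <- as.matrix(pb[, -1]); rownames(pm) <- pb$gene
ic <- utils::read.table("results/data/immune_content.tsv", sep = "\t",
                        header = TRUE)$immune_content
irf <- derive_ir_features(pm, ic)
cat(sprintf("IR features: %d positive, %d negative (rho > %.2f, q < %.2f)\n",
            length(irf$positive), length(irf$negative), irf$rho_min,
            irf$q_max))
write_gmt(gene_set_collection(list(positive_IR = irf$positive,
                                   negative_IR = irf$negative)),
          "results/ir_features.gmt")
utils::write.table(irf$table[order(-abs(irf$table$rho)), ],
                   "results/ir_correlations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote scfes.gmt, scfes_specificity.tsv, ir_features.gmt, ir_correlations.tsv\n")
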