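#!/usr/bin/env Rscript
# Generate the synthetic study data: multi-platform single-cell datasets with
# planted cell types, a pseudo-bulk cohort with planted archetypes and
# survival, a sorted purified-cell compendium, and tumor pseudobulk with
# planted immune-recruitment programs. Everything downstream (02-07) reads
# from results/data/.

suppressMessages(library(braintme))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

props <- c(Tcell = 0.3, Myeloid = 0.3, OG = 0.2, Bcell = 0.2)
cfg <- simulation_config(list(
  list(name = "mb10x", platform = "droplet-count", tumor_type = "MB",
       n_cells = 400, proportions = props),
  list(name = "mbss", platform = "full-length-tpm", tumor_type = "MB",
       n_cells = 400, proportions = props),
  list(name = "epn10x", platform = "droplet-count", tumor_type = "EPN",
       n_cells = 400, proportions = props),
  list(name = "epnss", platform = "full-length-tpm", tumor_type = "EPN",
       n_cells = 400, proportions = props)), seed = seed)
sets <- simulate_single_cell(cfg)
for (nm in names(sets)) {
  write_expression_mtx(sets[[nm]], file.path(out, nm))
  print(sets[[nm]])
}

cohort <- simulate_bulk_cohort(cfg)
write_bulk_cohort(cohort, file.path(out, "cohort"))
print(cohort)
cat("planted archetype sizes:\n")
print(table(cohort$samples$archetype))

comp <- simulate_sorted_compendium(cfg)
utils::write.table(
  data.frame(profile = colnames(comp$matrix), cell_type = comp$cell_type),
  file.path(out, "compendium_types.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(
  data.frame(gene = rownames(comp$matrix), comp$matrix, check.names = FALSE),
  file.path(out, "compendium.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("sorted compendium: %d profiles x %d genes, %d cell types\n",
            ncol(comp$matrix), nrow(comp$matrix),
            length(unique(comp$cell_type))))

ir <- simulate_ir_pseudobulk(cfg)
utils::write.table(
  data.frame(gene = rownames(ir$matrix), ir$matrix, check.names = FALSE),
  file.path(out, "tumor_pseudobulk.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(
  data.frame(sample = colnames(ir$matrix),
             immune_content = ir$immune_content),
  file.path(out, "immune_content.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("tumor pseudobulk: %d samples; planted IR programs: %d pos, %d neg\n",
            ncol(ir$matrix), length(ir$pos_genes), length(ir$neg_genes)))
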