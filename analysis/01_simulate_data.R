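#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with the
# ground truth recorded alongside. All outputs land under results/simdata/.

suppressPackageStartupMessages(library(betastab))
seed <- 20200828
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Exon/intron count matrices: 2000 genes, 3 control vs 3 knockout islet
## pools, 10% of genes stabilized and 10% transcriptionally induced
sim <- simulate_exon_intron_counts(2000, 3, seed = seed)
write_counts(sim$exon, file.path(out, "counts_exon.tsv"))
write_counts(sim$intron, file.path(out, "counts_intron.tsv"))
utils::write.table(sim$truth, file.path(out, "truth_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("counts: %d genes x %d samples (exon + intron), %d stabilized, %d tx-shifted\n",
            nrow(sim$exon$counts), ncol(sim$exon$counts),
            sum(sim$truth$stab_logfc > 0), sum(sim$truth$tx_logfc > 0)))

## A disallowed-like gene set: mostly planted-effect genes plus bystanders,
## for the enrichment stage
aff <- sim$truth$gene_id[sim$truth$stab_logfc > 0 | sim$truth$tx_logfc > 0]
set.seed(seed)
disallowed <- c(sample(aff, 45), sample(setdiff(sim$truth$gene_id, aff), 16))
write_gmt(list(gene_set("disallowed_like",
                        disallowed,
                        "synthetic beta-cell-disallowed-like set")),
          file.path(out, "disallowed_like.gmt"))
cat(sprintf("gene set: %d genes (45 affected, 16 bystanders)\n",
            length(disallowed)))

## Calcium traces: one control islet with strong beta-beta coupling and one
## knockout islet with a weaker, smaller coupled population
for (cfg in list(list(gt = "control", blocks = list(list(cells = 1:8, rho = 0.8),
                                                    list(cells = 9:14, rho = 0.7))),
                 list(gt = "knockout", blocks = list(list(cells = 1:5, rho = 0.6))))) {
  st <- simulate_traces(20, planted_blocks = cfg$blocks,
                        seed = seed + match(cfg$gt, c("control", "knockout")))
  write_traces(st$traces,
               file.path(out, sprintf("traces_%s.csv", cfg$gt)),
               file.path(out, sprintf("epochs_%s.csv", cfg$gt)))
  utils::write.table(
    data.frame(cell = rownames(st$truth$adjacency),
               n_partners = rowSums(st$truth$adjacency)),
    file.path(out, sprintf("truth_adjacency_%s.tsv", cfg$gt)),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("traces: 20 cells x 600 s per genotype (3G / 17G / KCl epochs)\n")

## Act-D decay courses: stabilized targets decay slower in the knockout,
## a non-target decays identically
decay_panel <- list(Aldob   = c(control = 2, knockout = 7),
                    Wnt5b   = c(control = 3, knockout = 9),
                    Cat     = c(control = 4, knockout = 10),
                    Yap1    = c(control = 3, knockout = 3))
decays <- do.call(rbind, lapply(names(decay_panel), function(g) {
  simulate_decay(decay_panel[[g]], cv = 0.05, n_reps = 3, gene = g,
                 seed = seed + which(names(decay_panel) == g))
}))
write_decay(decays, file.path(out, "decay_courses.csv"))
cat(sprintf("decay: %d courses (%s)\n", length(decay_panel),
            paste(names(decay_panel), collapse = ", ")))

## Bulk poly(A) densitograms: knockout shifts mass toward longer tails
gel_ctl <- simulate_densitogram(
  data.frame(length_nt = c(80, 20), weight = c(0.35, 0.65)),
  noise_sd = 0.0005, seed = seed + 11)
gel_ko <- simulate_densitogram(
  data.frame(length_nt = c(80, 20), weight = c(0.60, 0.40)),
  noise_sd = 0.0005, seed = seed + 12)
write_densitogram(gel_ctl, file.path(out, "densitogram_control.csv"),
                  file.path(out, "densitogram_marker.csv"))
write_densitogram(gel_ko, file.path(out, "densitogram_knockout.csv"),
                  file.path(out, "densitogram_marker.csv"))
cat("densitograms: control (35% > 50 nt planted) and knockout (60%)\n")
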