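#!/usr/bin/env Rscript
# Poly(A) tail densitometry (fraction of signal above 50 nt per genotype),
# gene-set enrichment of the disallowed-like set in the DE ranking, and
# transcriptome-proteome fold-change correlation.

suppressPackageStartupMessages(library(betastab))
simdir <- "results/simdata"
seed <- 20200828

## 1. poly(A): longer tails in the knockout
fr <- vapply(c("control", "knockout"), function(gt) {
  gel <- read_densitogram(
    file.path(simdir, sprintf("densitogram_%s.csv", gt)),
    file.path(simdir, "densitogram_marker.csv"))
  fraction_above(gel, 50)
}, 0)
cat(sprintf("poly(A) > 50 nt: control %.3f, knockout %.3f (difference %+.3f)\n",
            fr[["control"]], fr[["knockout"]],
            fr[["knockout"]] - fr[["control"]]))
utils::write.table(
  data.frame(genotype = names(fr), fraction_above_50nt = unname(fr)),
  "results/polya_fractions.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

## 2. GSEA of the disallowed-like set in the exon DE ranking
de <- utils::read.table("results/de_exon.tsv", header = TRUE, sep = "\t")
ranking <- rank_genes(de)
sets <- read_gmt(file.path(simdir, "disallowed_like.gmt"))
es <- gsea_es(ranking, sets[[1]])
gp <- gsea_permutation_p(ranking, sets[[1]], n_perm = 1000, seed = seed)
cat(sprintf("GSEA '%s': ES = %.3f, permutation p = %.3g, leading edge %d/%d\n",
            sets[[1]]$name, es$es, gp$p_perm, length(es$leading_edge),
            es$n_set_in_ranking))

## 3. transcriptome vs proteome: proteins follow mRNA with attenuation and
## measurement noise
set.seed(seed)
sig <- de[de$fdr < 0.05, ]
prot <- data.frame(protein_id = toupper(sig$gene_id),
                   log_fc = 0.8 * sig$log_fc +
                     stats::rnorm(nrow(sig), sd = 0.55))
co <- correlate_omics(sig[, c("gene_id", "log_fc")], prot)
cat(sprintf("mRNA vs protein logFC: r = %.3f, R2 = %.2f, p = %.3g (n = %d)\n",
            co$r, co$r_squared, co$p, co$n_matched))
utils::write.table(
  data.frame(r = co$r, r_squared = co$r_squared, p = co$p,
             n_matched = co$n_matched),
  "results/omics_correlation.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
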