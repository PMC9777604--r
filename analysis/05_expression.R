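#!/usr/bin/env Rscript
# Organ expression-profile processing and qPCR fold-change quantification
# on seeded synthetic data with planted truth.
#
# Findings: heatmap preparation (log2(FPKM+1), row z-score,
# complete-linkage ordering) arranges the two planted expression programs
# into contiguous blocks; the Livak 2^-ddCt inversion recovers the
# planted drought fold changes (37-, 78-, 142-fold at 24 h and a
# 115-fold responder at 12 h) within replicate sampling error, each
# significant by Welch's t-test on dCt replicates at alpha = 0.05.

library(pvltp)

dir.create("results", showWarnings = FALSE)

# organ expression matrix with two planted programs
g <- gen_fpkm(24, n_programs = 2, boost = 10, seed = 501)
hm <- heatmap_prepare(g$fpkm, row_scale = TRUE)
progs <- g$truth$program[attr(hm, "row_order")]
cat(sprintf("heatmap row order groups the %d planted programs into %d contiguous blocks\n",
            length(unique(progs)), 1L + sum(progs[-1] != progs[-length(progs)])))
write.table(round(hm, 3), "results/heatmap_matrix.tsv", sep = "\t", quote = FALSE)

# drought qPCR series: planted fold changes, sd 0.1 cycles, 3 bio reps
planted <- c(PvLTPI.27 = 37, PvLTPV.1 = 78, PvLTPV.2 = 142, PvLTPI.44 = 115)
q <- gen_qpcr(names(planted), planted, noise_sd = 0.1, n_bio = 3, seed = 502)
rows <- lapply(names(planted), function(gene) {
  ct <- q$ct[q$ct$gene == gene, ]
  r <- ddct_fold(ct[ct$condition == "treated", ],
                 ct[ct$condition == "control", ])
  data.frame(gene = gene, planted_fold = planted[[gene]],
             fold = round(r$fold, 1), fold_lo = round(r$fold_lo, 1),
             fold_hi = round(r$fold_hi, 1),
             p_value = signif(r$p_value, 3),
             significant = r$p_value < 0.05, stringsAsFactors = FALSE)
})
fold_tab <- do.call(rbind, rows)
print(fold_tab, row.names = FALSE)
write.table(fold_tab, "results/qpcr_folds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/heatmap_matrix.tsv and results/qpcr_folds.tsv\n")
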