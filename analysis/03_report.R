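#!/usr/bin/env Rscript

# Step 3: per-region summaries and figures.
#
# For the consensus regions found in step 2: per-group five-number summaries
# of the raw volumes (the numbers behind a group boxplot) and the AUC each
# region achieves on its own — the regions do not retain the multivariate
# accuracy in isolation. Draws the boxplots and the decision-value ROC curve
# to results/figures.pdf.

suppressPackageStartupMessages(library(morphclass))

out_dir <- "results"
rep_ <- jsonlite::read_json(file.path(out_dir, "report.json"),
                            simplifyVector = TRUE)
tab <- read_feature_table(file.path(out_dir, "cohort.csv"),
                          positive_class = "meditator")

consensus <- rep_$consensus_regions
if (!length(consensus)) {
  message("no consensus regions in this run; summarising the 5 most selected")
  freq <- read.csv(file.path(out_dir, "selection_frequencies.csv"))
  consensus <- freq$region[1:5]
}
rs <- region_summary(tab, consensus)
write.csv(rs, file.path(out_dir, "region_summary.csv"), row.names = FALSE)
print(rs, digits = 4)

pdf(file.path(out_dir, "figures.pdf"), width = 9, height = 4.5)
op <- par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
boxplot(tab$X[, consensus[1]] ~ tab$group,
        xlab = "", ylab = expression(volume ~ (mm^3)),
        main = consensus[1], col = c("grey85", "lightsteelblue"))
plot(rep_$roc$points$fpr, rep_$roc$points$tpr, type = "s", lwd = 2,
     xlab = "false positive rate", ylab = "true positive rate",
     main = sprintf("decision-value ROC (AUC %.3f)", rep_$roc$auc))
abline(0, 1, lty = 3)
par(op)
invisible(dev.off())
message("wrote region_summary.csv and figures.pdf under results/")
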