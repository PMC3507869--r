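#!/usr/bin/env Rscript
# Stage 3: epigenetic distance analysis and the hypomethylation screen.
#
# Ordinates all samples (both digests) by PCoA of Euclidean band
# distances, writes group centroids per line x enzyme, then screens every
# line by a two-group AMOVA of its HpaII vs MspI profiles (squared
# Euclidean distances, PhiPT, 9,999 label permutations): lines whose
# digests no longer diverge (permutation p > 0.05) are called effectively
# hypomethylated.

suppressPackageStartupMessages(library(epimsap))
SEED <- 1234L
out <- "results"
hpaii <- read_msap("results/run/msap_hpaii.tsv")
mspi <- read_msap("results/run/msap_mspi.tsv")
lines <- read.csv("results/run/lines.csv")

both <- rbind(hpaii$values, mspi$values)
rownames(both) <- c(paste0(rownames(hpaii$values), "_H"),
                    paste0(rownames(mspi$values), "_M"))
d <- msap_dist(both, metric = "euclidean")
p <- pcoa(d, n_axes = 2)
print(p)
grp <- paste(rep(hpaii$samples$line_id, 2),
             rep(c("HpaII", "MspI"), each = nrow(hpaii$values)), sep = ":")
write.csv(data.frame(sample = rownames(p$coordinates), group = grp,
                     p$coordinates),
          file.path(out, "pcoa_coordinates.csv"), row.names = FALSE)
cent <- group_centroids(p, grp)
write.csv(data.frame(group = rownames(cent), cent),
          file.path(out, "pcoa_centroids.csv"), row.names = FALSE)

scr <- screen_lines(hpaii, mspi, alpha = 0.05, n_permutations = 9999,
                    seed = SEED)
print(scr)
write.csv(as.data.frame(scr), file.path(out, "screen.csv"),
          row.names = FALSE)

flagged <- scr$line_id[scr$classified_hypomethylated]
truth <- lines$line_id[lines$effective]
message(sprintf("flagged: %s", paste(sort(flagged), collapse = ", ")))
message(sprintf("generator truth: %s", paste(sort(truth), collapse = ", ")))
message(sprintf("sensitivity %.2f, specificity %.2f",
                length(intersect(flagged, truth)) / length(truth),
                sum(!(scr$line_id %in% union(flagged, truth))) /
                  (nrow(scr) - length(truth))))
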