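#!/usr/bin/env Rscript
# Branching times and lineage-through-time series for the whole synthetic
# subfamily and each clade, exported as TSV plus a semilog LTT figure.

suppressPackageStartupMessages(library(bdltest))

data_dir <- "results/data"
out <- "results"
tree <- read_tree_file(file.path(data_dir, "tree.nwk"))
clades <- read.delim(file.path(data_dir, "clades.tsv"))

series <- list(all = ltt(branching_times(tree)))
for (cl in unique(clades$clade)) {
  sub <- prune_to_clade(tree, clades$taxon[clades$clade == cl])
  series[[cl]] <- ltt(branching_times(sub))
}

for (nm in names(series)) {
  f <- file.path(out, paste0("ltt_", nm, ".tsv"))
  write_ltt_tsv(series[[nm]], f)
  cat(sprintf("%-8s %2d lineages at present, crown %.2f Myr -> %s\n",
              nm, max(series[[nm]]$count), max(series[[nm]]$age), f))
}

pdf(file.path(out, "fig_ltt.pdf"), width = 6, height = 4.5)
cols <- c(all = "darkgreen", mexican = "goldenrod", gulf = "steelblue")
plot(NULL, xlim = rev(range(series$all$age)), ylim = c(log(2), log(30)),
     xlab = "Age (Myr before present)", ylab = "ln(lineages)",
     main = "Lineages through time")
for (nm in names(series))
  lines(series[[nm]]$age, series[[nm]]$log_count, type = "s",
        col = cols[[nm]], lwd = 2)
legend("topleft", legend = names(series), col = cols[names(series)],
       lwd = 2, bty = "n")
invisible(dev.off())
cat("figure -> results/fig_ltt.pdf\n")
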