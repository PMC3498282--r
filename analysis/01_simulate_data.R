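#!/usr/bin/env Rscript
# Build the synthetic study dataset: a dated two-clade ultrametric tree
# shaped like a small freshwater-crayfish subfamily (a "Mexican"-type clade
# with crown age 11.1 Myr and a "Gulf"-type clade with crown age 16.7 Myr,
# joined at a 21.9-Myr root), a clade-membership table, and a 16S-like
# HKY+Gamma alignment evolved along the tree.
#
# Everything downstream (02-05) reads the files this script writes under
# results/data/.

suppressPackageStartupMessages(library(bdltest))

seed <- 20120914L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

clades <- list(
  mexican = list(n = 14, lambda = 0.174, crown = 11.1),
  gulf    = list(n = 12, lambda = 0.106, crown = 16.7)
)
root_age <- 21.9

subs <- list()
i <- 0
for (nm in names(clades)) {
  i <- i + 1
  cl <- clades[[nm]]
  tr <- simulate_yule(n_tips = cl$n, lambda = cl$lambda, seed = seed + i)
  tr <- rescale_root_age(tr, cl$crown)   # pin the crown to the dated age
  tr$tip.label <- sprintf("%s_%02d", nm, seq_len(cl$n))
  subs[[nm]] <- tr
  cat(sprintf("%s clade: %d tips, crown %.1f Myr\n", nm, cl$n, cl$crown))
}

strip <- function(tr) sub(";$", "", write_newick(tr))
newick <- sprintf("(%s:%.10g,%s:%.10g);",
                  strip(subs$mexican), root_age - clades$mexican$crown,
                  strip(subs$gulf), root_age - clades$gulf$crown)
tree <- parse_tree(newick)
stopifnot(check_ultrametric(tree, 1e-8))
write_newick(tree, file.path(out, "tree.nwk"))
cat(sprintf("joined tree: %d tips, crown %.1f Myr -> %s\n",
            ape::Ntip(tree), crown_age(tree), file.path(out, "tree.nwk")))

clade_table <- do.call(rbind, lapply(names(subs), function(nm)
  data.frame(taxon = subs[[nm]]$tip.label, clade = nm)))
write.table(clade_table, file.path(out, "clades.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# 16S-like fragment: 501 bp, HKY with kappa ~ 4, gamma shape 0.232,
# ~0.5% substitutions per site per Myr
aln <- simulate_alignment(tree, length = 501, kappa = 4,
                          base_freqs = c(0.33, 0.12, 0.20, 0.35),
                          gamma_alpha = 0.232, rate_per_unit = 0.005,
                          seed = seed + 10)
write_fasta(aln, file.path(out, "locus16S.fasta"))
cat(sprintf("alignment: %d taxa x %d sites -> %s\n",
            nrow(aln), ncol(aln), file.path(out, "locus16S.fasta")))
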