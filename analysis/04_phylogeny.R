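#!/usr/bin/env Rscript
# Stage 4: subfamily phylogeny — center-star protein alignment, Poisson
# distances, neighbor-joining tree with seeded bootstrap supports.

library(loxfamily)

run_dir <- "results/run"
proteins <- read_fasta(file.path(run_dir, "data", "proteins.fasta"),
                       "protein")
filt <- read.delim(file.path(run_dir, "bona_fide_filter.tsv"))
asg <- read.delim(file.path(run_dir, "subfamily_assignment.tsv"))
members <- filt$gene_id[filt$bona_fide]

msa <- align_progressive(proteins[members], alignment_params("protein"))
tree <- bootstrap_support(msa, "poisson", replicates = 200, seed = 1)
ape::write.tree(tree, file.path(run_dir, "family_tree.nwk"))
write_fasta(setNames(as.vector(msa), names(msa)),
            file.path(run_dir, "family_alignment.fasta"))

# do the subfamilies form clades?
parts <- ape::prop.part(tree)
labs <- attr(parts, "labels")
sf <- setNames(asg$subfamily, asg$gene_id)
clades <- lapply(parts, function(p) labs[p])
# on an unrooted tree a group is a clade iff it (or its complement) is a
# bipartition side
monophyletic <- function(grp) {
  comp <- setdiff(labs, grp)
  any(vapply(clades, setequal, logical(1), grp)) ||
    any(vapply(clades, setequal, logical(1), comp))
}
for (s in unique(sf)) {
  cat(s, "members form a clade:",
      monophyletic(names(sf)[sf == s]), "\n")
}
cat("bootstrap supports:", paste(tree$node.label, collapse = " "), "\n")
cat("tree written to", file.path(run_dir, "family_tree.nwk"), "\n")
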