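#!/usr/bin/env Rscript
# Stage 3: member characterization — protein properties, gene structures,
# identity matrices, duplication classification.

library(loxfamily)

run_dir <- "results/run"
proteins <- read_fasta(file.path(run_dir, "data", "proteins.fasta"),
                       "protein")
filt <- read.delim(file.path(run_dir, "bona_fide_filter.tsv"))
members <- filt$gene_id[filt$bona_fide]

models <- read_gff3(file.path(run_dir, "data", "genes.gff3"))[members]
gm <- gene_model_table(models)
gm$protein_aa <- orf_to_protein_length(gm$orf_bp)
gm$mw_kda <- vapply(proteins[gm$gene_id], molecular_weight, numeric(1),
                    unit = "kDa")
gm$pi <- vapply(proteins[gm$gene_id], isoelectric_point, numeric(1))
write_tsv(gm, file.path(run_dir, "member_properties.tsv"))

st <- gene_structure_table(models)
write_tsv(st, file.path(run_dir, "gene_structures.tsv"))

idm <- identity_matrix(proteins[members], alignment_params("protein"))
write_identity_matrix(idm, file.path(run_dir, "identity_matrix_aa.tsv"))
dup <- detect_duplications(gm, idm)
write_tsv(dup, file.path(run_dir, "duplications.tsv"))

cat("molecular weights:", min(gm$mw_kda), "-", max(gm$mw_kda), "kDa; pI:",
    min(gm$pi), "-", max(gm$pi), "\n")
cat("intron phases observed:",
    paste(sort(unique(unlist(strsplit(st$intron_phases, ",")))),
          collapse = "/"), "\n")
cat("duplication calls:\n"); print(dup)
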