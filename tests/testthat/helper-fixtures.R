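## Fixture builders: tiny FASTA/GFF3 pairs written to tempfiles, and small
## simulation configurations shared across tests.

write_toy_genome <- function(seqs, features, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("toygenome")
    dir.create(dir)
  }
  fa <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), fa)
  gff <- file.path(dir, "annotation.gff3")
  lines <- c("##gff-version 3")
  if (nrow(features) > 0L) {
    lines <- c(lines, paste(features$chrom, "test", features$type,
                            features$start_1, features$end_1, ".",
                            features$strand, ".",
                            paste0("ID=", features$id), sep = "\t"))
  }
  writeLines(lines, gff)
  list(fasta = fa, gff = gff, dir = dir)
}

## features helper: 1-based inclusive coordinates as in a GFF3 file
gff_feature <- function(id, type, chrom, start_1, end_1, strand = "+") {
  data.frame(id = id, type = type, chrom = chrom, start_1 = start_1,
             end_1 = end_1, strand = strand, stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 42L, depth = 2, ...) {
  sim_config(seed = seed, n_chromosomes = 1L, chrom_length = 40000L,
             n_full_elements = 3L, include_chimeric = TRUE, n_solitary = 6L,
             n_genes = 4L, n_ltr_gene_pairs = 2L, n_trna = 1L, n_snorna = 1L,
             depth = depth, ...)
}
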