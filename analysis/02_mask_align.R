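#!/usr/bin/env Rscript
# Hard-mask the pseudogene duplication in the reference and align every
# sample's reads to the masked reference. After masking, the duplicated
# block is unmappable, so reads from all four homologous copies collapse
# onto the gene; the resulting SAMs and pileups feed the genotyping stage.

library(paramask)

sim_dir <- "results/sim"
out_dir <- "results/align"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

refseq <- read_fasta(file.path(sim_dir, "reference.fa"))
mask <- read_bed(file.path(sim_dir, "mask.bed"))
masked <- mask_reference(refseq, mask, coords = "bed")
write_fasta(masked, file.path(out_dir, "reference.masked.fa"))
message(sprintf("masked %d bases of %d (%.1f%%)",
                sum(mask$end - mask$start), nchar(refseq[[1]]),
                100 * sum(mask$end - mask$start) / nchar(refseq[[1]])))

offsets <- jsonlite::read_json(file.path(sim_dir, "offsets.json"))
gene_len <- offsets$gene$length
idx <- build_kmer_index(masked, 13L)

samples <- sub("_R1\\.fastq$", "",
               basename(list.files(sim_dir, pattern = "_R1\\.fastq$")))
for (nm in samples) {
  rs <- read_fastq(file.path(sim_dir, paste0(nm, c("_R1.fastq", "_R2.fastq"))))
  aln <- map_reads(rs, masked, index = idx)
  write_sam(aln, masked, file.path(out_dir, paste0(nm, ".sam")))
  pu <- pileup(aln, masked, region = c(1, gene_len))
  write_tsv(pu, file.path(out_dir, paste0(nm, ".pileup.tsv")))
  message(sprintf("%s: %d/%d reads aligned, mean gene depth %.1f",
                  nm, sum(!is.na(aln$pos)), nrow(aln),
                  mean(pu$depth)))
}
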