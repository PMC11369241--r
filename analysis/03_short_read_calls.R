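#!/usr/bin/env Rscript
# Short-read variant stage: derive the PSV catalog by aligning the two loci
# (independently of the simulator), scan the masked pileups for candidate
# sites, genotype them under the four-copy allele-balance model, and try to
# assign each variant to gene vs pseudogene via PSV co-observation.

library(paramask)

sim_dir <- "results/sim"
aln_dir <- "results/align"
out_dir <- "results/sr_calls"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

refseq <- read_fasta(file.path(sim_dir, "reference.fa"))
offsets <- jsonlite::read_json(file.path(sim_dir, "offsets.json"))
gene_len <- offsets$gene$length
gene_seq <- substr(refseq[[1]], 1, gene_len)
pseudo_seq <- substr(refseq[[1]], gene_len + 1, nchar(refseq[[1]]))

hmap <- derive_homology_map(gene_seq, pseudo_seq)
print(hmap)
write_homology_map(hmap, file.path(out_dir, "psv_catalog.tsv"),
                   file.path(out_dir, "homology_blocks.bed"),
                   contig = offsets$contig)

samples <- sub("\\.sam$", "", basename(list.files(aln_dir, pattern = "\\.sam$")))
all_calls <- list()
for (nm in samples) {
  aln <- read_sam(file.path(aln_dir, paste0(nm, ".sam")))
  pu <- read.delim(file.path(aln_dir, paste0(nm, ".pileup.tsv")))
  calls <- scan_candidates(pu, hmap, aln)
  if (nrow(calls)) all_calls[[nm]] <- cbind(sample = nm, calls)
  message(sprintf("%s: %d candidate site(s)", nm, nrow(calls)))
  if (nrow(calls))
    print(as.data.frame(calls)[, c("pos", "ref", "alt", "kind", "alt_count",
                                   "depth", "theta_map", "map_label",
                                   "locus")])
}
calls_tbl <- data.table::rbindlist(all_calls)
write_tsv(calls_tbl, file.path(out_dir, "site_calls.tsv"))

# score against the simulator's truth
truth <- read.delim(file.path(sim_dir, "truth_variants.tsv"))
truth$gene_pos <- ifelse(
  truth$locus == "gene", truth$pos,
  project_position(truth$pos, hmap, from = "pseudo"))
n_hit <- sum(paste(truth$sample, truth$gene_pos) %in%
               paste(calls_tbl$sample, calls_tbl$pos))
message(sprintf("recovered %d / %d truth variants; %d calls total",
                n_hit, nrow(truth), nrow(calls_tbl)))
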