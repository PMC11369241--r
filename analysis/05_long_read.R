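#!/usr/bin/env Rscript
# Long-read rescue stage, on a geometry whose introns are long enough to
# hold a 1678-bp deletion inside the homology block:
#   (a) family-11 pattern: recover a het 1678-bp gene exon deletion from
#       alignment gaps at 30x, with locus attribution from PSV binning;
#   (b) family-8 pattern: confirm homozygosity of a gene SNV that short
#       reads saw at ~50%, by re-genotyping gene-binned reads only;
#   (c) phase two het variants to establish trans (biallelic) configuration.

library(paramask)

out_dir <- "results/long_read"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ref <- make_paralog_reference(n_exons = 8, dup_first = 2, dup_last = 7,
                              exon_len = 200, intron_len = 800,
                              identity = 0.98, seed = 42)
hmap <- derive_homology_map(ref$gene_seq, ref$pseudo_seq)
paths <- write_reference(ref, file.path(out_dir, "ref"))
masked <- mask_reference(read_fasta(paths$fasta), read_bed(paths$mask_bed))
other <- function(seq, p) setdiff(c("A", "C", "G", "T"),
                                  substr(seq, p, p))[1]

## (a) 1678-bp exon deletion
d_start <- ref$exons$start[4] - 739L
truth_del <- sample_truth("S_del", exon_deletions = data.frame(
  locus = "gene", haplotype = 1L, start = d_start, end = d_start + 1677L))
haps <- simulate_sample(ref, truth_del)
lr <- simulate_long_reads(haps, coverage = 30, len_mean = 3000, len_sd = 800,
                          sub_error = 0.02, indel_error = 0.01, seed = 11)
write_fastq(lr, file.path(out_dir, "S_del.long"))
aln <- map_reads(lr, masked, k = 15, band = 60)
write_sam(aln, masked, file.path(out_dir, "S_del.sam"))
bins <- bin_reads(aln, hmap, q = 0.05)
write_tsv(bins, file.path(out_dir, "S_del.bins.tsv"))
dels <- detect_deletions(aln, bins, min_sv_len = 200, min_support = 3,
                         cluster_tol = 20)
write_tsv(dels, file.path(out_dir, "S_del.sv_calls.tsv"))
message("deletion calls (truth: start ", d_start, ", length 1678, gene):")
print(dels)
if (nrow(dels)) {
  cons <- annotate_consequence(
    list(kind = "sv_del", start = dels$start[1], end = dels$end[1]),
    ref$exons, ref$gene_seq)
  message(sprintf("consequence: %s (net %d coding nt)",
                  cons$kind, cons$details$net_nt))
}

## (b) homozygosity confirmation
p_hom <- ref$exons$start[5] + 90L
ab <- other(ref$gene_seq, p_hom)
truth_hom <- sample_truth("S_hom", small_variants = data.frame(
  locus = "gene", haplotype = c(1L, 2L), pos = p_hom,
  ref = substr(ref$gene_seq, p_hom, p_hom), alt = ab, kind = "snv"))
haps <- simulate_sample(ref, truth_hom)
lr <- simulate_long_reads(haps, coverage = 30, len_mean = 2500, len_sd = 600,
                          sub_error = 0.02, indel_error = 0.01, seed = 12)
aln <- map_reads(lr, masked, k = 15, band = 60)
bins <- bin_reads(aln, hmap, q = 0.05)
rg <- regenotype_per_locus(bins, aln, p_hom, ab, e = 0.02, min_reads = 5L,
                           ref_seq = ref$gene_seq)
message(sprintf(
  "site %d gene-binned re-genotype: %s (%d/%d alt reads, posterior %.3f)",
  p_hom, rg$genotype, rg$alt_count, rg$depth, rg$posterior))
write_tsv(data.frame(pos = p_hom, alt = ab, rg[c("genotype", "alt_count",
                                                 "depth", "posterior")]),
          file.path(out_dir, "S_hom.regenotype.tsv"))

## (c) phasing two het variants simulated in trans
p1 <- ref$exons$start[3] + 50L
p2 <- ref$exons$start[4] + 120L
hs <- data.frame(pos = c(p1, p2),
                 ref = c(substr(ref$gene_seq, p1, p1),
                         substr(ref$gene_seq, p2, p2)),
                 alt = c(other(ref$gene_seq, p1), other(ref$gene_seq, p2)))
truth_ph <- sample_truth("S_phase", small_variants = data.frame(
  locus = "gene", haplotype = c(1L, 2L), pos = hs$pos, ref = hs$ref,
  alt = hs$alt, kind = "snv"))
haps <- simulate_sample(ref, truth_ph)
lr <- simulate_long_reads(haps, coverage = 30, len_mean = 3000, len_sd = 500,
                          sub_error = 0.02, indel_error = 0.01, seed = 13)
aln <- map_reads(lr, masked, k = 15, band = 60)
bins <- bin_reads(aln, hmap, q = 0.05)
gene_reads <- bins$read_id[bins$assigned_locus == "gene"]
ph <- phase_variants(aln[aln$read_id %in% gene_reads, ], hs,
                     ref_seq = ref$gene_seq)
write_tsv(ph, file.path(out_dir, "S_phase.blocks.tsv"))
message(sprintf("sites %d and %d phase as: %s (truth: trans)",
                p1, p2, pair_phase(ph, p1, p2)))
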