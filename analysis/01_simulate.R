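#!/usr/bin/env Rscript
# Build the study reference pair and a small diploid case roster, and write
# every input the later stages consume: reference FASTA + mask BED, paired
# short-read FASTQs, and the per-sample truth tables.
#
# The roster mirrors the diagnostic patterns of interest:
#   S1_comphet - two heterozygous gene SNVs in trans (compound het)
#   S2_hom     - one homozygous gene SNV in the homology block
#   S3_pseudo  - a homozygous gene variant plus a het pseudogene-only SNV
#                (the pattern that looks triallelic until the pseudogene
#                 copy is recognised)
#   S5_null    - no variants

library(paramask)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ref <- make_paralog_reference(n_exons = 8, dup_first = 2, dup_last = 7,
                              exon_len = 200, intron_len = 300,
                              identity = 0.98, seed = 42)
print(ref)
paths <- write_reference(ref, out_dir)
write_tsv(ref$exons, file.path(out_dir, "exons.tsv"))

other <- function(seq, p) setdiff(c("A", "C", "G", "T"),
                                  substr(seq, p, p))[1]
gsnv <- function(p, hap) data.frame(
  locus = "gene", haplotype = hap, pos = p,
  ref = substr(ref$gene_seq, p, p), alt = other(ref$gene_seq, p),
  kind = "snv")

p1 <- ref$exons$start[3] + 37L
p2 <- ref$exons$start[5] + 81L
p_hom <- ref$exons$start[4] + 90L
p_ps <- ref$pseudo_hom_interval[1] +
  (ref$exons$start[6] + 55L - ref$homology_interval[1])

roster <- list(
  S1_comphet = sample_truth("S1_comphet",
                            small_variants = rbind(gsnv(p1, 1L), gsnv(p2, 2L))),
  S2_hom = sample_truth("S2_hom",
                        small_variants = rbind(gsnv(p_hom, 1L),
                                               gsnv(p_hom, 2L))),
  S3_pseudo = sample_truth("S3_pseudo", small_variants = rbind(
    gsnv(p_hom, 1L), gsnv(p_hom, 2L),
    data.frame(locus = "pseudo", haplotype = 2L, pos = p_ps,
               ref = substr(ref$pseudo_seq, p_ps, p_ps),
               alt = other(ref$pseudo_seq, p_ps), kind = "snv"))),
  S5_null = sample_truth("S5_null"))

truth_rows <- list()
for (nm in names(roster)) {
  haps <- simulate_sample(ref, roster[[nm]])
  rs <- simulate_short_reads(haps, coverage = 100, sub_error = 0.002,
                             seed = match(nm, names(roster)))
  write_fastq(rs, file.path(out_dir, nm))
  tv <- roster[[nm]]$small_variants
  if (nrow(tv)) truth_rows[[nm]] <- cbind(sample = nm, tv)
  message(sprintf("%s: %d read pairs, %d truth variants",
                  nm, nrow(rs) / 2, nrow(tv)))
}
write_tsv(do.call(rbind, truth_rows), file.path(out_dir, "truth_variants.tsv"))
message("reference, mask BED and FASTQs under ", out_dir)
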