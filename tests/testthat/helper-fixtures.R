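# Shared fixtures, built once per test run and cached. All data are
# generated in code; seeds are fixed so every run sees identical inputs.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# default toy locus pair: 8 exons, exons 2-7 duplicated at 98% identity
toy_ref <- function() fixture("toy_ref", function() {
  make_paralog_reference(n_exons = 8, dup_first = 2, dup_last = 7,
                         exon_len = 200, intron_len = 300,
                         identity = 0.98, seed = 42)
})

toy_map <- function() fixture("toy_map", function() {
  r <- toy_ref()
  derive_homology_map(r$gene_seq, r$pseudo_seq)
})

toy_masked <- function() fixture("toy_masked", function() {
  r <- toy_ref()
  d <- file.path(tempdir(), "toy_ref_dir")
  out <- write_reference(r, d)
  mask_reference(read_fasta(out$fasta), read_bed(out$mask_bed))
})

# geometry used for read-depth CNV work: longer exons give per-exon depth
# estimates tight enough to separate the 0.75 het-deletion ratio from 1.0
cnv_ref <- function() fixture("cnv_ref", function() {
  make_paralog_reference(n_exons = 8, dup_first = 3, dup_last = 6,
                         exon_len = 1400, intron_len = 300,
                         identity = 0.98, seed = 42)
})

cnv_map <- function() fixture("cnv_map", function() {
  r <- cnv_ref()
  derive_homology_map(r$gene_seq, r$pseudo_seq)
})

cnv_masked <- function() fixture("cnv_masked", function() {
  r <- cnv_ref()
  d <- file.path(tempdir(), "cnv_ref_dir")
  out <- write_reference(r, d)
  mask_reference(read_fasta(out$fasta), read_bed(out$mask_bed))
})

# geometry for long-read work: introns long enough that a 1678-bp deletion
# (exon plus flanking intronic sequence) fits inside the homology block
lr_ref <- function() fixture("lr_ref", function() {
  make_paralog_reference(n_exons = 8, dup_first = 2, dup_last = 7,
                         exon_len = 200, intron_len = 800,
                         identity = 0.98, seed = 42)
})

lr_map <- function() fixture("lr_map", function() {
  r <- lr_ref()
  derive_homology_map(r$gene_seq, r$pseudo_seq)
})

lr_masked <- function() fixture("lr_masked", function() {
  r <- lr_ref()
  d <- file.path(tempdir(), "lr_ref_dir")
  out <- write_reference(r, d)
  mask_reference(read_fasta(out$fasta), read_bed(out$mask_bed))
})

# a non-reference base for a given position
other_base <- function(seq, pos) {
  setdiff(c("A", "C", "G", "T"), substr(seq, pos, pos))[1]
}

# one-row small-variant spec at a gene position
snv_row <- function(ref, pos, haplotype, locus = "gene") {
  base_seq <- if (locus == "gene") ref$gene_seq else ref$pseudo_seq
  data.frame(locus = locus, haplotype = haplotype, pos = pos,
             ref = substr(base_seq, pos, pos),
             alt = other_base(base_seq, pos), kind = "snv",
             stringsAsFactors = FALSE)
}

# gene position -> pseudogene-locus position (toy refs have one block)
pseudo_pos_of <- function(ref, gene_pos) {
  gene_pos - ref$homology_interval[1] + ref$pseudo_hom_interval[1]
}
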