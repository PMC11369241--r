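# Long-read rescue: PSV binning, per-locus re-genotyping, deletion calling
# and read-backed phasing.

test_that("PSV voting bins error-free reads with the expected log-odds", {
  ref <- toy_ref()
  hmap <- toy_map()
  masked <- toy_masked()
  haps <- simulate_sample(ref, sample_truth("S0"))
  lr <- simulate_long_reads(haps, coverage = 15, len_mean = 1500,
                            len_sd = 300, sub_error = 0, indel_error = 0,
                            seed = 51)
  aln <- map_reads(lr, masked, k = 15, band = 60)
  bins <- bin_reads(aln, hmap, q = 0.05)
  j <- merge(bins, lr[, c("read_id", "origin_locus", "origin_start")],
             by = "read_id")
  assigned <- j[j$assigned_locus != "unassigned", ]
  expect_gt(nrow(assigned), 0.9 * nrow(j))
  expect_true(all(assigned$assigned_locus == assigned$origin_locus))
  # an error-free pseudo read spanning n PSVs scores -n * log((1-q)/q)
  w <- log(0.95 / 0.05)
  ps <- j[j$origin_locus == "pseudo" & j$n_psv_informative >= 10 &
            j$pseudo_flank == 0, ]
  expect_gt(nrow(ps), 0)
  expect_equal(ps$log_odds, -w * ps$n_psv_informative, tolerance = 1e-9)
})

test_that("binning misassignment is rare for reads spanning >= 5 PSVs", {
  # analytic oracle for the worst case (exactly 5 informative PSVs): with
  # vote weight w = log((1-q)/q) and assignment threshold 3 nats, a read is
  # MISassigned only when (5 - 2f) w <= -3, i.e. f >= 4 of 5 PSVs miscalled
  # (f = 3 gives |log-odds| = w < 3: the read drops to unassigned instead)
  q <- 0.05
  w <- log((1 - q) / q)
  f_needed <- min(which((5 - 2 * (0:5)) * w <= -3)) - 1
  expect_gte(f_needed, 3)
  p_mis <- sum(dbinom(f_needed:5, 5, q))
  expect_lt(p_mis, 1e-3)
  # empirical: noisy long reads at the binning error rate
  ref <- toy_ref()
  hmap <- toy_map()
  masked <- toy_masked()
  haps <- simulate_sample(ref, sample_truth("S0"))
  mis <- 0L; tot <- 0L
  for (s in 1:4) {
    lr <- simulate_long_reads(haps, coverage = 20, len_mean = 1200,
                              len_sd = 300, sub_error = 0.05,
                              indel_error = 0.01, seed = 60 + s)
    aln <- map_reads(lr, masked, k = 15, band = 60, step = 5L)
    bins <- bin_reads(aln, hmap, q = 0.05)
    j <- merge(bins, lr[, c("read_id", "origin_locus")], by = "read_id")
    j <- j[j$n_psv_informative >= 5 & j$assigned_locus %in%
             c("gene", "pseudo"), ]
    tot <- tot + nrow(j)
    mis <- mis + sum(j$assigned_locus != j$origin_locus)
  }
  expect_gt(tot, 200)
  expect_lte(mis / tot, 1e-3)
})

test_that("relabelling gene and pseudogene flips every PSV-based assignment", {
  ref <- toy_ref()
  hmap <- toy_map()
  masked <- toy_masked()
  haps <- simulate_sample(ref, sample_truth("S0"))
  lr <- simulate_long_reads(haps, coverage = 10, len_mean = 1500,
                            len_sd = 300, sub_error = 0.02,
                            indel_error = 0.005, seed = 53)
  aln <- map_reads(lr, masked, k = 15, band = 60)
  bins <- bin_reads(aln, hmap, q = 0.05)
  swapped <- hmap
  swapped$psvs <- transform(hmap$psvs, gene_base = pseudo_base,
                            pseudo_base = gene_base)
  bins_sw <- bin_reads(aln, swapped, q = 0.05)
  m <- match(bins$read_id, bins_sw$read_id)
  psv_only <- bins$unique_overlap < 30 & bins$pseudo_flank < 30
  expect_equal(bins_sw$log_odds[m][psv_only], -bins$log_odds[psv_only])
  flip <- c(gene = "pseudo", pseudo = "gene", unassigned = "unassigned")
  expect_identical(bins_sw$assigned_locus[m][psv_only],
                   unname(flip[bins$assigned_locus[psv_only]]))
})

test_that("per-locus re-genotyping calls the diploid MAP on binned reads", {
  # direct binomial behaviour on constructed single-base alignments
  mk_aln <- function(n_alt, n_ref, pos, ref_b, alt_b) {
    data.table::data.table(
      read_id = paste0("r", seq_len(n_alt + n_ref)),
      contig = "chrT", pos = pos, mapq = 60L, cigar = "1M", strand = "+",
      seq = c(rep(alt_b, n_alt), rep(ref_b, n_ref)),
      is_supplementary = FALSE)
  }
  bins <- data.frame(read_id = paste0("r", 1:30), assigned_locus = "gene")
  a <- mk_aln(28, 2, 100L, "C", "T")
  expect_equal(regenotype_per_locus(bins, a, 100L, "T", e = 0.05)$genotype,
               "alt/alt")
  a <- mk_aln(0, 30, 100L, "C", "T")
  expect_equal(regenotype_per_locus(bins, a, 100L, "T", e = 0.05)$genotype,
               "ref/ref")
  a <- mk_aln(16, 14, 100L, "C", "T")
  expect_equal(regenotype_per_locus(bins, a, 100L, "T", e = 0.05)$genotype,
               "ref/alt")
  # insufficient binned depth: no-call
  bins5 <- data.frame(read_id = paste0("r", 1:5), assigned_locus = "gene")
  a <- mk_aln(5, 0, 100L, "C", "T")
  expect_equal(regenotype_per_locus(bins5, a, 100L, "T",
                                    min_reads = 10L)$genotype, "no_call")
})

test_that("deletion detection recovers a het 1678-bp event with gene locus", {
  ref <- lr_ref()
  hmap <- lr_map()
  masked <- lr_masked()
  d_start <- ref$exons$start[4] - 739L
  del <- data.frame(locus = "gene", haplotype = 1L,
                    start = d_start, end = d_start + 1677L)
  haps <- simulate_sample(ref, sample_truth("S", exon_deletions = del))

  # null first: no deletion calls
  haps0 <- simulate_sample(ref, sample_truth("S0"))
  lr0 <- simulate_long_reads(haps0, coverage = 30, len_mean = 3000,
                             len_sd = 800, sub_error = 0.02,
                             indel_error = 0.01, seed = 55)
  aln0 <- map_reads(lr0, masked, k = 15, band = 60)
  expect_equal(nrow(detect_deletions(aln0, min_sv_len = 200)), 0)

  lr <- simulate_long_reads(haps, coverage = 30, len_mean = 3000,
                            len_sd = 800, sub_error = 0.02,
                            indel_error = 0.01, seed = 56)
  aln <- map_reads(lr, masked, k = 15, band = 60)
  bins <- bin_reads(aln, hmap, q = 0.05)
  dels <- detect_deletions(aln, bins, min_sv_len = 200, min_support = 3,
                           cluster_tol = 20)
  expect_equal(nrow(dels), 1)
  expect_lt(abs(dels$length - 1678), 20)
  expect_lt(abs(dels$start - d_start), 20)
  expect_equal(dels$locus, "gene")
  # roughly half the spanning reads support the het event
  expect_gte(dels$support, 3)
})

test_that("split supplementary alignments merge into a deletion signal", {
  a <- data.table::data.table(
    read_id = c("r1", "r1"), contig = "chrT", pos = c(1000L, 3000L),
    mapq = 60L, cigar = c("500M", "400M"), strand = "+",
    seq = c(strrep("A", 500), strrep("A", 400)),
    is_supplementary = c(FALSE, TRUE))
  dels <- detect_deletions(a, min_sv_len = 200, min_support = 1)
  expect_equal(nrow(dels), 1)
  expect_equal(dels$start, 1500L)
  expect_equal(dels$length, 1500L)
})

test_that("read-backed phasing separates cis from trans pairs", {
  ref <- lr_ref()
  hmap <- lr_map()
  masked <- lr_masked()
  p1 <- ref$exons$start[3] + 50L
  p2 <- ref$exons$start[4] + 120L
  r1 <- substr(ref$gene_seq, p1, p1); a1 <- other_base(ref$gene_seq, p1)
  r2 <- substr(ref$gene_seq, p2, p2); a2 <- other_base(ref$gene_seq, p2)
  hs <- data.frame(pos = c(p1, p2), ref = c(r1, r2), alt = c(a1, a2))
  run_phase <- function(hap_of_v2, seed) {
    sv <- data.frame(locus = "gene", haplotype = c(1L, hap_of_v2),
                     pos = c(p1, p2), ref = c(r1, r2), alt = c(a1, a2),
                     kind = "snv")
    haps <- simulate_sample(ref, sample_truth("S", small_variants = sv))
    lr <- simulate_long_reads(haps, coverage = 30, len_mean = 3000,
                              len_sd = 500, sub_error = 0.02,
                              indel_error = 0.01, seed = seed)
    aln <- map_reads(lr, masked, k = 15, band = 60, step = 5L)
    bins <- bin_reads(aln, hmap, q = 0.05)
    gene_reads <- bins$read_id[bins$assigned_locus == "gene"]
    ph <- phase_variants(aln[aln$read_id %in% gene_reads, ], hs,
                         ref_seq = ref$gene_seq)
    pair_phase(ph, p1, p2)
  }
  expect_equal(run_phase(2L, 57), "trans")  # compound het
  expect_equal(run_phase(1L, 58), "cis")    # same haplotype: not biallelic
})

test_that("multi-site haplotypes phase correctly across replicates", {
  # at 5% read error a conservative block break (margin < 0.8 on ~16 shared
  # reads) occurs in a small fraction of runs even for perfect allele
  # calls, so full recovery is asserted for nearly all replicates
  ref <- lr_ref()
  hmap <- lr_map()
  masked <- lr_masked()
  pos <- c(ref$exons$start[3] + 10L, ref$exons$start[4] + 60L,
           ref$exons$start[5] + 110L)
  refs <- vapply(pos, function(p) substr(ref$gene_seq, p, p), character(1))
  alts <- vapply(pos, function(p) other_base(ref$gene_seq, p), character(1))
  hs <- data.frame(pos = pos, ref = refs, alt = alts)
  truth_hap <- c(1L, 2L, 1L)  # alt alleles: hap1, hap2, hap1
  sv <- data.frame(locus = "gene", haplotype = truth_hap, pos = pos,
                   ref = refs, alt = alts, kind = "snv")
  haps <- simulate_sample(ref, sample_truth("S", small_variants = sv))
  ok <- 0L; wrong <- 0L
  for (s in 1:10) {
    lr <- simulate_long_reads(haps, coverage = 30, len_mean = 3000,
                              len_sd = 500, sub_error = 0.05,
                              indel_error = 0.01, seed = 70 + s)
    aln <- map_reads(lr, masked, k = 15, band = 60, step = 5L)
    bins <- bin_reads(aln, hmap, q = 0.05)
    gene_reads <- bins$read_id[bins$assigned_locus == "gene"]
    ph <- phase_variants(aln[aln$read_id %in% gene_reads, ], hs,
                         ref_seq = ref$gene_seq)
    full <- length(unique(ph$block_id)) == 1
    if (full && pair_phase(ph, pos[1], pos[2]) == "trans" &&
        pair_phase(ph, pos[1], pos[3]) == "cis") ok <- ok + 1L
    # a linked pair must never be phased the wrong way round
    if (pair_phase(ph, pos[1], pos[2]) == "cis" ||
        pair_phase(ph, pos[1], pos[3]) == "trans") wrong <- wrong + 1L
  }
  expect_gte(ok, 9L)
  expect_equal(wrong, 0L)
})
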