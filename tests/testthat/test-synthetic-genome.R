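# The generator: locus pair construction and read simulation.

test_that("reference construction obeys the duplication geometry", {
  ref <- toy_ref()
  hi <- ref$homology_interval
  expect_equal(hi[1], ref$exons$start[2])
  expect_equal(hi[2], ref$exons$end[7])
  # pseudogene = gene homology slice + PSV substitutions + its own flanks
  ph <- ref$pseudo_hom_interval
  core <- substr(ref$pseudo_seq, ph[1], ph[2])
  rebuilt <- substr(ref$gene_seq, hi[1], hi[2])
  for (i in seq_len(nrow(ref$psv_catalog)))
    substr(rebuilt, ref$psv_catalog$pseudo_pos[i] - ph[1] + 1L,
           ref$psv_catalog$pseudo_pos[i] - ph[1] + 1L) <-
      ref$psv_catalog$pseudo_base[i]
  expect_identical(core, rebuilt)
  # realised identity is 1 - n_psv / block length
  expect_equal(ref$identity,
               1 - nrow(ref$psv_catalog) / (hi[2] - hi[1] + 1))
  # PSV bases really differ
  expect_true(all(ref$psv_catalog$gene_base != ref$psv_catalog$pseudo_base))
  # every duplicated exon carries at least one PSV
  for (e in 2:7) {
    inside <- ref$psv_catalog$gene_pos >= ref$exons$start[e] &
      ref$psv_catalog$gene_pos <= ref$exons$end[e]
    expect_gte(sum(inside), 1)
  }
})

test_that("PSV count tracks the identity parameter within binomial error", {
  ref <- make_paralog_reference(n_exons = 10, dup_first = 2, dup_last = 8,
                                exon_len = 200, intron_len = 300,
                                identity = 0.98, seed = 1)
  hom_len <- diff(ref$homology_interval) + 1
  n <- nrow(ref$psv_catalog)
  expected <- 0.02 * hom_len
  # forced >=1 PSV/exon can only add a handful; 3 binomial sd covers it
  expect_lt(abs(n - expected), 3 * sqrt(hom_len * 0.02 * 0.98) + 7)
})

test_that("degenerate identity with the PSV floor disabled is rejected", {
  expect_error(
    make_paralog_reference(n_exons = 4, dup_first = 2, dup_last = 3,
                           exon_len = 50, intron_len = 50,
                           identity = 0.9999, seed = 1,
                           min_psv_per_exon = 0),
    "zero PSVs")
})

test_that("an 86-exon mimic leaves the first 5 and final 2 exons unique", {
  ref <- make_paralog_reference(n_exons = 86, dup_first = 6, dup_last = 84,
                                exon_len = 30, intron_len = 40,
                                identity = 0.98, seed = 7, flank_len = 100)
  hi <- ref$homology_interval
  unique_exons <- which(ref$exons$end < hi[1] | ref$exons$start > hi[2])
  expect_identical(unique_exons, c(1:5, 85:86))
  expect_equal(length(unique_exons), 5 + 2)
})

test_that("simulate_sample applies events to the right haplotypes", {
  ref <- toy_ref()
  # empty truth: four reference copies
  h0 <- simulate_sample(ref, sample_truth("S0"))
  expect_identical(h0$gene_hap1, ref$gene_seq)
  expect_identical(h0$gene_hap2, ref$gene_seq)
  expect_identical(h0$pseudo_hap1, ref$pseudo_seq)

  # hom gene SNV: both gene haplotypes change, pseudogene untouched
  p <- ref$exons$start[4] + 10L
  sv <- rbind(snv_row(ref, p, 1L), snv_row(ref, p, 2L))
  h1 <- simulate_sample(ref, sample_truth("S1", small_variants = sv))
  expect_identical(substr(h1$gene_hap1, p, p), sv$alt[1])
  expect_identical(substr(h1$gene_hap2, p, p), sv$alt[1])
  expect_identical(h1$pseudo_hap1, ref$pseudo_seq)

  # het 1678-bp deletion: one haplotype shorter by exactly 1678
  del <- data.frame(locus = "gene", haplotype = 1L,
                    start = ref$exons$start[3], end = ref$exons$start[3] + 1677L)
  h2 <- simulate_sample(ref, sample_truth("S2", exon_deletions = del))
  expect_equal(nchar(h2$gene_hap1), nchar(ref$gene_seq) - 1678L)
  expect_equal(nchar(h2$gene_hap2), nchar(ref$gene_seq))
})

test_that("sample_truth rejects inconsistent event sets", {
  ref <- toy_ref()
  p <- ref$exons$start[3] + 5L
  sv <- snv_row(ref, p, 1L)
  expect_error(sample_truth("S", small_variants = rbind(sv, sv)),
               "duplicate")
  del <- data.frame(locus = "gene", haplotype = 1L, start = p - 2L,
                    end = p + 2L)
  expect_error(sample_truth("S", small_variants = sv, exon_deletions = del),
               "overlaps")
})

test_that("short reads reproduce the requested collapsed coverage", {
  ref <- toy_ref()
  haps <- simulate_sample(ref, sample_truth("S0"))
  rs <- simulate_short_reads(haps, coverage = 100, sub_error = 0, seed = 3)
  # error-free reads are exact substrings of their source haplotype
  idx <- sample(nrow(rs), 50)
  for (i in idx) {
    hap <- haps[[paste0(rs$origin_locus[i], "_hap", rs$origin_hap[i])]]
    sq <- if (rs$mate[i] == 2L) revcomp(rs$seq[i]) else rs$seq[i]
    expect_identical(substr(hap, rs$origin_start[i],
                            rs$origin_start[i] + nchar(sq) - 1L), sq)
  }
  # collapsed depth over homology-block interior ~ coverage (the interior
  # avoids fragment-sampling ramps at the block edges)
  depth <- integer(nchar(ref$gene_seq))
  hi <- ref$homology_interval
  gene_rs <- rs[rs$origin_locus == "gene", ]
  ps_rs <- rs[rs$origin_locus == "pseudo", ]
  add_cov <- function(starts, lens, offset = 0L) {
    for (j in seq_along(starts)) {
      s <- starts[j] + offset; e <- s + lens[j] - 1L
      s <- max(1L, s); e <- min(length(depth), e)
      if (s <= e) depth[s:e] <<- depth[s:e] + 1L
    }
  }
  add_cov(gene_rs$origin_start, nchar(gene_rs$seq))
  add_cov(ps_rs$origin_start, nchar(ps_rs$seq),
          offset = hi[1] - ref$pseudo_hom_interval[1])
  interior <- (hi[1] + 300):(hi[2] - 300)
  m <- mean(depth[interior])
  expect_lt(abs(m - 100), 3 * sqrt(100 / length(interior) * 300))
})

test_that("read simulation is byte-deterministic given the seed", {
  ref <- toy_ref()
  haps <- simulate_sample(ref, sample_truth("S0"))
  a <- simulate_short_reads(haps, coverage = 20, sub_error = 0.01, seed = 11)
  b <- simulate_short_reads(haps, coverage = 20, sub_error = 0.01, seed = 11)
  expect_identical(a$seq, b$seq)
  expect_identical(a$read_id, b$read_id)
  d1 <- file.path(tempdir(), "fq_det1"); d2 <- file.path(tempdir(), "fq_det2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  write_fastq(a, file.path(d1, "s"))
  write_fastq(b, file.path(d2, "s"))
  expect_identical(readLines(file.path(d1, "s_R1.fastq")),
                   readLines(file.path(d2, "s_R1.fastq")))
  c1 <- simulate_long_reads(haps, coverage = 10, seed = 11)
  c2 <- simulate_long_reads(haps, coverage = 10, seed = 11)
  expect_identical(c1$seq, c2$seq)
})

test_that("long reads are exact substrings at zero error and span many PSVs", {
  ref <- toy_ref()
  haps <- simulate_sample(ref, sample_truth("S0"))
  lr <- simulate_long_reads(haps, coverage = 10, len_mean = 2000,
                            len_sd = 400, sub_error = 0, indel_error = 0,
                            seed = 5)
  for (i in seq_len(min(nrow(lr), 30))) {
    hap <- haps[[paste0(lr$origin_locus[i], "_hap", lr$origin_hap[i])]]
    expect_identical(substr(hap, lr$origin_start[i],
                            lr$origin_start[i] + nchar(lr$seq[i]) - 1L),
                     lr$seq[i])
  }
  # PSV spacing is ~50 bp at 98% identity, so a 2 kb read inside the block
  # spans many PSVs
  pc <- toy_ref()$psv_catalog
  ps <- lr[lr$origin_locus == "pseudo", ]
  n_spanned <- vapply(seq_len(nrow(ps)), function(i) {
    s <- ps$origin_start[i]; e <- s + nchar(ps$seq[i]) - 1L
    sum(pc$pseudo_pos >= s & pc$pseudo_pos <= e)
  }, numeric(1))
  expect_gte(median(n_spanned), 5)
})

test_that("FASTQ round-trips through write_fastq/read_fastq", {
  ref <- toy_ref()
  haps <- simulate_sample(ref, sample_truth("S0"))
  rs <- simulate_short_reads(haps, coverage = 5, sub_error = 0, seed = 2)
  d <- file.path(tempdir(), "fq_rt"); dir.create(d, showWarnings = FALSE)
  paths <- write_fastq(rs, file.path(d, "s"))
  back <- read_fastq(paths)
  expect_setequal(back$read_id, rs$read_id)
  m <- match(rs$read_id, back$read_id)
  expect_identical(back$seq[m], rs$seq)
})
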