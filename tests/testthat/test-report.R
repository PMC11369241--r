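# Consequence annotation, diagnostic tiering and cohort accounting.

test_that("exon-deletion consequences follow mod-3 arithmetic", {
  ex <- data.frame(exon = 1:3, start = c(101L, 401L, 701L),
                   end = c(250L, 550L, 850L))  # 150-bp coding exons
  gene <- strrep("A", 1000)
  # deletion removing one whole 150-nt exon: in frame, 50 aa lost
  a <- annotate_consequence(list(kind = "sv_del", start = 390L, end = 560L),
                            ex, gene)
  expect_equal(a$kind, "in_frame_indel")
  expect_false(a$frameshift)
  expect_equal(a$details$deleted_aa, 50L)
  expect_equal(a$details$net_nt, -150L)
  # deletion clipping 100 exonic nt: frameshift
  b <- annotate_consequence(list(kind = "sv_del", start = 401L, end = 500L),
                            ex, gene)
  expect_equal(b$kind, "frameshift")
  expect_true(b$frameshift)
  # purely intronic deletion
  d <- annotate_consequence(list(kind = "sv_del", start = 260L, end = 380L),
                            ex, gene)
  expect_equal(d$kind, "intronic")
  # outside the transcript entirely
  e <- annotate_consequence(list(kind = "sv_del", start = 900L, end = 950L),
                            ex, gene)
  expect_equal(e$kind, "non_coding")
})

test_that("frameshift flag equals nt mod 3 over many simulated deletions", {
  ex <- data.frame(exon = 1:4, start = c(101L, 401L, 701L, 1001L),
                   end = c(250L, 550L, 850L, 1150L))
  gene <- strrep("A", 1300)
  set.seed(77)
  for (i in 1:50) {
    s <- sample(80:1100, 1); e <- s + sample(10:400, 1)
    a <- annotate_consequence(list(kind = "sv_del", start = s, end = e),
                              ex, gene)
    nt <- sum(pmax(0, pmin(e, ex$end) - pmax(s, ex$start) + 1))
    if (nt == 0) {
      expect_true(a$kind %in% c("intronic", "non_coding"))
    } else {
      expect_equal(a$frameshift, (nt %% 3) != 0)
      if (nt %% 3 == 0) expect_equal(a$details$deleted_aa * 3L, nt)
    }
  }
})

test_that("SNV consequences use codon lookup on the toy transcript", {
  # CDS: ATG AAA TAC TGG ... place exon so codons are known
  cds <- "ATGAAATACTGGGGC"
  gene <- paste0(strrep("T", 50), cds, strrep("T", 50))
  ex <- data.frame(exon = 1L, start = 51L, end = 50L + nchar(cds))
  # AAA -> TAA: stop gain at codon 2, position 4 of CDS
  a <- annotate_consequence(list(kind = "snv", pos = 54L, ref = "A",
                                 alt = "T"), ex, gene)
  expect_equal(a$kind, "stop_gain")
  # TAC -> TAT: synonymous (Tyr)
  b <- annotate_consequence(list(kind = "snv", pos = 59L, ref = "C",
                                 alt = "T"), ex, gene)
  expect_equal(b$kind, "synonymous")
  # TGG -> TGC: missense (Trp -> Cys)
  d <- annotate_consequence(list(kind = "snv", pos = 62L, ref = "G",
                                 alt = "C"), ex, gene)
  expect_equal(d$kind, "missense")
  # intronic positions 1-2 bp from the exon boundary are splice sites
  e <- annotate_consequence(list(kind = "snv", pos = 50L, ref = "T",
                                 alt = "A"), ex, gene)
  expect_equal(e$kind, "splice_site")
})

test_that("small indels classify by net coding change", {
  ex <- data.frame(exon = 1L, start = 101L, end = 400L)
  gene <- strrep("ACGT", 150)
  # 2-bp deletion in the exon: frameshift
  v <- list(kind = "del", pos = 150L,
            ref = substr(gene, 150, 152), alt = substr(gene, 150, 150))
  expect_equal(annotate_consequence(v, ex, gene)$kind, "frameshift")
  # 3-bp insertion: in-frame
  v <- list(kind = "ins", pos = 150L, ref = substr(gene, 150, 150),
            alt = paste0(substr(gene, 150, 150), "AAA"))
  a <- annotate_consequence(v, ex, gene)
  expect_equal(a$kind, "in_frame_indel")
  expect_equal(a$details$net_nt, 3L)
})

test_that("acceptor gain retention follows the offset arithmetic", {
  # offset -39: 38 retained nucleotides, frameshift
  a <- acceptor_gain_inclusion(-39)
  expect_equal(a$details$retained_nt, 38L)
  expect_true(a$frameshift)
  # offset -4: 3 retained nucleotides, one extra codon, in frame
  b <- acceptor_gain_inclusion(-4)
  expect_equal(b$details$retained_nt, 3L)
  expect_false(b$frameshift)
  # offsets -1/-2 would hit the canonical acceptor
  expect_error(acceptor_gain_inclusion(-1), "canonical acceptor")
  expect_error(acceptor_gain_inclusion(-2), "canonical acceptor")
  # optional sequence check: intron ending ...AG at the right offset
  intron <- paste0(strrep("T", 60), "AG", strrep("T", 38))
  expect_equal(acceptor_gain_inclusion(-39, intron)$details$retained_nt, 38L)
  bad <- strrep("T", 100)
  expect_error(acceptor_gain_inclusion(-39, bad), "no AG")
})

mk_sr_call <- function(pos, theta, region = "homology", locus = "gene") {
  data.frame(pos = pos, ref = "A", alt = "T", kind = "snv",
             alt_count = round(100 * theta), depth = 100L,
             region_type = region, map_label = "x", theta_map = theta,
             posterior = 0.99, ambiguous = FALSE, locus = locus,
             locus_posterior = 0.99, log_odds = 10)
}

test_that("diagnostic tiers combine SR and LR evidence", {
  # two trans het variants from SR alone
  s <- assemble_status(rbind(mk_sr_call(100, 0.25), mk_sr_call(900, 0.25)),
                       lr_results = list(phase = "trans"))
  expect_equal(s$tier, "solved_SR")
  expect_equal(s$gene_alleles_found, 2L)
  # one SR het + one LR gene deletion: the family-11/13 pattern
  s <- assemble_status(mk_sr_call(100, 0.25),
                       lr_results = list(deletions = data.frame(
                         start = 500, end = 2177, length = 1678,
                         support = 14, locus = "gene")))
  expect_equal(s$tier, "solved_LR")
  # a single homozygous call (theta 0.5 in homology) solves by SR
  s <- assemble_status(mk_sr_call(100, 0.5))
  expect_equal(s$tier, "solved_SR")
  expect_equal(s$phase_evidence, "homozygous")
  # one het only: partial
  s <- assemble_status(mk_sr_call(100, 0.25))
  expect_equal(s$tier, "partial")
  # pseudogene-assigned variants never count
  s <- assemble_status(rbind(mk_sr_call(100, 0.25),
                             mk_sr_call(900, 0.25, locus = "pseudo")))
  expect_equal(s$tier, "partial")
  # a cis-only pair is not biallelic: downgraded with a warning
  s <- assemble_status(rbind(mk_sr_call(100, 0.25), mk_sr_call(900, 0.25)),
                       lr_results = list(phase = "cis"))
  expect_equal(s$tier, "partial")
  expect_match(s$warning, "cis")
})

test_that("adding a trans second allele never downgrades the tier", {
  tiers <- c(unsolved = 0, partial = 1, solved_LR = 2, solved_SR = 2)
  one <- assemble_status(mk_sr_call(100, 0.25))
  two <- assemble_status(rbind(mk_sr_call(100, 0.25), mk_sr_call(900, 0.25)),
                         lr_results = list(phase = "trans"))
  expect_gte(tiers[[two$tier]], tiers[[one$tier]])
})

test_that("the packaged 17-family cohort reproduces the published accounting", {
  fix <- load_family_fixture()
  expect_equal(length(unique(fix$family)), 17)
  st <- families_to_statuses(fix)
  expect_equal(nrow(st), 17)
  cs <- cohort_summary(st, n_referred = 437, n_genetically_confirmed = 242)
  expect_equal(unname(cs$counts[["solved_SR"]]), 15)
  expect_equal(unname(cs$counts[["solved_LR"]]), 2)
  expect_equal(cs$n_solved, 17)
  expect_equal(cs$n_homozygous, 6)
  expect_equal(cs$n_compound_het, 11)
  expect_equal(cs$gene_positive_percent, 7L)
  # tier counts sum to the number of families
  expect_equal(sum(cs$counts), nrow(st))
})

test_that("cohort_summary rejects degenerate inputs", {
  st <- families_to_statuses()
  expect_error(cohort_summary(st[0, ], 437, 242), "empty cohort")
  expect_error(cohort_summary(st, 437, 0), "positive")
  expect_error(cohort_summary(st, 10, 242), "inconsistent")
})
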