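# Consequence annotation on the toy transcript, per-sample diagnostic
# tiering, and cohort accounting. The transcript model is the simulator's
# exon table read as a single CDS in frame from the first exon base.

codon_to_aa <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

coding_pos <- function(pos, exon_table) {
  # 1-based CDS coordinate of a genomic position, NA if intronic
  before <- exon_table$end < pos
  in_ex <- which(exon_table$start <= pos & exon_table$end >= pos)
  if (length(in_ex) == 0) return(NA_integer_)
  sum(exon_table$end[before] - exon_table$start[before] + 1L) +
    (pos - exon_table$start[in_ex] + 1L)
}

coding_overlap <- function(start, end, exon_table) {
  # number of coding (exonic) bases in [start, end]
  s <- pmax(start, exon_table$start); e <- pmin(end, exon_table$end)
  sum(pmax(0L, e - s + 1L))
}

#' Annotate the molecular consequence of a variant on the toy transcript
#'
#' SNVs in coding sequence get codon lookup (stop_gain / missense /
#' synonymous); positions within 2 bp of an exon boundary on the intron side
#' are splice_site; indels and exon-scale deletions are classified by the
#' net coding-length change: frameshift iff `net mod 3 != 0`, otherwise
#' in_frame_indel with `deleted_aa = deleted coding nt / 3`. Variants
#' touching no exon are intronic; variants outside the transcript span are
#' non_coding.
#'
#' @param variant list with `kind` ("snv", "ins", "del", "sv_del"); for
#'   point events `pos`, `ref`, `alt` (VCF-anchored for ins/del); for
#'   `sv_del` `start`, `end` (1-based inclusive deleted interval).
#' @param exon_table data.frame `exon`, `start`, `end`.
#' @param gene_seq gene sequence (codon lookup for SNVs).
#' @return list (`consequence_annotation`): `kind`, `details` (named list
#'   with e.g. `net_nt`, `deleted_aa`, `aa_change`), `frameshift` flag.
#' @export
annotate_consequence <- function(variant, exon_table, gene_seq) {
  ex <- as.data.frame(exon_table)
  tx_start <- min(ex$start); tx_end <- max(ex$end)

  if (variant$kind == "sv_del") {
    s <- variant$start; e <- variant$end
    if (e < tx_start || s > tx_end)
      return(list(kind = "non_coding", details = list(), frameshift = FALSE))
    nt <- coding_overlap(s, e, ex)
    if (nt == 0)
      return(list(kind = "intronic", details = list(net_nt = 0L),
                  frameshift = FALSE))
    fs <- (nt %% 3L) != 0L
    return(list(kind = if (fs) "frameshift" else "in_frame_indel",
                details = list(net_nt = -nt,
                               deleted_aa = if (!fs) nt %/% 3L else NA_integer_),
                frameshift = fs))
  }

  pos <- variant$pos
  if (pos < tx_start - 2L || pos > tx_end + 2L)
    return(list(kind = "non_coding", details = list(), frameshift = FALSE))
  # splice sites: +-1/2 intronic bases flanking any exon
  near_donor <- any(pos > ex$end & pos <= ex$end + 2L)
  near_acceptor <- any(pos < ex$start & pos >= ex$start - 2L)

  if (variant$kind == "snv") {
    cp <- coding_pos(pos, ex)
    if (is.na(cp)) {
      if (near_donor || near_acceptor)
        return(list(kind = "splice_site", details = list(), frameshift = FALSE))
      return(list(kind = "intronic", details = list(), frameshift = FALSE))
    }
    cds <- paste(vapply(seq_len(nrow(ex)), function(i)
      substr(gene_seq, ex$start[i], ex$end[i]), character(1)), collapse = "")
    codon_i <- (cp - 1L) %/% 3L
    off <- (cp - 1L) %% 3L
    codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    if (nchar(codon) < 3)
      return(list(kind = "non_coding", details = list(), frameshift = FALSE))
    new_codon <- codon
    substr(new_codon, off + 1L, off + 1L) <- variant$alt
    aa_old <- codon_to_aa(codon); aa_new <- codon_to_aa(new_codon)
    kind <- if (aa_new == "*" && aa_old != "*") "stop_gain"
    else if (aa_new == aa_old) "synonymous" else "missense"
    return(list(kind = kind,
                details = list(aa_change = paste0(aa_old, ceiling(cp / 3), aa_new)),
                frameshift = FALSE))
  }

  # anchored small indels: changed bases start after the anchor
  if (variant$kind == "del") {
    len <- nchar(variant$ref) - nchar(variant$alt)
    s <- pos + nchar(variant$alt); e <- pos + nchar(variant$ref) - 1L
    nt <- coding_overlap(s, e, ex)
  } else {  # ins
    len <- nchar(variant$alt) - nchar(variant$ref)
    nt <- if (!is.na(coding_pos(pos, ex))) len else 0L
  }
  if (nt == 0) {
    if (near_donor || near_acceptor)
      return(list(kind = "splice_site", details = list(), frameshift = FALSE))
    return(list(kind = "intronic", details = list(net_nt = 0L),
                frameshift = FALSE))
  }
  net <- if (variant$kind == "del") -nt else nt
  fs <- (abs(net) %% 3L) != 0L
  list(kind = if (fs) "frameshift" else "in_frame_indel",
       details = list(net_nt = net,
                      deleted_aa = if (!fs && net < 0) (-net) %/% 3L else NA_integer_),
       frameshift = fs)
}

#' Transcript consequence of a novel intronic splice-acceptor gain
#'
#' An intronic A>G creating a new AG acceptor whose G sits `intronic_offset`
#' bases upstream of the exon start (offset -1 = last intronic base) causes
#' the spliceosome to retain the intronic bases between the new acceptor and
#' the exon: `retained_nt = |offset| - 1`. The inclusion frameshifts the
#' transcript iff `retained_nt mod 3 != 0`. Offsets of -1 or -2 would
#' disrupt the canonical acceptor rather than create a new one and are
#' rejected.
#'
#' @param intronic_offset negative integer offset of the novel G relative to
#'   the downstream exon start.
#' @param intron_seq optional intron sequence (post-variant, 3' end adjacent
#'   to the exon) used to verify the AG dinucleotide at the offset.
#' @return list (`consequence_annotation`): `kind = "acceptor_gain"`,
#'   `details$retained_nt`, `frameshift`.
#' @export
acceptor_gain_inclusion <- function(intronic_offset, intron_seq = NULL) {
  stopifnot(length(intronic_offset) == 1, intronic_offset == round(intronic_offset))
  if (intronic_offset >= -2)
    stop("offset >= -2 would disrupt, not create, the canonical acceptor")
  if (!is.null(intron_seq)) {
    L <- nchar(intron_seq)
    g_at <- L + intronic_offset + 1L
    if (g_at < 2 || substr(intron_seq, g_at - 1L, g_at) != "AG")
      stop("no AG dinucleotide at the stated offset in intron_seq")
  }
  retained <- as.integer(-intronic_offset - 1L)
  list(kind = "acceptor_gain",
       details = list(retained_nt = retained),
       frameshift = (retained %% 3L) != 0L)
}

#' Combine short-read, CNV and long-read evidence into a diagnostic tier
#'
#' Counting rules: a pseudogene-assigned variant never contributes; a
#' homology-region call at theta 0.5 counts as a homozygous gene variant
#' (two alleles); theta 0.25 (or a unique-region het) counts one. CNV or
#' long-read deletion events attributed to the gene add one allele each.
#' `solved_SR` requires two alleles from the short-read stage alone;
#' `solved_LR` when the long-read stage supplied the missing allele (or the
#' locus/zygosity resolution); one allele gives `partial`; cis-only phase
#' evidence for the claimed biallelic pair downgrades to `partial` with a
#' warning.
#'
#' @param sr_calls site-call table from [scan_candidates()] (may be empty).
#' @param cnv_calls optional `events` table from [call_combined_cn()] with
#'   an `attribution` column.
#' @param lr_results optional list with elements `deletions`
#'   ([detect_deletions()] output), `regenotype` (per-site
#'   [regenotype_per_locus()] results), `phase` ("trans"/"cis"/NULL).
#' @param sample_id sample label.
#' @return one-row data.frame: `sample_id`, `gene_alleles_found` (capped at
#'   2), `tier`, `phase_evidence`, `warning`.
#' @export
assemble_status <- function(sr_calls, cnv_calls = NULL, lr_results = NULL,
                            sample_id = "S1") {
  sr <- as.data.frame(sr_calls)
  sr_alleles <- 0L
  hom_seen <- FALSE
  if (nrow(sr)) {
    sr <- sr[sr$locus != "pseudo", , drop = FALSE]
    for (i in seq_len(nrow(sr))) {
      hom <- (sr$region_type[i] == "homology" && sr$theta_map[i] == 0.5) ||
        (sr$region_type[i] == "unique" && sr$theta_map[i] == 1.0)
      sr_alleles <- sr_alleles + if (hom) 2L else 1L
      hom_seen <- hom_seen || hom
    }
  }
  cnv_alleles <- 0L
  if (!is.null(cnv_calls) && nrow(as.data.frame(cnv_calls))) {
    cc <- as.data.frame(cnv_calls)
    baseline <- if ("region_type" %in% names(cc))
      ifelse(cc$region_type == "homology", 4L, 2L) else 4L
    ok <- cc$cn < baseline
    if ("attribution" %in% names(cc)) ok <- ok & cc$attribution == "gene"
    cnv_alleles <- sum(ok)
  }
  lr_alleles <- 0L
  if (!is.null(lr_results)) {
    if (!is.null(lr_results$deletions) && nrow(lr_results$deletions))
      lr_alleles <- lr_alleles +
        sum(lr_results$deletions$locus %in% c("gene", NA_character_))
  }
  phase <- if (!is.null(lr_results) && !is.null(lr_results$phase))
    lr_results$phase
  else if (hom_seen) "homozygous" else "unphased"

  total <- min(sr_alleles + cnv_alleles + lr_alleles, 2L)
  warn <- ""
  if (identical(phase, "cis") && sr_alleles >= 2L && !hom_seen) {
    total <- 1L
    warn <- "claimed biallelic pair is in cis; second allele not established"
  }
  tier <- if (total >= 2L && sr_alleles >= 2L) "solved_SR"
  else if (total >= 2L) "solved_LR"
  else if (total == 1L) "partial" else "unsolved"
  data.frame(sample_id = sample_id, gene_alleles_found = total, tier = tier,
             phase_evidence = phase, warning = warn,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the packaged 17-family variant fixture
#'
#' A transcription of the variant table of a published 17-family cohort with
#' biallelic variants in a pseudogene-shadowed PCD gene: per family, the one
#' or two causal alleles with cDNA change, zygosity, and the sequencing
#' stage that detected each allele. The table lists 25 distinct cDNA changes
#' (the source text says 24; the rows are preserved as printed).
#'
#' @return data.frame with columns `family`, `allele`, `cdna`, `protein`,
#'   `acmg`, `zygosity`, `detected_by`, `region`.
#' @export
load_family_fixture <- function() {
  path <- system.file("extdata", "families17.tsv", package = "paramask")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Diagnostic statuses for the fixture families
#'
#' Applies the tiering rules to the fixture: a homozygous variant counts two
#' alleles with homozygous phase evidence; a compound-heterozygous pair
#' counts both (in trans); a family is `solved_LR` iff any of its alleles
#' required the long-read stage.
#'
#' @param fixture output of [load_family_fixture()].
#' @return data.frame of per-family statuses (as [assemble_status()] rows).
#' @export
families_to_statuses <- function(fixture = load_family_fixture()) {
  out <- lapply(split(fixture, fixture$family), function(f) {
    hom <- any(f$zygosity == "hom")
    n_alleles <- if (hom) 2L else min(nrow(f), 2L)
    lr <- any(f$detected_by == "LR")
    tier <- if (n_alleles >= 2L) { if (lr) "solved_LR" else "solved_SR" }
    else if (n_alleles == 1L) "partial" else "unsolved"
    data.frame(sample_id = f$family[1], gene_alleles_found = n_alleles,
               tier = tier,
               phase_evidence = if (hom) "homozygous" else "trans",
               warning = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(suppressWarnings(as.integer(sub("^F", "", out$sample_id)))), ]
}

#' Cohort-level diagnostic accounting
#'
#' @param statuses data.frame of per-sample statuses.
#' @param n_referred families referred for testing.
#' @param n_genetically_confirmed families with a confirmed genetic
#'   diagnosis (denominator of the gene-positive fraction).
#' @return list: `counts` (per tier), `n_solved`, `n_homozygous`,
#'   `n_compound_het`, `gene_positive_percent` (rounded to nearest integer).
#' @export
cohort_summary <- function(statuses, n_referred, n_genetically_confirmed) {
  st <- as.data.frame(statuses)
  if (nrow(st) == 0) stop("empty cohort")
  if (n_genetically_confirmed <= 0 || n_referred <= 0)
    stop("cohort denominators must be positive")
  n_solved <- sum(st$tier %in% c("solved_SR", "solved_LR"))
  if (!(n_solved <= n_genetically_confirmed &&
        n_genetically_confirmed <= n_referred))
    stop("inconsistent counts: solved <= confirmed <= referred required")
  counts <- table(factor(st$tier, levels = c("solved_SR", "solved_LR",
                                             "partial", "unsolved")))
  solved <- st[st$tier %in% c("solved_SR", "solved_LR"), , drop = FALSE]
  list(counts = counts,
       n_solved = n_solved,
       n_homozygous = sum(solved$phase_evidence == "homozygous"),
       n_compound_het = sum(solved$phase_evidence %in% c("trans")),
       gene_positive_percent =
         as.integer(round(100 * n_solved / n_genetically_confirmed)))
}
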