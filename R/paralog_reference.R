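#' Build a toy gene/pseudogene reference pair
#'
#' Generates a random gene locus with `n_exons` exons, then copies the block
#' spanning exons `dup_first`..`dup_last` (including the intervening introns)
#' into a pseudogene locus, substituting paralogous sequence variants (PSVs)
#' at density `1 - identity`. This reproduces, at desk scale, the geometry of
#' a gene whose internal exon block is duplicated into a near-identical
#' pseudogene, with only the flanking exons remaining unique to the gene.
#'
#' Layout on the gene locus: intron, exon, intron, exon, ..., exon, intron
#' (`n_exons` exons, `n_exons + 1` introns). The homology interval runs from
#' the first base of exon `dup_first` to the last base of exon `dup_last`.
#'
#' @param n_exons number of exons on the gene locus.
#' @param dup_first,dup_last 1-based indices of the first and last duplicated
#'   exon.
#' @param exon_len,intron_len lengths (bp) of every exon / intron.
#' @param identity target sequence identity of the duplication, in
#'   `[0.5, 1)`. The number of PSVs is `round((1 - identity) * block length)`.
#' @param seed integer seed; the construction is deterministic given it.
#' @param min_psv_per_exon every duplicated exon is forced to carry at least
#'   this many PSVs (default 1) so each exon is locus-resolvable; set to 0 to
#'   disable the floor.
#' @param flank_len unique flanking sequence (bp) added on both sides of each
#'   locus, emulating the surrounding genomic context: the gene body sits
#'   inside gene flanks, and the duplicated block inside its own (unrelated)
#'   pseudogene flanks. Flanks keep fragment sampling uniform across the
#'   loci and, like the real flanking chromosome sequence, are not masked.
#' @return an object of class `paralog_ref` with elements `gene_seq`,
#'   `pseudo_seq`, `exons` (data.frame `exon`, `start`, `end`, 1-based
#'   inclusive), `dup_range`, `homology_interval` (c(start, end) on the gene),
#'   `pseudo_hom_interval` (c(start, end) of the homologous block on the
#'   pseudogene locus), `psv_catalog` (data.frame `gene_pos`, `pseudo_pos`,
#'   `gene_base`, `pseudo_base`), and `identity` (realised identity of the
#'   block).
#' @export
make_paralog_reference <- function(n_exons, dup_first, dup_last,
                                   exon_len = 200L, intron_len = 300L,
                                   identity = 0.98, seed = 1L,
                                   min_psv_per_exon = 1L, flank_len = 800L) {
  stopifnot(n_exons >= 1, dup_first >= 1, dup_last >= dup_first,
            dup_last <= n_exons, exon_len >= 10, intron_len >= 0,
            identity >= 0.5, identity < 1, flank_len >= 0)
  set.seed(seed)

  exon_starts <- flank_len + intron_len +
    (seq_len(n_exons) - 1L) * (exon_len + intron_len) + 1L
  exons <- data.frame(exon = seq_len(n_exons),
                      start = as.integer(exon_starts),
                      end = as.integer(exon_starts + exon_len - 1L))
  gene_len <- n_exons * exon_len + (n_exons + 1L) * intron_len +
    2L * flank_len
  gene_seq <- random_dna(gene_len)

  hom_start <- exons$start[dup_first]
  hom_end <- exons$end[dup_last]
  hom_len <- hom_end - hom_start + 1L

  n_psv <- round((1 - identity) * hom_len)
  if (n_psv < 1 && min_psv_per_exon < 1)
    stop("identity so high that the homology block carries zero PSVs; ",
         "lower `identity` or keep `min_psv_per_exon` >= 1")
  # keep PSVs off the outermost bases of the block so the block boundary is
  # anchored by exact sequence on both sides (mirrors real duplications,
  # whose breakpoints are defined by contiguous identical sequence)
  edge_pad <- min(12L, (hom_len - 1L) %/% 3L)
  pickable <- (edge_pad + 1L):(hom_len - edge_pad)
  psv_pos <- sort(sample(pickable, min(n_psv, length(pickable))))

  if (min_psv_per_exon > 0) {
    for (e in dup_first:dup_last) {
      lo <- max(exons$start[e] - hom_start + 1L, edge_pad + 1L)
      hi <- min(exons$end[e] - hom_start + 1L, hom_len - edge_pad)
      n_have <- sum(psv_pos >= lo & psv_pos <= hi)
      if (n_have < min_psv_per_exon) {
        free <- setdiff(lo:hi, psv_pos)
        add <- sample(free, min_psv_per_exon - n_have)
        psv_pos <- sort(c(psv_pos, add))
      }
    }
  }
  if (length(psv_pos) == 0)
    stop("identity so high that the homology block carries zero PSVs")

  gene_bases <- chars_at(gene_seq, psv_pos + hom_start - 1L)
  pseudo_bases <- vapply(gene_bases, function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)

  pseudo_chars <- str_chars(substr(gene_seq, hom_start, hom_end))
  pseudo_chars[psv_pos] <- pseudo_bases
  pseudo_seq <- paste0(random_dna(flank_len),
                       paste(pseudo_chars, collapse = ""),
                       random_dna(flank_len))

  structure(list(
    gene_seq = gene_seq,
    pseudo_seq = pseudo_seq,
    exons = exons,
    dup_range = c(dup_first, dup_last),
    homology_interval = c(hom_start, hom_end),
    pseudo_hom_interval = c(flank_len + 1L, flank_len + hom_len),
    flank_len = flank_len,
    psv_catalog = data.frame(
      gene_pos = as.integer(psv_pos + hom_start - 1L),
      pseudo_pos = as.integer(psv_pos + flank_len),
      gene_base = gene_bases,
      pseudo_base = pseudo_bases,
      stringsAsFactors = FALSE),
    identity = 1 - length(psv_pos) / hom_len
  ), class = "paralog_ref")
}

#' @export
print.paralog_ref <- function(x, ...) {
  cat(sprintf(
    "paralog_ref: gene %d bp (%d exons), pseudogene %d bp (exons %d-%d duplicated)\n",
    nchar(x$gene_seq), nrow(x$exons), nchar(x$pseudo_seq),
    x$dup_range[1], x$dup_range[2]))
  cat(sprintf("  homology block gene:%d-%d, %d PSVs, identity %.4f\n",
              x$homology_interval[1], x$homology_interval[2],
              nrow(x$psv_catalog), x$identity))
  invisible(x)
}

#' Specify a diploid sample's true genotype
#'
#' A `sample_truth` couples small variants and exon-scale deletions to a
#' haplotype of a locus. Positions are 1-based on the unaltered locus
#' sequence (gene or pseudogene coordinates, matching `locus`).
#'
#' @param sample_id sample label.
#' @param small_variants data.frame with columns `locus` ("gene"/"pseudo"),
#'   `haplotype` (1/2, or both rows for a homozygous variant), `pos`,
#'   `ref` (reference allele string), `alt` (alternate allele string),
#'   `kind` ("snv", "ins", "del"). For "ins", `ref` is the anchor base and
#'   `alt` the anchor plus inserted bases; for "del", `ref` is the anchor
#'   plus deleted bases and `alt` the anchor (VCF style).
#' @param exon_deletions data.frame with columns `locus`, `haplotype`,
#'   `start`, `end` (1-based inclusive interval removed from that haplotype).
#' @return object of class `sample_truth`.
#' @export
sample_truth <- function(sample_id = "S1", small_variants = NULL,
                         exon_deletions = NULL) {
  empty_sv <- data.frame(locus = character(), haplotype = integer(),
                         pos = integer(), ref = character(), alt = character(),
                         kind = character(), stringsAsFactors = FALSE)
  empty_del <- data.frame(locus = character(), haplotype = integer(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  sv <- if (is.null(small_variants)) empty_sv else as.data.frame(small_variants)
  dels <- if (is.null(exon_deletions)) empty_del else as.data.frame(exon_deletions)
  if (nrow(sv)) {
    stopifnot(all(sv$locus %in% c("gene", "pseudo")),
              all(sv$haplotype %in% c(1L, 2L)),
              all(sv$kind %in% c("snv", "ins", "del")))
    key <- paste(sv$locus, sv$haplotype, sv$pos)
    if (anyDuplicated(key)) stop("duplicate events on one haplotype/position")
  }
  if (nrow(dels)) {
    stopifnot(all(dels$locus %in% c("gene", "pseudo")),
              all(dels$haplotype %in% c(1L, 2L)), all(dels$end >= dels$start))
    for (i in seq_len(nrow(dels))) {
      hit <- sv$locus == dels$locus[i] & sv$haplotype == dels$haplotype[i] &
        sv$pos >= dels$start[i] & sv$pos <= dels$end[i]
      if (any(hit)) stop("exon deletion overlaps a small variant on the same haplotype")
    }
  }
  structure(list(sample_id = sample_id, small_variants = sv,
                 exon_deletions = dels), class = "sample_truth")
}

apply_events_to_seq <- function(seq, sv, dels) {
  # apply right-to-left so earlier coordinates stay valid
  ev <- rbind(
    if (nrow(sv)) data.frame(pos = sv$pos, ref = sv$ref, alt = sv$alt) else NULL,
    if (nrow(dels)) data.frame(pos = dels$start,
                               ref = vapply(seq_len(nrow(dels)), function(i)
                                 substr(seq, dels$start[i], dels$end[i]), character(1)),
                               alt = "") else NULL)
  if (is.null(ev) || nrow(ev) == 0) return(seq)
  ev <- ev[order(-ev$pos), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i]; r <- ev$ref[i]
    if (substr(seq, p, p + nchar(r) - 1L) != r)
      stop(sprintf("reference allele mismatch at pos %d: expected %s", p, r))
    seq <- paste0(substr(seq, 1L, p - 1L), ev$alt[i],
                  substr(seq, p + nchar(r), nchar(seq)))
  }
  seq
}

#' Materialise the four haplotype sequences of a diploid sample
#'
#' Applies the sample's events to the reference pair, producing the two gene
#' and two pseudogene haplotypes that co-exist in a real sample (and whose
#' reads will all collapse onto the gene after masking).
#'
#' @param ref a [make_paralog_reference()] object.
#' @param truth a [sample_truth()] object.
#' @return named list of four DNA strings: `gene_hap1`, `gene_hap2`,
#'   `pseudo_hap1`, `pseudo_hap2`.
#' @export
simulate_sample <- function(ref, truth) {
  stopifnot(inherits(ref, "paralog_ref"), inherits(truth, "sample_truth"))
  sv <- truth$small_variants; dels <- truth$exon_deletions
  out <- list()
  for (locus in c("gene", "pseudo")) {
    base <- if (locus == "gene") ref$gene_seq else ref$pseudo_seq
    for (h in 1:2) {
      s <- sv[sv$locus == locus & sv$haplotype == h, , drop = FALSE]
      d <- dels[dels$locus == locus & dels$haplotype == h, , drop = FALSE]
      if (nrow(s) && (any(s$pos < 1) || any(s$pos > nchar(base))))
        stop("variant position outside ", locus, " locus")
      out[[paste0(locus, "_hap", h)]] <- apply_events_to_seq(base, s, d)
    }
  }
  out
}
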