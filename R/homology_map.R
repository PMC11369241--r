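#' Derive the homology map and PSV catalog by pairwise alignment
#'
#' Locally aligns the pseudogene locus against the gene locus (affine gaps:
#' match +1, mismatch -1, gap open 4, gap extend 1), so unrelated flanking
#' sequence on either locus is trimmed and only the homologous duplication
#' aligns. Mismatch columns become paralogous sequence variants (PSVs); gap
#' runs split the alignment into collinear homology blocks. The map is
#' derived purely from the two sequences, never from simulator internals,
#' so downstream callers cannot peek at generator truth.
#'
#' @param gene_seq,pseudo_seq DNA strings of the two loci.
#' @param min_block minimum block length (bp) retained in the map.
#' @param min_aligned_frac the aligned region must cover at least this
#'   fraction of the shorter locus, else the pair is rejected as
#'   non-paralogous.
#' @return object of class `homology_map`: `blocks` (data.frame
#'   `gene_start`, `gene_end`, `pseudo_start`, `pseudo_end`, `orientation`),
#'   `psvs` (data.frame `gene_pos`, `pseudo_pos`, `gene_base`,
#'   `pseudo_base`), `identity_observed`, and `gene_len`.
#' @export
derive_homology_map <- function(gene_seq, pseudo_seq, min_block = 30L,
                                min_aligned_frac = 0.3) {
  stopifnot(nchar(gene_seq) > 0, nchar(pseudo_seq) > 0)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pseudo_seq),
    subject = Biostrings::DNAString(gene_seq),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  pat <- str_chars(as.character(Biostrings::alignedPattern(al)))
  sub <- str_chars(as.character(Biostrings::alignedSubject(al)))
  sub_off <- Biostrings::start(Biostrings::subject(al)) - 1L
  pat_off <- Biostrings::start(Biostrings::pattern(al)) - 1L

  # trim alignment termini until each ends in a clean run of >= 8 matched
  # columns: chance extension of the local alignment into unrelated flanking
  # sequence would otherwise add spurious edge PSVs
  min_run <- 8L
  is_match <- pat == sub & pat != "-"
  lo <- 1L; hi <- length(pat)
  repeat {
    moved <- FALSE
    while (lo <= hi - min_run + 1L && !all(is_match[lo:(lo + min_run - 1L)])) {
      bad <- lo + max(which(!is_match[lo:(lo + min_run - 1L)])) - 1L
      sub_off <- sub_off + sum(sub[lo:bad] != "-")
      pat_off <- pat_off + sum(pat[lo:bad] != "-")
      lo <- bad + 1L
      moved <- TRUE
    }
    while (hi >= lo + min_run - 1L && !all(is_match[(hi - min_run + 1L):hi])) {
      bad <- hi - min_run + min(which(!is_match[(hi - min_run + 1L):hi]))
      hi <- bad - 1L
      moved <- TRUE
    }
    if (!moved) break
  }
  if (hi - lo + 1L < min_run)
    stop("no clean aligned segment between the sequences")
  pat <- pat[lo:hi]; sub <- sub[lo:hi]

  gene_pos <- cumsum(sub != "-") + sub_off
  pseudo_pos <- cumsum(pat != "-") + pat_off
  aligned <- sub != "-" & pat != "-"
  n_aligned <- sum(aligned)
  if (n_aligned < min_aligned_frac * min(nchar(gene_seq), nchar(pseudo_seq)))
    stop(sprintf(
      "only %d aligned columns between loci of %d and %d bp: ",
      n_aligned, nchar(gene_seq), nchar(pseudo_seq)),
      "sequences do not look like a paralog pair")
  mism <- aligned & sub != pat
  identity_observed <- 1 - sum(mism) / n_aligned
  if (identity_observed < 0.5)
    stop(sprintf(
      "aligned identity %.2f < 0.5: sequences do not look like a paralog pair",
      identity_observed))

  # blocks: maximal runs of aligned columns, split by any gap
  r <- rle(aligned)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blk <- data.frame(col_start = starts[r$values], col_end = ends[r$values])
  blocks <- data.frame(
    gene_start = gene_pos[blk$col_start],
    gene_end = gene_pos[blk$col_end],
    pseudo_start = pseudo_pos[blk$col_start],
    pseudo_end = pseudo_pos[blk$col_end],
    orientation = "+")
  blocks <- blocks[blocks$gene_end - blocks$gene_start + 1L >= min_block, ,
                   drop = FALSE]
  rownames(blocks) <- NULL

  psvs <- data.frame(
    gene_pos = gene_pos[mism],
    pseudo_pos = pseudo_pos[mism],
    gene_base = sub[mism],
    pseudo_base = pat[mism],
    stringsAsFactors = FALSE)
  # keep only PSVs inside retained blocks
  if (nrow(psvs)) {
    inside <- vapply(psvs$gene_pos, function(p)
      any(p >= blocks$gene_start & p <= blocks$gene_end), logical(1))
    psvs <- psvs[inside, , drop = FALSE]
    rownames(psvs) <- NULL
  }
  structure(list(blocks = blocks, psvs = psvs,
                 identity_observed = identity_observed,
                 gene_len = nchar(gene_seq)),
            class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("homology_map: %d block(s), %d PSVs, observed identity %.4f\n",
              nrow(x$blocks), nrow(x$psvs), x$identity_observed))
  invisible(x)
}

#' Classify a gene position as homologous or unique
#'
#' A position is `"homology"` iff it falls inside an aligned block of the
#' map; variants at `"unique"` positions behave as ordinary diploid sites
#' (allele fractions 0.5 / 1.0 instead of 0.25 / 0.5).
#'
#' @param pos_on_gene 1-based position(s) on the gene locus.
#' @param map a [derive_homology_map()] object.
#' @return character vector, `"homology"` or `"unique"`.
#' @export
classify_region <- function(pos_on_gene, map) {
  stopifnot(inherits(map, "homology_map"))
  if (any(pos_on_gene < 1 | pos_on_gene > map$gene_len))
    stop("position outside gene bounds")
  vapply(pos_on_gene, function(p)
    if (any(p >= map$blocks$gene_start & p <= map$blocks$gene_end))
      "homology" else "unique",
    character(1))
}

#' Project a pseudogene position onto the gene (and back)
#'
#' @param pos position(s) to project.
#' @param map a [derive_homology_map()] object.
#' @param from `"pseudo"` (default) projects pseudo -> gene; `"gene"`
#'   projects gene -> pseudo.
#' @return integer positions (NA where unaligned).
#' @export
project_position <- function(pos, map, from = c("pseudo", "gene")) {
  from <- match.arg(from)
  b <- map$blocks
  vapply(pos, function(p) {
    if (from == "pseudo") {
      i <- which(p >= b$pseudo_start & p <= b$pseudo_end)
      if (length(i) == 0) return(NA_integer_)
      as.integer(b$gene_start[i[1]] + (p - b$pseudo_start[i[1]]))
    } else {
      i <- which(p >= b$gene_start & p <= b$gene_end)
      if (length(i) == 0) return(NA_integer_)
      as.integer(b$pseudo_start[i[1]] + (p - b$gene_start[i[1]]))
    }
  }, integer(1))
}

#' Write the PSV catalog as TSV and homology blocks as BED
#'
#' @param map a [derive_homology_map()] object.
#' @param psv_path,block_path output paths (either may be NULL to skip).
#' @param contig contig name used in the BED output.
#' @export
write_homology_map <- function(map, psv_path = NULL, block_path = NULL,
                               contig = "gene") {
  if (!is.null(psv_path))
    write_tsv(map$psvs[, c("gene_pos", "gene_base", "pseudo_base")], psv_path)
  if (!is.null(block_path))
    write_bed(data.frame(contig = contig, start = map$blocks$gene_start - 1L,
                         end = map$blocks$gene_end, name = "homology"),
              block_path)
  invisible(NULL)
}
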