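# CIGAR expansion and pileup. The expanded per-base table (one row per
# aligned read base, plus rows for deleted reference positions) is the
# common currency for pileups, PSV voting and locus assignment.

parse_cigar_tokens <- function(cigars) {
  m <- gregexpr("\\d+[MIDSH]", cigars)
  regmatches(cigars, m)
}

#' Expand alignments to per-base records
#'
#' @param alignments alignment table from [map_reads()] or [read_sam()].
#' @return data.table with one row per aligned base: `aidx` (row index into
#'   `alignments`), `read_id`, `contig`, `ref_pos`, `read_pos` (NA at deleted
#'   positions), `base` (`"-"` at deleted positions).
#' @export
expand_alignments <- function(alignments) {
  a <- as.data.table(alignments)
  a <- a[!is.na(pos)]
  if (nrow(a) == 0)
    return(data.table(aidx = integer(), read_id = character(),
                      contig = character(), ref_pos = integer(),
                      read_pos = integer(), base = character()))
  a[, aidx := .I]
  toks <- parse_cigar_tokens(a$cigar)
  n_tok <- lengths(toks)
  seg <- data.table(
    aidx = rep(a$aidx, n_tok),
    op = sub("^\\d+", "", unlist(toks)),
    len = as.integer(sub("[MIDSH]$", "", unlist(toks))))
  seg[, q_adv := len * (op %in% c("M", "I", "S"))]
  seg[, r_adv := len * (op %in% c("M", "D"))]
  seg[, qstart := 1L + cumsum(q_adv) - q_adv, by = aidx]
  seg[, rstart := a$pos[aidx] + cumsum(r_adv) - r_adv, by = aidx]

  msk <- seg[op == "M"]
  m_rows <- if (nrow(msk)) {
    n <- msk$len
    read_pos <- rep(msk$qstart, n) + sequence(n) - 1L
    data.table(aidx = rep(msk$aidx, n),
               ref_pos = rep(msk$rstart, n) + sequence(n) - 1L,
               read_pos = read_pos,
               base = substring(rep(a$seq[msk$aidx], n), read_pos, read_pos))
  } else NULL
  dsk <- seg[op == "D"]
  d_rows <- if (nrow(dsk)) {
    n <- dsk$len
    data.table(aidx = rep(dsk$aidx, n),
               ref_pos = rep(dsk$rstart, n) + sequence(n) - 1L,
               read_pos = NA_integer_, base = "-")
  } else NULL
  out <- rbindlist(list(m_rows, d_rows))
  out[, read_id := a$read_id[aidx]]
  out[, contig := a$contig[aidx]]
  setorder(out, ref_pos, aidx)
  out[]
}

#' Collect insertion events from alignments
#'
#' @inheritParams expand_alignments
#' @return data.table `aidx`, `read_id`, `ref_pos` (base immediately left of
#'   the insertion), `ins_len`, `ins_seq`.
#' @export
insertion_events <- function(alignments) {
  a <- as.data.table(alignments)
  a <- a[!is.na(pos)]
  if (nrow(a) == 0)
    return(data.table(aidx = integer(), read_id = character(),
                      ref_pos = integer(), ins_len = integer(),
                      ins_seq = character()))
  a[, aidx := .I]
  toks <- parse_cigar_tokens(a$cigar)
  n_tok <- lengths(toks)
  seg <- data.table(
    aidx = rep(a$aidx, n_tok),
    op = sub("^\\d+", "", unlist(toks)),
    len = as.integer(sub("[MIDSH]$", "", unlist(toks))))
  seg[, q_adv := len * (op %in% c("M", "I", "S"))]
  seg[, r_adv := len * (op %in% c("M", "D"))]
  seg[, qstart := 1L + cumsum(q_adv) - q_adv, by = aidx]
  seg[, rstart := a$pos[aidx] + cumsum(r_adv) - r_adv, by = aidx]
  ins <- seg[op == "I"]
  if (nrow(ins) == 0)
    return(data.table(aidx = integer(), read_id = character(),
                      ref_pos = integer(), ins_len = integer(),
                      ins_seq = character()))
  data.table(aidx = ins$aidx, read_id = a$read_id[ins$aidx],
             ref_pos = ins$rstart - 1L, ins_len = ins$len,
             ins_seq = substring(a$seq[ins$aidx], ins$qstart,
                                 ins$qstart + ins$len - 1L))
}

#' Per-position pileup from masked alignments
#'
#' Counts A/C/G/T and deleted-base support per reference position. Depth is
#' the sum of base counts plus the deletion count; soft-clipped bases never
#' enter the pileup.
#'
#' @param alignments alignment table.
#' @param ref_seqs named character vector with the (masked) reference.
#' @param region optional `c(start, end)` (1-based inclusive) restricting the
#'   output; default: positions 1..contig length.
#' @param contig contig to pile up (default: the single contig present).
#' @return data.table with columns `contig`, `pos`, `ref`, `depth`, `A`,
#'   `C`, `G`, `T`, `del`, `ins` (number of insertion events anchored at the
#'   position).
#' @export
pileup <- function(alignments, ref_seqs, region = NULL, contig = NULL) {
  if (is.null(contig)) {
    cand <- unique(stats::na.omit(as.data.table(alignments)$contig))
    contig <- if (length(cand)) cand[1] else names(ref_seqs)[1]
  }
  L <- nchar(ref_seqs[[contig]])
  if (is.null(region)) region <- c(1L, L)
  pos_range <- seq.int(region[1], region[2])

  ctg_want <- contig
  ex <- expand_alignments(alignments)
  ex <- ex[contig == ctg_want & ref_pos >= region[1] & ref_pos <= region[2]]
  counts <- if (nrow(ex))
    data.table::dcast(ex[, .N, by = .(ref_pos, base)],
                      ref_pos ~ base, value.var = "N", fill = 0L)
  else data.table(ref_pos = integer())
  for (b in c(DNA_BASES, "-")) if (!b %in% names(counts)) counts[, (b) := 0L]

  ins <- insertion_events(alignments)
  ins_n <- if (nrow(ins)) ins[ref_pos >= region[1] & ref_pos <= region[2],
                              .(ins = .N), by = ref_pos]
  else data.table(ref_pos = integer(), ins = integer())

  out <- data.table(contig = contig, pos = pos_range,
                    ref = chars_at(ref_seqs[[contig]], pos_range))
  out <- merge(out, counts, by.x = "pos", by.y = "ref_pos", all.x = TRUE)
  out <- merge(out, ins_n, by.x = "pos", by.y = "ref_pos", all.x = TRUE)
  for (b in c(DNA_BASES, "-", "ins"))
    out[is.na(get(b)), (b) := 0L]
  setnames(out, "-", "del")
  out[, depth := A + C + G + T + del]
  setcolorder(out, c("contig", "pos", "ref", "depth", "A", "C", "G", "T",
                     "del", "ins"))
  setorder(out, pos)
  out[]
}
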