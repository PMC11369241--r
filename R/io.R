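# File-format plumbing: FASTA via Biostrings, FASTQ/BED/SAM as the minimal
# text formats the pipeline exchanges with external tools.

#' Write a reference pair to disk
#'
#' Default mode `"single"` concatenates gene + pseudogene into one contig
#' (`chrT`) with a JSON sidecar recording the locus offsets, so that BED
#' masking of the pseudogene interval is meaningful — the layout the masking
#' strategy operates on. Mode `"split"` writes two records (`gene`,
#' `pseudo`).
#'
#' @param ref a [make_paralog_reference()] object.
#' @param dir output directory (created if needed).
#' @param mode `"single"` (default) or `"split"`.
#' @param contig contig name used in single mode.
#' @return invisibly, a list with the FASTA path, the mask BED path
#'   (single mode: the pseudogene interval in 0-based half-open convention),
#'   and the offsets sidecar path.
#' @export
write_reference <- function(ref, dir, mode = c("single", "split"),
                            contig = "chrT") {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference.fa")
  bed <- file.path(dir, "mask.bed")
  sidecar <- file.path(dir, "offsets.json")
  gene_len <- nchar(ref$gene_seq); pseudo_len <- nchar(ref$pseudo_seq)
  ph <- ref$pseudo_hom_interval
  if (mode == "single") {
    seqs <- Biostrings::DNAStringSet(paste0(ref$gene_seq, ref$pseudo_seq))
    names(seqs) <- contig
    Biostrings::writeXStringSet(seqs, fa)
    # BED: 0-based half-open. Only the homologous duplication is masked —
    # the pseudogene's flanking sequence, like the real surrounding
    # chromosome, stays mappable.
    write_bed(data.frame(contig = contig, start = gene_len + ph[1] - 1L,
                         end = gene_len + ph[2], name = "pseudo_mask"),
              bed)
    jsonlite::write_json(
      list(contig = contig,
           gene = list(offset = 0L, length = gene_len),
           pseudo = list(offset = gene_len, length = pseudo_len)),
      sidecar, auto_unbox = TRUE)
  } else {
    seqs <- Biostrings::DNAStringSet(c(gene = ref$gene_seq,
                                       pseudo = ref$pseudo_seq))
    Biostrings::writeXStringSet(seqs, fa)
    write_bed(data.frame(contig = "pseudo", start = ph[1] - 1L, end = ph[2],
                         name = "pseudo_mask"), bed)
    jsonlite::write_json(
      list(gene = list(contig = "gene", length = gene_len),
           pseudo = list(contig = "pseudo", length = pseudo_len)),
      sidecar, auto_unbox = TRUE)
  }
  invisible(list(fasta = fa, mask_bed = bed, offsets = sidecar))
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a read set as FASTQ
#'
#' Short paired read sets are written as `<prefix>_R1.fastq` /
#' `<prefix>_R2.fastq`; long read sets as `<prefix>.fastq`. Only read id,
#' sequence and quality are written — truth-origin columns never leave the
#' simulator's tables.
#'
#' @param reads a `read_set` from [simulate_short_reads()] or
#'   [simulate_long_reads()].
#' @param prefix output path prefix.
#' @return invisibly, the file path(s).
#' @export
write_fastq <- function(reads, prefix) {
  fq_lines <- function(d)
    as.vector(rbind(paste0("@", d$read_id), d$seq, "+", d$qual))
  if (identical(attr(reads, "platform"), "short_paired")) {
    p1 <- paste0(prefix, "_R1.fastq"); p2 <- paste0(prefix, "_R2.fastq")
    writeLines(fq_lines(reads[reads$mate == 1L, ]), p1)
    writeLines(fq_lines(reads[reads$mate == 2L, ]), p2)
    invisible(c(p1, p2))
  } else {
    p <- paste0(prefix, ".fastq")
    writeLines(fq_lines(reads), p)
    invisible(p)
  }
}

#' Read FASTQ file(s) into a read set
#' @param paths one or two (paired) FASTQ paths.
#' @export
read_fastq <- function(paths) {
  one <- function(p, mate) {
    ln <- readLines(p)
    stopifnot(length(ln) %% 4 == 0)
    data.table(read_id = sub("^@", "", ln[seq(1, length(ln), 4)]),
               mate = mate,
               seq = ln[seq(2, length(ln), 4)],
               qual = ln[seq(4, length(ln), 4)])
  }
  if (length(paths) == 2) {
    rs <- rbindlist(list(one(paths[1], 1L), one(paths[2], 2L)))
    setattr(rs, "platform", "short_paired")
  } else {
    rs <- one(paths[1], NA_integer_)
    setattr(rs, "platform", "long")
  }
  rs[]
}

#' Write intervals as BED (0-based half-open)
#' @param intervals data.frame with columns `contig`, `start`, `end` and
#'   optionally `name`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("contig", "start", "end", "name"), names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#' @param path BED path.
#' @export
read_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("contig", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  d
}

#' Write alignments as minimal SAM
#'
#' Emits a valid header (`@HD`, `@SQ`) and one line per aligned read with
#' POS/CIGAR/MAPQ filled in, so external viewers and samtools accept the
#' output. Unaligned reads get flag 4 with `*` position fields.
#'
#' @param alignments an alignment table from [map_reads()].
#' @param ref_seqs named character vector of reference sequences (for `@SQ`
#'   lengths).
#' @param path output path.
#' @export
write_sam <- function(alignments, ref_seqs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_seqs), nchar(ref_seqs)))
  a <- as.data.table(alignments)
  body <- ifelse(
    is.na(a$pos),
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", a$read_id, a$seq),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            a$read_id,
            ifelse(is.na(a$strand) | a$strand == "+", 0L, 16L),
            a$contig, a$pos, a$mapq, a$cigar, a$seq))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Accepts minimal SAM as produced by [write_sam()] or by external aligners
#' (only the 11 mandatory columns are used; supplementary alignments are
#' kept and flagged).
#'
#' @param path SAM path.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0) return(empty_alignments())
  f <- data.table::tstrsplit(ln, "\t", fixed = TRUE, keep = 1:11)
  flag <- as.integer(f[[2]])
  aligned <- bitwAnd(flag, 4L) == 0L
  data.table(
    read_id = f[[1]],
    contig = ifelse(aligned, f[[3]], NA_character_),
    pos = ifelse(aligned, as.integer(f[[4]]), NA_integer_),
    mapq = as.integer(f[[5]]),
    cigar = ifelse(aligned, f[[6]], NA_character_),
    strand = ifelse(aligned, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    seq = f[[10]],
    is_supplementary = bitwAnd(flag, 2048L) > 0L)
}

empty_alignments <- function() {
  data.table(read_id = character(), contig = character(), pos = integer(),
             mapq = integer(), cigar = character(), strand = character(),
             seq = character(), is_supplementary = logical())
}

#' Write a table as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
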