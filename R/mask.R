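#' Hard-mask intervals of a reference (maskfasta semantics)
#'
#' Replaces every base inside the given intervals with `N`, leaving sequence
#' length and all other bases untouched. With the pseudogene interval masked,
#' no seed k-mer can be indexed there, so all four homologous alleles are
#' forced to align onto the gene locus.
#'
#' @param ref_seqs named character vector of reference sequences (or a path
#'   to a FASTA file).
#' @param mask data.frame of intervals with columns `contig`, `start`, `end`;
#'   interpretation of `start`/`end` follows `coords`.
#' @param coords `"bed"` (default): 0-based half-open, the bedtools
#'   convention; `"one-based"`: 1-based inclusive. Published masked intervals
#'   are sometimes printed without stating the convention, so it is explicit
#'   here rather than guessed.
#' @return named character vector of masked sequences, same lengths.
#' @export
mask_reference <- function(ref_seqs, mask, coords = c("bed", "one-based")) {
  coords <- match.arg(coords)
  if (is.character(ref_seqs) && length(ref_seqs) == 1 && file.exists(ref_seqs))
    ref_seqs <- read_fasta(ref_seqs)
  if (is.null(names(ref_seqs)) || any(names(ref_seqs) == ""))
    stop("reference sequences must be named")
  mask <- as.data.frame(mask)
  if (nrow(mask) == 0) return(ref_seqs)
  stopifnot(all(c("contig", "start", "end") %in% names(mask)))
  out <- ref_seqs
  for (i in seq_len(nrow(mask))) {
    ctg <- mask$contig[i]
    if (!ctg %in% names(out)) stop("unknown contig in mask: ", ctg)
    L <- nchar(out[[ctg]])
    if (coords == "bed") {
      s1 <- mask$start[i] + 1L; e1 <- mask$end[i]
    } else {
      s1 <- mask$start[i]; e1 <- mask$end[i]
    }
    if (s1 < 1 || e1 > L || e1 < s1)
      stop(sprintf("mask interval out of bounds on %s: [%d, %d] vs length %d",
                   ctg, s1, e1, L))
    substr(out[[ctg]], s1, e1) <- strrep("N", e1 - s1 + 1L)
  }
  out
}
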