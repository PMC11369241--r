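# Read simulation. A read set is a data.table with one row per read:
#   read_id, mate (1/2, NA for long reads), seq, qual,
#   origin_locus, origin_hap, origin_start (1-based on the haplotype string).
# The origin_* columns exist for scoring only; the mapper and all callers
# consume only read_id/seq (enforced by never passing origin columns on).

QUAL_SHORT <- "?"  # Q30
QUAL_LONG <- "-"   # Q12

apply_sub_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0) return(seqs)
  gpos <- sort(sample.int(total, n_err))
  offs <- c(0L, cumsum(lens))
  idx <- findInterval(gpos, offs, left.open = TRUE)  # read index per error
  local_pos <- gpos - offs[idx]
  for (i in unique(idx)) {
    p <- local_pos[idx == i]
    ch <- str_chars(seqs[i])
    ch[p] <- vapply(ch[p], function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

apply_indel_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    n_ev <- rbinom(1L, n, rate)
    if (n_ev == 0) next
    pos <- sort(sample.int(n, n_ev), decreasing = TRUE)
    is_ins <- runif(n_ev) < 0.5
    ch <- str_chars(seqs[i])
    for (j in seq_len(n_ev)) {
      p <- pos[j]
      if (is_ins[j]) {
        ch <- append(ch, sample(DNA_BASES, 1L), after = p)
      } else if (length(ch) > 1L) {
        ch <- ch[-p]
      }
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

hap_table <- function(haplotypes) {
  stopifnot(is.list(haplotypes), length(haplotypes) == 4)
  nm <- names(haplotypes)
  data.frame(
    name = nm,
    locus = sub("_hap[12]$", "", nm),
    hap = as.integer(sub("^.*_hap", "", nm)),
    len = vapply(haplotypes, nchar, integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Simulate paired-end short reads from the four haplotypes
#'
#' Fragments are drawn uniformly from each haplotype at `coverage / 4` fold
#' per haplotype, so the collapsed (masked-alignment) depth over the homology
#' block totals `coverage`, while unique gene regions sit near
#' `coverage / 2` — the depth signature of pseudogene masking. Fragment
#' lengths are uniform on `[frag_min, frag_max]` (default 150-300 bp,
#' mirroring a capture-based paired-end library); substitution errors are
#' i.i.d. at `sub_error`. Base qualities are a constant Q30.
#'
#' @param haplotypes list of four haplotype strings from [simulate_sample()].
#' @param coverage collapsed fold-coverage over the homology block.
#' @param read_len read length (bp).
#' @param frag_min,frag_max fragment length bounds (bp).
#' @param sub_error per-base substitution error rate.
#' @param seed integer seed; output is byte-deterministic given it.
#' @return a `read_set` data.table (paired rows share a `read_id` stem with
#'   `/1` and `/2` suffixes) with attribute `platform = "short_paired"`.
#' @export
simulate_short_reads <- function(haplotypes, coverage = 100, read_len = 150L,
                                 frag_min = 150L, frag_max = 300L,
                                 sub_error = 0.001, seed = 1L) {
  stopifnot(coverage > 0, read_len > 0, frag_max >= frag_min, frag_min > 0)
  set.seed(seed)
  ht <- hap_table(haplotypes)
  out <- vector("list", nrow(ht))
  for (i in seq_len(nrow(ht))) {
    L <- ht$len[i]
    seq_i <- haplotypes[[i]]
    n_frag <- max(1L, as.integer(ceiling(coverage / 4 * L / (2 * read_len))))
    flen <- pmin(L, sample(seq.int(frag_min, frag_max), n_frag, replace = TRUE))
    fstart <- as.integer(floor(runif(n_frag, 1, L - flen + 1 + 1)))
    fstart <- pmin(fstart, L - flen + 1L)
    frag <- substring(seq_i, fstart, fstart + flen - 1L)
    rl <- pmin(read_len, flen)
    r1 <- substring(frag, 1L, rl)
    r2 <- revcomp(substring(frag, flen - rl + 1L, flen))
    ids <- sprintf("%s_f%06d", ht$name[i], seq_len(n_frag))
    out[[i]] <- data.table(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      mate = rep(c(1L, 2L), each = n_frag),
      seq = c(r1, r2),
      origin_locus = ht$locus[i], origin_hap = ht$hap[i],
      origin_start = c(fstart, fstart + flen - rl))
  }
  rs <- rbindlist(out)
  rs[, seq := apply_sub_errors(seq, sub_error)]
  rs[, qual := strrep(QUAL_SHORT, nchar(seq))]
  setattr(rs, "platform", "short_paired")
  rs[]
}

#' Simulate long (nanopore-like) reads from the four haplotypes
#'
#' Read lengths are log-normal with mean `len_mean` and sd `len_sd`;
#' substitution and 1-bp indel errors are applied at the given rates. Reads
#' are drawn uniformly from each haplotype at `coverage / 4` fold, so reads
#' spanning a deleted interval on a deletion-carrying haplotype contain the
#' junction. Base qualities are a constant Q12.
#'
#' @inheritParams simulate_short_reads
#' @param len_mean,len_sd mean and sd of read length (bp).
#' @param indel_error per-base 1-bp insertion/deletion error rate.
#' @return a `read_set` data.table with attribute `platform = "long"`.
#' @export
simulate_long_reads <- function(haplotypes, coverage = 30, len_mean = 3000,
                                len_sd = 1000, sub_error = 0.02,
                                indel_error = 0.01, seed = 1L) {
  stopifnot(coverage > 0, len_mean > 0, len_sd >= 0)
  set.seed(seed)
  ht <- hap_table(haplotypes)
  out <- vector("list", nrow(ht))
  for (i in seq_len(nrow(ht))) {
    L <- ht$len[i]
    n_reads <- max(1L, as.integer(ceiling(coverage / 4 * L / min(len_mean, L))))
    if (len_sd > 0) {
      lp <- lnorm_params(len_mean, len_sd)
      lens <- as.integer(round(rlnorm(n_reads, lp$meanlog, lp$sdlog)))
    } else lens <- rep(as.integer(len_mean), n_reads)
    lens <- pmax(200L, pmin(L, lens))
    rstart <- as.integer(floor(runif(n_reads, 1, L - lens + 1 + 1)))
    rstart <- pmin(rstart, L - lens + 1L)
    out[[i]] <- data.table(
      read_id = sprintf("%s_l%06d", ht$name[i], seq_len(n_reads)),
      mate = NA_integer_,
      seq = substring(haplotypes[[i]], rstart, rstart + lens - 1L),
      origin_locus = ht$locus[i], origin_hap = ht$hap[i],
      origin_start = rstart)
  }
  rs <- rbindlist(out)
  rs[, seq := apply_sub_errors(seq, sub_error)]
  rs[, seq := apply_indel_errors(seq, indel_error)]
  rs[, qual := strrep(QUAL_LONG, nchar(seq))]
  setattr(rs, "platform", "long")
  rs[]
}
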