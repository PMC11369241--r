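# Long-read rescue stage. Long reads span many PSVs, so each read can be
# assigned to gene or pseudogene by voting over the PSV bases it covers.
# Binning undoes the masking collapse: per-locus re-genotyping confirms
# homozygosity without parents, alignment gaps reveal exon deletions, and
# co-covered heterozygous sites are phased read-backed.

#' Bin long reads to gene vs pseudogene by PSV voting
#'
#' Each read votes `+log((1-q)/q)` for a gene-base match and the negative
#' for a pseudo-base match at every PSV it spans (other bases are ignored as
#' sequencing errors). Reads reaching `|log_odds| >= threshold_lo` are
#' assigned; reads whose alignment covers `>= unique_margin` bases outside
#' every homology block are gene-origin by construction and assigned
#' directly.
#'
#' @param alignments long-read alignment table (on the masked reference, so
#'   all reads sit on the gene locus).
#' @param map a [derive_homology_map()] object.
#' @param q per-base error rate for the vote weight.
#' @param threshold_lo log-odds (nats) required to leave "unassigned".
#' @param unique_margin bases of unique (non-block) gene sequence that force
#'   a direct gene assignment.
#' @param expanded optional precomputed [expand_alignments()] table.
#' @return data.table: `read_id`, `assigned_locus` ("gene"/"pseudo"/
#'   "unassigned"), `log_odds`, `n_psv_informative`, `unique_overlap`.
#' @export
bin_reads <- function(alignments, map, q = 0.05, threshold_lo = 3,
                      unique_margin = 30L, expanded = NULL) {
  stopifnot(q > 0, q < 0.3)
  a <- as.data.table(alignments)[!is.na(pos)]
  if (nrow(a) == 0)
    return(data.table(read_id = character(), assigned_locus = character(),
                      log_odds = numeric(), n_psv_informative = integer(),
                      unique_overlap = integer()))
  ex <- if (is.null(expanded)) expand_alignments(alignments) else expanded
  psv <- as.data.table(map$psvs)
  setnames(psv, "gene_pos", "ref_pos")
  obs <- ex[ref_pos %in% psv$ref_pos & base != "-"]
  obs <- psv[obs, on = "ref_pos", nomatch = NULL]
  w <- log((1 - q) / q)
  obs[, vote := fifelse(base == gene_base, w,
                        fifelse(base == pseudo_base, -w, 0))]
  votes <- obs[vote != 0, .(log_odds = sum(vote), n_psv_informative = .N),
               by = read_id]

  # bases outside homology blocks per read (aligned M bases only)
  blk <- map$blocks
  in_block <- rep(FALSE, map$gene_len)
  for (i in seq_len(nrow(blk)))
    in_block[blk$gene_start[i]:blk$gene_end[i]] <- TRUE
  uo <- ex[base != "-" & ref_pos <= map$gene_len & !in_block[ref_pos],
           .(unique_overlap = .N), by = read_id]

  out <- data.table(read_id = unique(a$read_id))
  out <- merge(out, votes, by = "read_id", all.x = TRUE)
  out <- merge(out, uo, by = "read_id", all.x = TRUE)
  # reads aligned beyond the gene locus sit in pseudogene flanking sequence
  # (the only unmasked non-gene territory) and are pseudo-origin directly
  pflank <- ex[ref_pos > map$gene_len, .(pseudo_flank = .N), by = read_id]
  out <- merge(out, pflank, by = "read_id", all.x = TRUE)
  out[is.na(log_odds), log_odds := 0]
  out[is.na(n_psv_informative), n_psv_informative := 0L]
  out[is.na(unique_overlap), unique_overlap := 0L]
  out[is.na(pseudo_flank), pseudo_flank := 0L]
  # PSV votes accumulate over the whole read and are the stronger evidence;
  # unique-sequence overlap decides only reads the PSVs leave ambiguous
  out[, assigned_locus := fifelse(
    log_odds >= threshold_lo, "gene",
    fifelse(log_odds <= -threshold_lo, "pseudo",
            fifelse(pseudo_flank >= unique_margin, "pseudo",
                    fifelse(unique_overlap >= unique_margin, "gene",
                            "unassigned"))))]
  out[]
}

#' Call the allele each read carries at a site, by local realignment
#'
#' Noisy long reads can be locally smeared around a variant (indel errors
#' fall in the anchor-free window the variant itself creates), so the single
#' pileup base at the column under-calls the true allele. This helper takes
#' each read's segment across `pos +/- window` and slides it against two
#' candidate references — the window with the ref allele and with the alt
#' allele at its centre — scoring identity over small shifts; the better
#' match wins, ties are NA.
#'
#' @param alignments alignment table.
#' @param pos 1-based site position.
#' @param ref_allele,alt_allele the two candidate bases (SNVs).
#' @param ref_seq the reference sequence string (gene portion).
#' @param window half-width (bp) of the comparison window.
#' @param max_shift largest local misalignment (bp) tolerated.
#' @param expanded optional precomputed [expand_alignments()] table.
#' @return data.table `read_id`, `allele` ("ref"/"alt"/NA).
#' @export
site_allele_calls <- function(alignments, pos, ref_allele, alt_allele,
                              ref_seq, window = 12L, max_shift = 3L,
                              expanded = NULL) {
  ex <- if (is.null(expanded)) expand_alignments(alignments) else expanded
  a <- as.data.table(alignments)[!is.na(pos)]
  near <- ex[ref_pos >= pos - window & ref_pos <= pos + window &
               !is.na(read_pos)]
  if (nrow(near) == 0)
    return(data.table(read_id = character(), allele = character()))
  segs <- near[, .(rp_min = min(read_pos), rp_max = max(read_pos),
                   r_min = min(ref_pos), r_max = max(ref_pos),
                   n_cols = .N), by = read_id]
  # require the read to span the whole window (within a little smear)
  segs <- segs[n_cols >= window & r_min <= pos - window + 2L &
                 r_max >= pos + window - 2L]
  win_ref <- substr(ref_seq, pos - window, pos + window)
  win_alt <- win_ref
  substr(win_alt, window + 1L, window + 1L) <- alt_allele
  if (substr(win_ref, window + 1L, window + 1L) != ref_allele)
    stop("ref_allele does not match the reference at pos")
  i_ref <- utf8ToInt(win_ref); i_alt <- utf8ToInt(win_alt)
  wl <- length(i_ref)

  # banded semi-global alignment: the whole candidate window must align,
  # the segment's ends are free; indel errors in the segment cost gaps
  # instead of derailing the comparison
  score_against <- function(iseg, iwin) {
    ls <- length(iseg)
    gap <- 2L
    band <- max_shift + 3L
    prev <- rep(0L, ls + 1L)  # row 0: free segment prefix
    for (i in seq_len(wl)) {
      cur <- rep(-10000L, ls + 1L)
      cur[1] <- -gap * i
      jlo <- max(1L, i - band); jhi <- min(ls, i + band)
      for (j in jlo:jhi) {
        m <- if (iseg[j] == iwin[i]) 1L else -1L
        best <- prev[j] + m
        if (prev[j + 1L] - gap > best) best <- prev[j + 1L] - gap
        if (cur[j] - gap > best) best <- cur[j] - gap
        cur[j + 1L] <- best
      }
      prev <- cur
    }
    max(prev)  # free segment suffix
  }
  seq_by_read <- setNames(a$seq, a$read_id)
  out <- segs[, {
    sq <- seq_by_read[[read_id]]
    iseg <- utf8ToInt(substr(sq, rp_min, rp_max))
    s_ref <- score_against(iseg, i_ref)
    s_alt <- score_against(iseg, i_alt)
    allele <- if (s_ref > s_alt) "ref" else if (s_alt > s_ref) "alt"
    else NA_character_
    .(allele = allele)
  }, by = read_id]
  out
}

#' Re-genotype a site per locus using binned long reads
#'
#' Restricting to reads binned to one locus undoes the four-copy collapse:
#' a variant that is truly homozygous in the gene shows ~100% alt among
#' gene-binned reads (instead of the ~50% seen in the masked short-read
#' pileup), confirming homozygosity without parental samples. Diploid
#' binomial genotyping over theta in {0, 0.5, 1} with per-base error `e`.
#'
#' @param bins output of [bin_reads()].
#' @param alignments long-read alignment table.
#' @param site_pos 1-based gene position.
#' @param alt_allele alt base, or `"-"` for a deletion allele.
#' @param locus which bin to genotype (default "gene").
#' @param e per-base error rate.
#' @param min_reads minimum binned reads covering the site (else no-call).
#' @param ref_seq optional reference sequence string; when given (SNVs
#'   only), per-read alleles come from windowed realignment
#'   ([site_allele_calls()]) instead of the raw pileup base, which is
#'   robust to local alignment smear in noisy reads.
#' @param expanded optional precomputed [expand_alignments()] table.
#' @return list: `genotype` ("ref/ref", "ref/alt", "alt/alt" or "no_call"),
#'   `alt_count`, `depth`, `posterior`.
#' @export
regenotype_per_locus <- function(bins, alignments, site_pos, alt_allele,
                                 locus = "gene", e = 0.05, min_reads = 10L,
                                 ref_seq = NULL, expanded = NULL) {
  ex <- if (is.null(expanded)) expand_alignments(alignments) else expanded
  keep <- bins$read_id[bins$assigned_locus == locus]
  if (!is.null(ref_seq) && alt_allele %in% DNA_BASES) {
    ref_allele <- substr(ref_seq, site_pos, site_pos)
    calls <- site_allele_calls(alignments, site_pos, ref_allele, alt_allele,
                               ref_seq, expanded = ex)
    calls <- calls[read_id %in% keep & !is.na(allele)]
    depth <- nrow(calls)
    if (depth < min_reads)
      return(list(genotype = "no_call", alt_count = NA_integer_,
                  depth = depth, posterior = NA_real_))
    alt_count <- sum(calls$allele == "alt")
  } else {
    col <- ex[ref_pos == site_pos & read_id %in% keep]
    depth <- nrow(col)
    if (depth < min_reads)
      return(list(genotype = "no_call", alt_count = NA_integer_,
                  depth = depth, posterior = NA_real_))
    alt_count <- sum(col$base == alt_allele)
  }
  theta <- c(0, 0.5, 1)
  p <- theta * (1 - e) + (1 - theta) * e / 3
  ll <- dbinom(alt_count, depth, p, log = TRUE)
  post <- exp(ll - max(ll)); post <- post / sum(post)
  gt <- c("ref/ref", "ref/alt", "alt/alt")[which.max(post)]
  list(genotype = gt, alt_count = alt_count, depth = depth,
       posterior = max(post))
}

# deletion evidence: long D ops in CIGARs, plus colinear supplementary pairs
deletion_signals <- function(alignments, min_sv_len) {
  a <- as.data.table(alignments)[!is.na(pos)]
  if (nrow(a) == 0)
    return(data.table(read_id = character(), start = integer(),
                      len = integer()))
  a[, aidx := .I]
  toks <- parse_cigar_tokens(a$cigar)
  n_tok <- lengths(toks)
  seg <- data.table(
    aidx = rep(a$aidx, n_tok),
    op = sub("^\\d+", "", unlist(toks)),
    len = as.integer(sub("[MIDSH]$", "", unlist(toks))))
  seg[, r_adv := len * (op %in% c("M", "D"))]
  seg[, rstart := a$pos[aidx] + cumsum(r_adv) - r_adv, by = aidx]
  d <- seg[op == "D" & len >= min_sv_len,
           .(read_id = a$read_id[aidx], start = rstart, len = len)]
  # split alignments: primary + supplementary of the same read flanking a gap
  sup <- a[, .N, by = read_id][N > 1, read_id]
  extra <- list()
  for (r in sup) {
    ar <- a[read_id == r][order(pos)]
    for (i in seq_len(nrow(ar) - 1L)) {
      span1 <- cigar_ref_span(ar$cigar[i])
      gap <- ar$pos[i + 1L] - (ar$pos[i] + span1)
      if (!is.na(gap) && gap >= min_sv_len)
        extra[[length(extra) + 1L]] <- data.table(
          read_id = r, start = ar$pos[i] + span1, len = gap)
    }
  }
  rbindlist(c(list(d), extra))
}

cigar_ref_span <- function(cigar) {
  toks <- parse_cigar_tokens(cigar)[[1]]
  op <- sub("^\\d+", "", toks)
  len <- as.integer(sub("[MIDSH]$", "", toks))
  sum(len[op %in% c("M", "D")])
}

#' Detect exon-scale deletions from long-read alignment gaps
#'
#' Collects deletion ops of length `>= min_sv_len` (and gaps between
#' colinear split alignments of one read), clusters them by breakpoint
#' proximity (`cluster_tol` bp on both start and length), and reports each
#' cluster's median breakpoints with its read support. The event locus is
#' the majority bin of the supporting reads.
#'
#' @param alignments long-read alignment table.
#' @param bins optional [bin_reads()] output for locus attribution.
#' @param min_sv_len minimum deletion length (bp).
#' @param min_support minimum supporting reads per event.
#' @param cluster_tol breakpoint clustering tolerance (bp).
#' @return data.table of SV calls: `start`, `end` (1-based inclusive on the
#'   gene), `length`, `support`, `locus`.
#' @export
detect_deletions <- function(alignments, bins = NULL, min_sv_len = 200L,
                             min_support = 3L, cluster_tol = 20L) {
  stopifnot(min_sv_len > 0, min_support > 0, cluster_tol >= 0)
  sig <- deletion_signals(alignments, min_sv_len)
  if (nrow(sig) == 0)
    return(data.table(start = integer(), end = integer(), length = integer(),
                      support = integer(), locus = character()))
  # chain-linkage on start position, then on length within each start group
  setorder(sig, start)
  sig[, cl_s := cumsum(c(TRUE, diff(start) > cluster_tol))]
  setorder(sig, cl_s, len)
  sig[, cl := cumsum(c(TRUE, diff(len) > cluster_tol | diff(cl_s) != 0L))]
  ev <- sig[, .(start = as.integer(round(median(start))),
                length = as.integer(round(median(len))),
                support = .N,
                reads = list(unique(read_id))), by = cl]
  ev <- ev[support >= min_support]
  if (nrow(ev) == 0)
    return(data.table(start = integer(), end = integer(), length = integer(),
                      support = integer(), locus = character()))
  ev[, end := start + length - 1L]
  ev[, locus := vapply(reads, function(r) {
    if (is.null(bins)) return(NA_character_)
    b <- bins$assigned_locus[match(r, bins$read_id)]
    b <- b[!is.na(b) & b != "unassigned"]
    if (length(b) == 0) return("ambiguous")
    names(sort(table(b), decreasing = TRUE))[1]
  }, character(1))]
  ev[, .(start, end, length, support, locus)]
}

#' Phase heterozygous variants with read-backed greedy linking
#'
#' Sites are visited in coordinate order; consecutive sites sharing at least
#' `min_reads` informative reads are linked when the majority orientation
#' (alt alleles co-occurring = cis vs alternating = trans) wins at least
#' `margin` of the votes; otherwise the block breaks. Within a block, the
#' first site's alt allele defines haplotype 1.
#'
#' @param alignments long-read alignment table.
#' @param het_sites data.frame with `pos`, `ref`, `alt` (alt `"-"` for
#'   deletion alleles).
#' @param min_reads minimum shared informative reads to link two sites.
#' @param margin minimum vote fraction for the winning orientation.
#' @param ref_seq optional reference string enabling realignment-based
#'   per-read allele calls at SNV sites (see [site_allele_calls()]).
#' @param expanded optional precomputed [expand_alignments()] table.
#' @return data.table: `block_id`, `pos`, `alt_hap` (1/2), `n_link`
#'   (supporting reads for the link to the previous site), `n_conflict`.
#' @export
phase_variants <- function(alignments, het_sites, min_reads = 5L,
                           margin = 0.8, ref_seq = NULL, expanded = NULL) {
  hs <- as.data.frame(het_sites)
  hs <- hs[order(hs$pos), , drop = FALSE]
  ex <- if (is.null(expanded)) expand_alignments(alignments) else expanded
  # per-read allele at each site: 1 = alt, 0 = ref, NA otherwise
  allele_at <- function(i) {
    if (!is.null(ref_seq) && hs$alt[i] %in% DNA_BASES &&
        hs$ref[i] %in% DNA_BASES) {
      calls <- site_allele_calls(alignments, hs$pos[i], hs$ref[i], hs$alt[i],
                                 ref_seq, expanded = ex)
      al <- ifelse(calls$allele == "alt", 1L,
                   ifelse(calls$allele == "ref", 0L, NA_integer_))
      return(setNames(al, calls$read_id))
    }
    col <- ex[ref_pos == hs$pos[i]]
    al <- ifelse(col$base == hs$alt[i], 1L,
                 ifelse(col$base == hs$ref[i], 0L, NA_integer_))
    setNames(al, col$read_id)
  }
  alleles <- lapply(seq_len(nrow(hs)), allele_at)
  block_id <- integer(nrow(hs))
  alt_hap <- integer(nrow(hs))
  n_link <- integer(nrow(hs)); n_conflict <- integer(nrow(hs))
  cur_block <- 1L
  block_id[1] <- cur_block; alt_hap[1] <- 1L
  for (i in seq_len(nrow(hs))[-1]) {
    a1 <- alleles[[i - 1L]]; a2 <- alleles[[i]]
    shared <- intersect(names(a1)[!is.na(a1)], names(a2)[!is.na(a2)])
    if (length(shared) < min_reads) {
      cur_block <- cur_block + 1L
      block_id[i] <- cur_block; alt_hap[i] <- 1L
      next
    }
    same <- a1[shared] == a2[shared]
    n_cis <- sum(same); n_trans <- sum(!same)
    win <- max(n_cis, n_trans) / (n_cis + n_trans)
    if (win < margin) {
      cur_block <- cur_block + 1L
      block_id[i] <- cur_block; alt_hap[i] <- 1L
      n_conflict[i] <- min(n_cis, n_trans)
      next
    }
    block_id[i] <- cur_block
    prev_hap <- alt_hap[i - 1L]
    alt_hap[i] <- if (n_cis >= n_trans) prev_hap else 3L - prev_hap
    n_link[i] <- max(n_cis, n_trans)
    n_conflict[i] <- min(n_cis, n_trans)
  }
  data.table(block_id = block_id, pos = hs$pos, ref = hs$ref, alt = hs$alt,
             alt_hap = alt_hap, n_link = n_link, n_conflict = n_conflict)
}

#' Cis/trans relation of two phased sites
#'
#' @param phased output of [phase_variants()].
#' @param pos1,pos2 site positions.
#' @return `"cis"`, `"trans"`, or `"unphased"` (different blocks).
#' @export
pair_phase <- function(phased, pos1, pos2) {
  i <- match(pos1, phased$pos); j <- match(pos2, phased$pos)
  if (is.na(i) || is.na(j) || phased$block_id[i] != phased$block_id[j])
    return("unphased")
  if (phased$alt_hap[i] == phased$alt_hap[j]) "cis" else "trans"
}
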