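# Four-copy allele-balance genotyping. After pseudogene masking, a homology
# position carries reads from four collapsed alleles (two gene + two
# pseudogene haplotypes), so a variant on a copies out of four shows an
# expected alt fraction of a/4: 0.25 for heterozygous, 0.50 for homozygous
# in one locus — the skewed ratios the masking strategy is built around.

#' Hypothesis grid for a region type
#'
#' @param region_type `"homology"` (four collapsed copies) or `"unique"`
#'   (ordinary diploid).
#' @return data.frame with `label`, `theta` (expected alt fraction) and the
#'   default `prior`.
#' @export
genotype_hypotheses <- function(region_type = c("homology", "unique")) {
  region_type <- match.arg(region_type)
  if (region_type == "homology") {
    h <- data.frame(
      label = c("ref", "het_one_locus", "hom_one_locus_or_het_both",
                "three_copies", "all_copies"),
      theta = c(0, 0.25, 0.5, 0.75, 1),
      prior = c(1, 1, 1, 0.01, 0.01))
  } else {
    h <- data.frame(label = c("ref", "het", "hom"),
                    theta = c(0, 0.5, 1),
                    prior = c(1, 1, 1))
  }
  h$prior <- h$prior / sum(h$prior)
  h
}

#' Expected alt-read fraction under the collapsed-copy model
#'
#' In homology regions four copies collapse onto the gene, so zygosity maps
#' to alt fractions of a/4; in unique regions only the two gene haplotypes
#' are present and the ordinary diploid a/2 applies.
#'
#' @param zygosity `"het"` or `"hom"` (per locus).
#' @param n_loci_carrying number of loci (gene, pseudogene) carrying the
#'   variant: 1 or 2.
#' @param region_type `"homology"` or `"unique"`.
#' @return expected alt fraction.
#' @export
expected_alt_fraction <- function(zygosity = c("het", "hom"),
                                  n_loci_carrying = 1L,
                                  region_type = c("homology", "unique")) {
  zygosity <- match.arg(zygosity)
  region_type <- match.arg(region_type)
  stopifnot(n_loci_carrying %in% c(1L, 2L))
  copies <- (if (zygosity == "het") 1L else 2L) * n_loci_carrying
  if (region_type == "unique") {
    if (n_loci_carrying == 2L)
      stop("unique regions have no pseudogene copy: n_loci_carrying must be 1")
    copies / 2
  } else {
    copies / 4
  }
}

#' Genotype one site from alt/depth counts
#'
#' Binomial likelihood over the hypothesis grid:
#' `L(h) = Binom(alt | depth, p_h)` with
#' `p_h = theta_h (1 - eps) + (1 - theta_h) eps / 3` (symmetric per-base
#' error, eps/3 to each alternative base). The MAP hypothesis is reported;
#' the call is flagged ambiguous when the top two log-likelihoods are within
#' 2 nats of each other — such sites are the ones routed to the long-read
#' stage.
#'
#' @param alt_count,depth alt-supporting and total read counts.
#' @param region_type `"homology"` or `"unique"`.
#' @param epsilon per-base sequencing error rate, in (0, 0.25).
#' @param prior optional prior vector over the hypothesis grid (recycled /
#'   normalised); default: the grid's own priors.
#' @param ambig_margin nats separating the top two log-likelihoods below
#'   which the call is flagged ambiguous.
#' @return a one-row data.frame (`site_call`): `alt_count`, `depth`,
#'   `region_type`, `map_label`, `theta_map`, `posterior`, `ambiguous`, plus
#'   attribute `loglik` (named log-likelihood vector).
#' @export
genotype_site <- function(alt_count, depth,
                          region_type = c("homology", "unique"),
                          epsilon = 0.01, prior = NULL, ambig_margin = 2) {
  region_type <- match.arg(region_type)
  stopifnot(alt_count >= 0, alt_count <= depth, epsilon > 0, epsilon < 0.25)
  hyp <- genotype_hypotheses(region_type)
  if (!is.null(prior)) {
    stopifnot(length(prior) == nrow(hyp), all(prior >= 0), sum(prior) > 0)
    hyp$prior <- prior / sum(prior)
  }
  if (depth == 0) {
    out <- data.frame(alt_count = 0L, depth = 0L, region_type = region_type,
                      map_label = "no_call", theta_map = NA_real_,
                      posterior = NA_real_, ambiguous = NA)
    attr(out, "loglik") <- setNames(rep(NA_real_, nrow(hyp)), hyp$label)
    return(out)
  }
  p_h <- hyp$theta * (1 - epsilon) + (1 - hyp$theta) * epsilon / 3
  ll <- dbinom(alt_count, depth, p_h, log = TRUE)
  lpost <- ll + log(hyp$prior)
  post <- exp(lpost - max(lpost))
  post <- post / sum(post)
  best <- which.max(post)
  ll_sorted <- sort(ll, decreasing = TRUE)
  out <- data.frame(
    alt_count = alt_count, depth = depth, region_type = region_type,
    map_label = hyp$label[best], theta_map = hyp$theta[best],
    posterior = post[best],
    ambiguous = (ll_sorted[1] - ll_sorted[2]) < ambig_margin)
  attr(out, "loglik") <- setNames(ll, hyp$label)
  attr(out, "posteriors") <- setNames(post, hyp$label)
  out
}

#' Assign a called variant to gene vs pseudogene by PSV co-observation
#'
#' Short-read locus assignment is only possible when alt-bearing reads also
#' overlap at least one PSV: each such read votes with
#' `+log((1-q)/q)` per PSV base matching the gene allele and `-log((1-q)/q)`
#' per pseudo-allele match (other bases are ignored as errors). The summed
#' log-odds give a locus posterior; the site stays `"ambiguous"` when
#' `|log-odds| < threshold` or fewer than `min_votes` informative reads
#' exist — quantifying why short reads alone often cannot place a variant.
#'
#' @param site_pos 1-based gene position of the variant.
#' @param alt_allele alt base (SNVs) or `"-"` for deletion-supporting reads.
#' @param alignments alignment table covering the site.
#' @param map a [derive_homology_map()] object (PSV source).
#' @param q per-base error rate used in the vote weight.
#' @param threshold absolute log-odds (nats) required for assignment.
#' @param min_votes minimum informative alt reads.
#' @param expanded optional precomputed [expand_alignments()] table.
#' @return list: `locus` ("gene"/"pseudo"/"ambiguous"), `log_odds`,
#'   `locus_posterior` (P(gene)), `n_informative`.
#' @export
assign_locus <- function(site_pos, alt_allele, alignments, map, q = 0.01,
                         threshold = 3, min_votes = 3L, expanded = NULL) {
  ex <- if (is.null(expanded)) expand_alignments(alignments) else expanded
  alt_reads <- unique(ex[ref_pos == site_pos & base == alt_allele, read_id])
  if (length(alt_reads) == 0)
    return(list(locus = "ambiguous", log_odds = 0, locus_posterior = 0.5,
                n_informative = 0L))
  psv <- as.data.table(map$psvs)
  setnames(psv, "gene_pos", "ref_pos")
  obs <- ex[read_id %in% alt_reads & ref_pos %in% psv$ref_pos]
  obs <- psv[obs, on = "ref_pos", nomatch = NULL]
  w <- log((1 - q) / q)
  obs[, vote := fifelse(base == gene_base, w,
                        fifelse(base == pseudo_base, -w, 0))]
  informative <- obs[vote != 0]
  n_inf <- length(unique(informative$read_id))
  lo <- sum(informative$vote)
  locus <- if (n_inf < min_votes || abs(lo) < threshold) "ambiguous"
  else if (lo > 0) "gene" else "pseudo"
  list(locus = locus, log_odds = lo,
       locus_posterior = 1 / (1 + exp(-lo)), n_informative = n_inf)
}

#' Scan a pileup for candidate variant sites and genotype them
#'
#' A column becomes a candidate when its strongest non-reference, non-PSV
#' signal (alt base, deletion support from short D ops, or insertion events)
#' reaches `min_alt_frac` at depth `>= min_depth`. PSV columns are expected
#' to sit at pseudo-base fraction ~0.5 under masking and are suppressed
#' unless the fraction departs from 0.5 by more than `psv_margin` (such
#' departures are copy-number signals, consumed by the CNV caller instead).
#' Deletion support from long D ops (`> max_small_del`) is excluded so
#' exon-scale deletion junctions are not mistaken for small indels.
#'
#' @param pu pileup table from [pileup()].
#' @param map a [derive_homology_map()] object.
#' @param alignments alignment table (for locus assignment votes).
#' @param min_alt_frac candidate threshold on the alt fraction (default
#'   0.12, an operating point that catches theta = 0.25 sites with high
#'   sensitivity at 100x).
#' @param min_depth minimum column depth.
#' @param epsilon sequencing error rate for genotyping.
#' @param psv_margin departure from 0.5 beyond which a PSV column is no
#'   longer treated as reference-state.
#' @param max_small_del deletion ops longer than this (bp) are CNV-scale and
#'   ignored here.
#' @param q,locus_threshold,locus_min_votes passed to [assign_locus()].
#' @return data.table of site calls: `pos`, `ref`, `alt`, `kind`,
#'   `alt_count`, `depth`, `region_type`, `map_label`, `theta_map`,
#'   `posterior`, `ambiguous`, `locus`, `locus_posterior`, `log_odds`.
#' @export
scan_candidates <- function(pu, map, alignments, min_alt_frac = 0.12,
                            min_depth = 20L, epsilon = 0.01,
                            psv_margin = 0.2, max_small_del = 50L,
                            q = 0.01, locus_threshold = 3,
                            locus_min_votes = 3L) {
  stopifnot(min_alt_frac > 0, min_depth > 0)
  pu <- as.data.table(pu)
  psv <- as.data.table(map$psvs)
  ex <- expand_alignments(alignments)

  # deletion support restricted to small D ops
  small_del <- del_support_by_op(alignments, max_small_del)
  pu <- merge(pu, small_del, by = "pos", all.x = TRUE)
  pu[is.na(small_del_n), small_del_n := 0L]

  ins_ev <- insertion_events(alignments)
  ins_n <- if (nrow(ins_ev)) ins_ev[, .(ins_n = .N), by = ref_pos] else
    data.table(ref_pos = integer(), ins_n = integer())
  pu <- merge(pu, ins_n, by.x = "pos", by.y = "ref_pos", all.x = TRUE)
  pu[is.na(ins_n), ins_n := 0L]

  # vectorised prefilter: strongest non-ref, non-PSV signal per column
  bc <- as.matrix(pu[, .(A, C, G, T)])
  bc[cbind(seq_len(nrow(pu)), match(pu$ref, DNA_BASES))] <- -1L
  psv_row <- match(pu$pos, psv$gene_pos)
  is_psv <- !is.na(psv_row)
  if (any(is_psv)) {
    pb <- psv$pseudo_base[psv_row[is_psv]]
    pseudo_n <- bc[cbind(which(is_psv), match(pb, DNA_BASES))]
    frac_pseudo <- pseudo_n / pmax(pu$depth[is_psv], 1L)
    quiet_psv <- abs(frac_pseudo - 0.5) <= psv_margin
    # PSV pseudo base never counts as an alt candidate
    bc[cbind(which(is_psv), match(pb, DNA_BASES))] <- -1L
    drop <- rep(FALSE, nrow(pu)); drop[which(is_psv)[quiet_psv]] <- TRUE
  } else drop <- rep(FALSE, nrow(pu))
  snv_count <- apply(bc, 1, max)
  alt_base_i <- apply(bc, 1, which.max)
  best_count <- pmax(snv_count, pu$small_del_n, pu$ins_n)
  cand <- which(!drop & pu$depth >= min_depth &
                  best_count / pmax(pu$depth, 1L) >= min_alt_frac)

  calls <- list()
  for (i in cand) {
    row <- pu[i]
    kind <- c("snv", "del", "ins")[
      which.max(c(snv_count[i], row$small_del_n, row$ins_n))]
    alt_count <- best_count[i]
    alt <- switch(kind,
                  snv = DNA_BASES[alt_base_i[i]],
                  del = "-",
                  ins = {
                    sq <- ins_ev[ref_pos == row$pos, ins_seq]
                    names(sort(table(sq), decreasing = TRUE))[1]
                  })
    region_type <- classify_region(row$pos, map)
    gt <- genotype_site(alt_count, row$depth, region_type, epsilon)
    la <- if (region_type == "unique")
      list(locus = "gene", locus_posterior = 1, log_odds = Inf)  # no paralog copy
    else assign_locus(row$pos,
                      if (kind == "snv") alt else "-",
                      alignments, map, q = q, threshold = locus_threshold,
                      min_votes = locus_min_votes, expanded = ex)
    if (kind == "ins" && region_type == "homology") {
      # insertion-bearing reads are identified by their I ops, not pileup base
      la <- assign_locus_for_reads(
        unique(ins_ev[ref_pos == row$pos, read_id]), ex, map, q,
        locus_threshold, locus_min_votes)
    }
    calls[[length(calls) + 1L]] <- data.table(
      pos = row$pos, ref = row$ref, alt = alt, kind = kind,
      alt_count = alt_count, depth = row$depth, region_type = region_type,
      map_label = gt$map_label, theta_map = gt$theta_map,
      posterior = gt$posterior, ambiguous = gt$ambiguous,
      locus = la$locus, locus_posterior = la$locus_posterior,
      log_odds = la$log_odds)
  }
  if (length(calls) == 0)
    return(data.table(pos = integer(), ref = character(), alt = character(),
                      kind = character(), alt_count = integer(),
                      depth = integer(), region_type = character(),
                      map_label = character(), theta_map = numeric(),
                      posterior = numeric(), ambiguous = logical(),
                      locus = character(), locus_posterior = numeric(),
                      log_odds = numeric()))
  out <- rbindlist(calls)
  # a k-bp deletion supports k adjacent columns; keep the leftmost
  is_del <- out$kind == "del"
  drop <- is_del & (out$pos - 1L) %in% out$pos[is_del]
  out[!drop]
}

# per-position deletion support counting only D ops <= max_len
del_support_by_op <- function(alignments, max_len) {
  a <- as.data.table(alignments)
  a <- a[!is.na(pos)]
  if (nrow(a) == 0) return(data.table(pos = integer(), small_del_n = integer()))
  a[, aidx := .I]
  toks <- parse_cigar_tokens(a$cigar)
  n_tok <- lengths(toks)
  seg <- data.table(
    aidx = rep(a$aidx, n_tok),
    op = sub("^\\d+", "", unlist(toks)),
    len = as.integer(sub("[MIDSH]$", "", unlist(toks))))
  seg[, r_adv := len * (op %in% c("M", "D"))]
  seg[, rstart := a$pos[aidx] + cumsum(r_adv) - r_adv, by = aidx]
  d <- seg[op == "D" & len <= max_len]
  if (nrow(d) == 0) return(data.table(pos = integer(), small_del_n = integer()))
  n <- d$len
  dt <- data.table(pos = rep(d$rstart, n) + sequence(n) - 1L)
  dt[, .(small_del_n = .N), by = pos]
}

assign_locus_for_reads <- function(read_ids, ex, map, q, threshold, min_votes) {
  if (length(read_ids) == 0)
    return(list(locus = "ambiguous", log_odds = 0, locus_posterior = 0.5,
                n_informative = 0L))
  psv <- as.data.table(map$psvs)
  setnames(psv, "gene_pos", "ref_pos")
  obs <- ex[read_id %in% read_ids & ref_pos %in% psv$ref_pos]
  obs <- psv[obs, on = "ref_pos", nomatch = NULL]
  w <- log((1 - q) / q)
  obs[, vote := fifelse(base == gene_base, w,
                        fifelse(base == pseudo_base, -w, 0))]
  informative <- obs[vote != 0]
  n_inf <- length(unique(informative$read_id))
  lo <- sum(informative$vote)
  locus <- if (n_inf < min_votes || abs(lo) < threshold) "ambiguous"
  else if (lo > 0) "gene" else "pseudo"
  list(locus = locus, log_odds = lo,
       locus_posterior = 1 / (1 + exp(-lo)), n_informative = n_inf)
}
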