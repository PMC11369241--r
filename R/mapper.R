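# Built-in seed-and-extend mapper. Exact k-mer seeds against the masked
# reference (k-mers containing 'N' are never indexed, so masked pseudogene
# placement is impossible), anchors chained by diagonal clustering, gaps
# between chained clusters emitted as CIGAR I/D ops. This is deliberately a
# small mapper for desk-scale references, not a general-purpose aligner.

#' Build the k-mer seed index for a (masked) reference
#'
#' Indexes every k-mer of the reference except those containing `N` (so
#' masked territory can never seed an alignment) and those occurring more
#' than `max_occ` times. Build once and pass to [map_reads()] when mapping
#' many read sets against the same reference.
#'
#' @param ref_seqs named character vector of reference sequences.
#' @param k seed length.
#' @param max_occ repetitive k-mer cutoff.
#' @return a data.table (`kmer`, `contig`, `rpos`) with attributes `k` and
#'   `max_occ`.
#' @export
build_kmer_index <- function(ref_seqs, k, max_occ = 8L) {
  dt <- kmer_index(ref_seqs, k, max_occ)
  setattr(dt, "k", k)
  setattr(dt, "max_occ", max_occ)
  dt
}

kmer_index <- function(ref_seqs, k, max_occ = 8L) {
  idx <- vector("list", length(ref_seqs))
  for (i in seq_along(ref_seqs)) {
    s <- ref_seqs[[i]]
    n <- nchar(s) - k + 1L
    if (n < 1) next
    starts <- seq_len(n)
    km <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    idx[[i]] <- data.table(kmer = km[keep], contig = names(ref_seqs)[i],
                           rpos = starts[keep])
  }
  dt <- rbindlist(idx)
  if (nrow(dt)) {
    dt[, n_occ := .N, by = kmer]
    dt <- dt[n_occ <= max_occ][, n_occ := NULL]
  }
  dt
}

n_mismatch <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Chain anchors (qpos, rpos) of one read into an alignment skeleton:
# diagonal clustering with tolerance `band`, greedy left-to-right cluster
# chaining, then a monotone anchor path. Returns NULL if unchainable.
chain_anchors <- function(qpos, rpos, k, band) {
  diag <- rpos - qpos
  o <- order(diag, qpos)
  qpos <- qpos[o]; rpos <- rpos[o]; diag <- diag[o]
  n <- length(qpos)
  brk <- which(c(TRUE, diff(diag) > band))
  cl_start <- brk
  cl_end <- c(brk[-1] - 1L, n)
  n_cl <- length(cl_start)
  support <- cl_end - cl_start + 1L
  qmin <- qmax <- rmin <- rmax <- integer(n_cl)
  for (i in seq_len(n_cl)) {
    sl <- cl_start[i]:cl_end[i]
    qmin[i] <- min(qpos[sl]); qmax[i] <- max(qpos[sl])
    rmin[i] <- min(rpos[sl]); rmax[i] <- max(rpos[sl])
  }
  # suppress 1-2 anchor noise clusters without discarding the short side of
  # a genuine junction chain (e.g. a read barely spanning a deletion)
  keep_min <- min(max(2L, min(ceiling(0.15 * max(support)), 4L)),
                  max(support))
  cand <- which(support >= keep_min)
  cand <- cand[order(qmin[cand], rmin[cand])]
  kept <- integer(0)
  prev_q <- -Inf; prev_r <- -Inf
  for (i in cand) {
    if (qmin[i] > prev_q - k + 1L && rmin[i] > prev_r - k + 1L &&
        rmin[i] >= prev_r - band) {
      kept <- c(kept, i)
      prev_q <- qmax[i]; prev_r <- rmax[i]
    }
  }
  if (length(kept) == 0) return(NULL)
  sel <- unlist(lapply(kept, function(i) cl_start[i]:cl_end[i]))
  q <- qpos[sel]; r <- rpos[sel]
  o <- order(q, r)
  q <- q[o]; r <- r[o]
  keep <- !logical(length(q))
  last_q <- q[1]; last_r <- r[1]
  for (i in seq_along(q)[-1]) {
    if (q[i] > last_q && r[i] > last_r &&
        (r[i] - last_r) - (q[i] - last_q) > -band) {
      last_q <- q[i]; last_r <- r[i]
    } else keep[i] <- FALSE
  }
  q <- q[keep]; r <- r[keep]

  # walk anchor starts, emitting M between starts and I/D at diagonal shifts
  nq <- length(q)
  ops <- character(2L * nq + 1L); lens <- integer(2L * nq + 1L)
  n_op <- 0L
  add_op <- function(op, len) {
    if (len <= 0L) return()
    if (n_op > 0L && ops[n_op] == op) lens[n_op] <<- lens[n_op] + len
    else { n_op <<- n_op + 1L; ops[n_op] <<- op; lens[n_op] <<- len }
  }
  if (nq > 1L) for (i in 2:nq) {
    dq <- q[i] - q[i - 1L]; dr <- r[i] - r[i - 1L]
    add_op("M", min(dq, dr))
    if (dr > dq) add_op("D", dr - dq)
    if (dq > dr) add_op("I", dq - dr)
  }
  add_op("M", k)  # the final anchor itself
  list(q1 = q[1], r1 = r[1], ops = ops[seq_len(n_op)],
       lens = lens[seq_len(n_op)])
}

# How far an ungapped extension may run (integer-coded sequences): the
# extension must stay locally homologous — at most 3 mismatches in any
# 8-base window — and never end on a mismatch. Unrelated sequence beyond a
# homology boundary (~75% mismatch) stops within a base or two, while runs
# of nearby PSVs (legitimate paralog differences) pass.
ext_walk <- function(a, b) {
  n <- length(a)
  if (n == 0L) return(0L)
  d <- a != b
  lim <- n
  if (n >= 8L) {
    ws <- cumsum(as.integer(d))
    win <- ws[8:n] - c(0L, ws[seq_len(n - 8L)])
    bad <- which(win > 3L)
    if (length(bad)) lim <- bad[1] - 1L  # stop before the offending window
  } else if (sum(d) > 3L) {
    lim <- 0L
  }
  while (lim > 0L && d[lim]) lim <- lim - 1L
  lim
}

N_INT <- utf8ToInt("N")

finish_alignment <- function(sk, iseq, iref, read_len, ref_len) {
  ops <- sk$ops; lens <- sk$lens
  pos <- sk$r1       # ref position of the first aligned op
  qstart <- sk$q1    # read position of the first aligned op

  # (1) refine every indel junction: the split point between the M runs
  # flanking an I/D op is only anchor-resolution accurate, which would smear
  # the bases between the true event and its op over the wrong columns.
  # Rescan shifts of the junction and keep the best-matching placement
  # (leftmost on ties).
  if (length(ops) >= 3L) {
    rcur <- pos; qcur <- qstart
    for (i in seq_along(ops)) {
      if (ops[i] %in% c("I", "D") && i > 1L && i < length(ops) &&
          ops[i - 1L] == "M" && ops[i + 1L] == "M") {
        L <- lens[i]
        qL <- if (ops[i] == "I") L else 0L  # read bases the op consumes
        rL <- if (ops[i] == "D") L else 0L  # ref bases the op consumes
        w_cap <- if (max(rL, qL) >= 30L) 60L else 15L
        w <- min(w_cap, lens[i - 1L] - 1L, lens[i + 1L] - 1L)
        if (w >= 1L) {
          sc <- rep(-1L, 2L * w + 1L)
          for (ci in seq_along(sc)) {
            s <- ci - w - 1L
            lq <- qcur + s - w; lr <- rcur + s - w
            rq <- qcur + qL + s; rr <- rcur + rL + s
            if (lq < 1L || lr < 1L || rq + w - 1L > read_len ||
                rr + w - 1L > ref_len) next
            sc[ci] <- sum(iseq[lq:(lq + w - 1L)] == iref[lr:(lr + w - 1L)]) +
              sum(iseq[rq:(rq + w - 1L)] == iref[rr:(rr + w - 1L)])
          }
          best <- which.max(sc) - w - 1L
          if (best != 0L && sc[best + w + 1L] >= 0L) {
            lens[i - 1L] <- lens[i - 1L] + best
            lens[i + 1L] <- lens[i + 1L] - best
            qcur <- qcur + best; rcur <- rcur + best
          }
        }
      }
      if (ops[i] %in% c("M", "I")) qcur <- qcur + lens[i]
      if (ops[i] %in% c("M", "D")) rcur <- rcur + lens[i]
    }
  }

  # (2) a chain must not jump a masked gap: a D op whose reference interval
  # contains N joins two placements that cannot belong to one locus; keep
  # the side with more aligned bases and clip the rest
  repeat {
    rcur <- pos
    bad <- 0L
    for (i in seq_along(ops)) {
      if (ops[i] == "D" &&
          any(iref[rcur:(rcur + lens[i] - 1L)] == N_INT)) {
        bad <- i; break
      }
      if (ops[i] %in% c("M", "D")) rcur <- rcur + lens[i]
    }
    if (bad == 0L) break
    left_m <- sum(lens[seq_len(bad - 1L)][ops[seq_len(bad - 1L)] == "M"])
    right_m <- sum(lens[-seq_len(bad)][ops[-seq_len(bad)] == "M"])
    if (left_m >= right_m) {
      ops <- ops[seq_len(bad - 1L)]; lens <- lens[seq_len(bad - 1L)]
    } else {
      r_adv <- sum(lens[seq_len(bad)][ops[seq_len(bad)] %in% c("M", "D")])
      q_adv <- sum(lens[seq_len(bad)][ops[seq_len(bad)] %in% c("M", "I")])
      pos <- pos + r_adv
      qstart <- qstart + q_adv
      ops <- ops[-seq_len(bad)]; lens <- lens[-seq_len(bad)]
    }
    if (length(ops) == 0L) return(NULL)
  }

  # (3) leading extension, walked outward from the first anchor
  lead_q <- qstart - 1L
  lead_max <- min(lead_q, pos - 1L)
  lead <- if (lead_max > 0) {
    ext_walk(rev(iseq[(qstart - lead_max):(qstart - 1L)]),
             rev(iref[(pos - lead_max):(pos - 1L)]))
  } else 0L
  pos <- pos - lead
  if (lead > 0) {
    if (ops[1] == "M") lens[1] <- lens[1] + lead
    else { ops <- c("M", ops); lens <- c(lead, lens) }
  }
  clip5 <- lead_q - lead
  # (4) trailing extension
  q_end <- qstart - lead + sum(lens[ops %in% c("M", "I")]) - 1L
  r_end <- pos + sum(lens[ops %in% c("M", "D")]) - 1L
  tail_q <- read_len - q_end
  tail_max <- min(tail_q, ref_len - r_end)
  tail_ext <- if (tail_max > 0)
    ext_walk(iseq[(q_end + 1L):(q_end + tail_max)],
             iref[(r_end + 1L):(r_end + tail_max)])
  else 0L
  if (tail_ext > 0) {
    n <- length(ops)
    if (ops[n] == "M") lens[n] <- lens[n] + tail_ext
    else { ops <- c(ops, "M"); lens <- c(lens, tail_ext) }
  }
  clip3 <- tail_q - tail_ext
  if (clip5 > 0) { ops <- c("S", ops); lens <- c(clip5, lens) }
  if (clip3 > 0) { ops <- c(ops, "S"); lens <- c(lens, clip3) }

  # mismatch count over M blocks
  nm <- 0L
  qcur <- 1L; rcur <- pos
  for (i in seq_along(ops)) {
    li <- lens[i]
    if (ops[i] == "M") {
      nm <- nm + sum(iseq[qcur:(qcur + li - 1L)] !=
                       iref[rcur:(rcur + li - 1L)])
      qcur <- qcur + li; rcur <- rcur + li
    } else if (ops[i] == "S") {
      qcur <- qcur + li
    } else if (ops[i] == "I") {
      qcur <- qcur + li; nm <- nm + li
    } else {
      rcur <- rcur + li
    }
  }
  n_m <- sum(lens[ops == "M"])
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""),
       nm = as.integer(nm), n_m = n_m,
       score = n_m - 2L * as.integer(nm) - 4L * sum(ops %in% c("I", "D")))
}

#' Map reads to a (masked) reference with the built-in toy mapper
#'
#' Seed-and-extend: exact k-mer anchors against the reference, diagonal
#' clustering with tolerance `band`, greedy cluster chaining, and CIGAR
#' emission with I/D ops at diagonal shifts (so a read spanning a deleted
#' interval yields one alignment containing a long D op). Both orientations
#' are tried; the one with more anchor hits wins; equal-scoring placements
#' resolve to the leftmost position. Reads that cannot be anchored are
#' returned with `pos = NA`, never dropped.
#'
#' @param reads a `read_set` (only `read_id` and `seq` are used) or a
#'   character vector of sequences.
#' @param ref_seqs named character vector of (masked) reference sequences.
#' @param k seed length (>= 11).
#' @param band diagonal clustering tolerance (bp); also the largest indel
#'   drift tolerated inside one cluster.
#' @param step anchor sampling stride along the read (default `k`, i.e.
#'   abutting anchors; lower it for very high error rates).
#' @param max_occ k-mers occurring more often than this in the reference are
#'   not used as anchors.
#' @param index optional precomputed [build_kmer_index()] for `ref_seqs`
#'   (must have been built with the same `k`).
#' @return data.table with columns `read_id`, `contig`, `pos` (1-based
#'   leftmost), `mapq`, `cigar`, `strand`, `seq` (oriented as aligned),
#'   `nm`, `score`, `is_supplementary`.
#' @export
map_reads <- function(reads, ref_seqs, k = 13L, band = 40L, step = NULL,
                      max_occ = 8L, index = NULL) {
  stopifnot(k >= 11)
  if (is.null(step)) step <- k
  if (is.character(reads)) {
    reads <- data.table(read_id = paste0("r", seq_along(reads)), seq = reads)
  }
  rd_id <- reads$read_id
  rd_seq <- reads$seq
  rd_rc <- revcomp(rd_seq)
  lens <- nchar(rd_seq)
  n_reads <- length(rd_seq)
  if (is.null(index)) {
    idx <- kmer_index(ref_seqs, k, max_occ)
  } else {
    if (attr(index, "k") != k)
      stop("index was built with k = ", attr(index, "k"),
           " but map_reads was called with k = ", k)
    idx <- index
  }

  anchor_tbl <- function(seqs, strand) {
    n_off <- pmax(0L, ((nchar(seqs) - k) %/% step) + 1L)
    if (sum(n_off) == 0) return(NULL)
    ridx <- rep(seq_along(seqs), n_off)
    qpos <- (sequence(n_off) - 1L) * step + 1L
    data.table(ridx = ridx, strand = strand, qpos = qpos,
               kmer = substring(seqs[ridx], qpos, qpos + k - 1L))
  }
  qk <- rbindlist(list(anchor_tbl(rd_seq, "+"), anchor_tbl(rd_rc, "-")))
  hits <- if (nrow(idx) && !is.null(qk) && nrow(qk))
    idx[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  else data.table()

  # preallocated outputs
  o_pos <- rep(NA_integer_, n_reads); o_cigar <- rep(NA_character_, n_reads)
  o_strand <- rep(NA_character_, n_reads); o_contig <- rep(NA_character_, n_reads)
  o_mapq <- integer(n_reads); o_nm <- rep(NA_integer_, n_reads)
  o_score <- rep(NA_integer_, n_reads)

  if (nrow(hits)) {
    # best (strand, contig) per read by hit count; ties: "+" then first contig
    cnt <- hits[, .N, by = .(ridx, strand, contig)]
    setorder(cnt, ridx, -N, strand, contig)
    cnt <- cnt[!duplicated(ridx)]
    hits <- hits[cnt[, .(ridx, strand, contig)],
                 on = c("ridx", "strand", "contig"), nomatch = NULL]
    setorder(hits, ridx)
    ref_len_by <- vapply(ref_seqs, nchar, integer(1))

    # fast path: all anchors of a read on one diagonal and the full-length
    # placement inside the contig -> ungapped full-M alignment
    agg <- hits[, .(dmin = min(rpos - qpos), dmax = max(rpos - qpos),
                    n = .N, strand = strand[1], contig = contig[1]),
                by = ridx]
    agg[, len := lens[ridx]]
    agg[, pos0 := dmin + 1L]
    fast <- agg[dmin == dmax & pos0 >= 1L &
                  pos0 + len - 1L <= ref_len_by[contig]]
    if (nrow(fast)) {
      sq <- fifelse(fast$strand == "+", rd_seq[fast$ridx], rd_rc[fast$ridx])
      rf <- substring(unlist(ref_seqs[fast$contig], use.names = FALSE),
                      fast$pos0, fast$pos0 + fast$len - 1L)
      nm_v <- integer(nrow(fast))
      term_bad <- logical(nrow(fast))
      tw <- 12L  # terminal window: a mismatch pile-up there means the
                 # read's end hangs over a boundary the anchors cannot see
      for (j in seq_len(nrow(fast))) {
        d <- utf8ToInt(sq[j]) != utf8ToInt(rf[j])
        nm_v[j] <- sum(d)
        n <- length(d)
        w <- min(tw, n)
        term_bad[j] <- sum(d[seq_len(w)]) >= 4L ||
          sum(d[seq.int(n - w + 1L, n)]) >= 4L
      }
      keep_f <- !term_bad
      fast <- fast[keep_f]
      if (nrow(fast)) {
        fi <- fast$ridx
        o_pos[fi] <- fast$pos0
        o_cigar[fi] <- paste0(fast$len, "M")
        o_strand[fi] <- fast$strand
        o_contig[fi] <- fast$contig
        o_mapq[fi] <- fifelse(fast$n >= 2L, 60L, 20L)
        o_nm[fi] <- nm_v[keep_f]
        o_score[fi] <- fast$len - 2L * nm_v[keep_f]
      }
    }

    slow <- setdiff(unique(hits$ridx), fast$ridx)
    if (length(slow)) {
      iref_by <- lapply(ref_seqs, utf8ToInt)
      hits_slow <- hits[ridx %in% slow]
      h_ridx <- hits_slow$ridx; h_q <- hits_slow$qpos; h_r <- hits_slow$rpos
      h_strand <- hits_slow$strand; h_contig <- hits_slow$contig
      grp_end <- c(which(diff(h_ridx) != 0L), length(h_ridx))
      grp_start <- c(1L, head(grp_end, -1L) + 1L)
      for (g in seq_along(grp_start)) {
        sl <- grp_start[g]:grp_end[g]
        i <- h_ridx[sl[1]]
        ctg <- h_contig[sl[1]]
        seq_i <- if (h_strand[sl[1]] == "+") rd_seq[i] else rd_rc[i]
        sk <- chain_anchors(h_q[sl], h_r[sl], k, band)
        if (is.null(sk)) next
        fin <- finish_alignment(sk, utf8ToInt(seq_i), iref_by[[ctg]],
                                lens[i], ref_len_by[[ctg]])
        if (is.null(fin) || fin$n_m < k) next
        o_pos[i] <- fin$pos; o_cigar[i] <- fin$cigar
        o_strand[i] <- h_strand[sl[1]]; o_contig[i] <- ctg
        o_mapq[i] <- if (length(sl) >= 2L) 60L else 20L
        o_nm[i] <- fin$nm; o_score[i] <- fin$score
      }
    }
  }
  res <- data.table(
    read_id = rd_id, contig = o_contig, pos = o_pos, mapq = o_mapq,
    cigar = o_cigar, strand = o_strand,
    seq = ifelse(is.na(o_strand) | o_strand == "+", rd_seq, rd_rc),
    nm = o_nm, score = o_score, is_supplementary = FALSE)
  setorder(res, contig, pos, read_id, na.last = TRUE)
  res[]
}
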