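#' Find unique exact-match anchors between two genomes
#'
#' Anchors are maximal exact matches seeded by k-mers whose canonical form
#' occurs exactly once in each genome, both strands considered. Repeated
#' sequence (TE families, satellite arrays) carries no unique k-mers and is
#' therefore anchor-free, which is what makes "fails to align uniquely"
#' fall out of the block construction without a masking step.
#'
#' @param refG,qryG Genome states or named character vectors of chromosome
#'   sequences.
#' @param k Odd k-mer size >= 11 (default 21).
#' @return data.table of anchors: `ref_chrom`, `ref_start`, `ref_end`,
#'   `qry_chrom`, `qry_start`, `qry_end`, `strand` (+1/-1), sorted by
#'   reference coordinate. Coordinates 0-based half-open.
#' @export
find_anchors <- function(refG, qryG, k = 21L) {
  if (k %% 2L == 0L || k < 11L) stop("'k' must be an odd integer >= 11")
  rs <- genome_seqs(refG)
  qs <- genome_seqs(qryG)
  a <- data.table::as.data.table(cpp_find_anchors(unname(rs), unname(qs), k))
  out <- data.table::data.table(
    ref_chrom = names(rs)[a$ref_chrom_i], ref_start = a$ref_start,
    ref_end = a$ref_end, qry_chrom = names(qs)[a$qry_chrom_i],
    qry_start = a$qry_start, qry_end = a$qry_end, strand = a$strand)
  data.table::setorderv(out, c("ref_chrom", "ref_start", "ref_end"))
  out
}

genome_seqs <- function(g) {
  if (is.list(g) && !is.null(g$seq)) unlist(g$seq)
  else if (is.character(g) && !is.null(names(g))) g
  else stop("expected a genome state or a named character vector of sequences")
}

#' Chain anchors into collinear synteny blocks
#'
#' Successive anchors join the same block when they share query chromosome,
#' orientation and monotone coordinates, and both the reference and query
#' gaps are at most `max_gap`. Blocks spanning less than `min_block` bp of
#' reference are discarded; residual overlaps between adjacent block
#' extents (from anchor extension through shared sequence) are clipped at
#' the midpoint so blocks partition cleanly.
#'
#' @param anchors From [find_anchors()].
#' @param max_gap Maximum within-block gap (bp, default 20000).
#' @param min_block Minimum block span on the reference (bp, default 1000).
#' @return data.table of blocks with a `block_id` column, plus the input
#'   anchors annotated by block in `attr(, "anchors")`.
#' @export
chain_anchors <- function(anchors, max_gap = 20000L, min_block = 1000L) {
  a <- data.table::as.data.table(anchors)
  if (!nrow(a)) {
    b <- data.table::data.table(block_id = integer(), ref_chrom = character(),
      ref_start = numeric(), ref_end = numeric(), qry_chrom = character(),
      qry_start = numeric(), qry_end = numeric(), strand = integer(),
      n_anchors = integer(), anchored_bp = numeric())
    data.table::setattr(b, "anchors", a)
    return(b)
  }
  a <- unique(a)    # seed runs can extend to identical maximal matches
  data.table::setorderv(a, c("ref_chrom", "ref_start", "ref_end"))
  # Remove anchors whose diagonal deviates far from the local running
  # median of their (chromosome pair, strand) group: clustered k-mer
  # matches between different copies of a repeat family link distant loci
  # and would otherwise shatter the chains through euchromatin.
  a$diag <- ifelse(a$strand == 1L, a$qry_start - a$ref_start,
                   a$qry_start + a$ref_start)
  grp <- paste(a$ref_chrom, a$qry_chrom, a$strand)
  ok <- rep(TRUE, nrow(a))
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) < 5L) next
    win <- min(9L, length(i) - (1L - length(i) %% 2L))
    med <- stats::runmed(a$diag[i], win, endrule = "median")
    ok[i] <- abs(a$diag[i] - med) <= max_gap
  }
  a <- a[ok, ]
  # Isolated anchors that contradict both neighbours are k-mer matches
  # between different repeat copies, not homology: drop them when the
  # flanking anchors chain through without them (one-anchor lookahead).
  consistent <- function(p, n) {
    if (is.na(p[1])) return(FALSE)
    if (p[1] != n[1] || p[4] != n[4] || p[7] != n[7]) return(FALSE)
    rgap <- n[2] - p[3]
    qgap <- if (n[7] == 1L) n[5] - p[6] else p[5] - n[6]
    if (rgap > max_gap || qgap > max_gap) return(FALSE)
    # equal negative gaps = same diagonal: anchors extended through a
    # repeat with no unique seeds; that is one collinear run, not a break
    (rgap >= -200 && qgap >= -200) || rgap == qgap
  }
  am <- cbind(as.integer(factor(a$ref_chrom)), a$ref_start, a$ref_end,
              as.integer(factor(a$qry_chrom, levels = unique(c(a$qry_chrom)))),
              a$qry_start, a$qry_end, a$strand)
  n_a <- nrow(am)
  block <- integer(n_a)
  keep <- rep(TRUE, n_a)
  cur <- 0L
  tail_i <- NA_integer_
  i <- 1L
  while (i <= n_a) {
    tl <- if (is.na(tail_i)) rep(NA_real_, 7) else am[tail_i, ]
    if (consistent(tl, am[i, ])) {
      block[i] <- cur
      tail_i <- i
    } else if (!is.na(tail_i) && i < n_a && consistent(tl, am[i + 1L, ]) &&
               am[i, 3] - am[i, 2] < 200) {
      keep[i] <- FALSE     # short isolated outlier: a repeat cross-match
    } else {
      cur <- cur + 1L
      block[i] <- cur
      tail_i <- i
    }
    i <- i + 1L
  }
  a <- a[keep, ]
  a$block_id <- block[keep]
  # within each block keep the maximum-weight collinear subchain (weighted
  # longest increasing subsequence on query position): residual repeat
  # cross-matches inside a block would corrupt projection and identity
  keep2 <- rep(TRUE, nrow(a))
  for (bid in unique(a$block_id)) {
    idx <- which(a$block_id == bid)
    if (length(idx) < 3L) next
    q <- if (a$strand[idx[1]] == 1L) a$qry_start[idx] else -a$qry_start[idx]
    keep2[idx] <- cpp_wlis(q, a$ref_end[idx] - a$ref_start[idx])
  }
  a <- a[keep2, ]
  summarize_blocks <- function(a) {
    a[, list(ref_chrom = ref_chrom[1],
             ref_start = min(ref_start), ref_end = max(ref_end),
             qry_chrom = qry_chrom[1],
             qry_start = min(qry_start), qry_end = max(qry_end),
             strand = strand[1], n_anchors = .N,
             anchored_bp = sum(ref_end - ref_start)),
      by = "block_id"]
  }
  b <- summarize_blocks(a)

  # Reunite neighbouring blocks that a cluster of repeat cross-matches
  # split apart: merge consecutive blocks that are mutually collinear, and
  # drop a thinly-anchored interloper whose removal makes its neighbours
  # collinear (such a sliver is a repeat-family artefact, not synteny).
  block_pair_ok <- function(p, n) {
    p$ref_chrom == n$ref_chrom && p$qry_chrom == n$qry_chrom &&
      p$strand == n$strand &&
      {
        rgap <- n$ref_start - p$ref_end
        qgap <- if (n$strand == 1L) n$qry_start - p$qry_end
                else p$qry_start - n$qry_end
        rgap <= max_gap && rgap >= -200 && qgap <= max_gap && qgap >= -200
      }
  }
  thin <- 1000
  for (pass in 1:6) {
    data.table::setorderv(b, c("ref_chrom", "ref_start"))
    changed <- FALSE
    # drop runs of thinly-anchored blocks sandwiched between collinear
    # well-anchored neighbours
    big_idx <- which(b$anchored_bp >= thin)
    drop_ids <- integer(0)
    if (length(big_idx) >= 2L) {
      for (x in seq_len(length(big_idx) - 1L)) {
        p <- big_idx[x]; n <- big_idx[x + 1L]
        if (n - p < 2L) next
        if (b$ref_chrom[p] != b$ref_chrom[n]) next
        run <- (p + 1L):(n - 1L)
        if (!all(b$anchored_bp[run] < thin)) next   # only thin runs are noise
        if (block_pair_ok(b[p, ], b[n, ]))
          drop_ids <- c(drop_ids, b$block_id[run])
      }
    }
    if (length(drop_ids)) {
      a <- a[!a$block_id %in% drop_ids, ]
      b <- summarize_blocks(a)
      data.table::setorderv(b, c("ref_chrom", "ref_start"))
      changed <- TRUE
    }
    # merge consecutive collinear blocks
    i <- 2L
    while (i <= nrow(b)) {
      if (block_pair_ok(b[i - 1L, ], b[i, ])) {
        a$block_id[a$block_id == b$block_id[i]] <- b$block_id[i - 1L]
        b <- summarize_blocks(a)
        data.table::setorderv(b, c("ref_chrom", "ref_start"))
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed) break
  }
  # merged blocks can need a final monotonicity pass
  keep3 <- rep(TRUE, nrow(a))
  data.table::setorderv(a, c("ref_chrom", "ref_start", "ref_end"))
  for (bid in unique(a$block_id)) {
    idx <- which(a$block_id == bid)
    if (length(idx) < 3L) next
    q <- if (a$strand[idx[1]] == 1L) a$qry_start[idx] else -a$qry_start[idx]
    keep3[idx] <- cpp_wlis(q, a$ref_end[idx] - a$ref_start[idx])
  }
  a <- a[keep3, ]
  b <- summarize_blocks(a)
  # span and anchor-weight floors: spans below min_block, and blocks with
  # almost no anchored sequence (repeat-noise slivers), are dropped
  b <- b[b$ref_end - b$ref_start >= min_block & b$anchored_bp >= 200, ]
  a <- a[a$block_id %in% b$block_id, ]

  # clip residual overlaps so block extents are pairwise disjoint per
  # genome: sweeping in coordinate order, a later block yields to the
  # running maximum end of the earlier ones
  clip <- function(b, cs, ss, es) {
    data.table::setorderv(b, c(cs, ss))
    run_end <- -Inf; run_chrom <- ""
    for (i in seq_len(nrow(b))) {
      if (b[[cs]][i] != run_chrom) { run_chrom <- b[[cs]][i]; run_end <- -Inf }
      if (b[[ss]][i] < run_end)
        data.table::set(b, i, ss, min(run_end, b[[es]][i]))
      run_end <- max(run_end, b[[es]][i])
    }
    b
  }
  b <- clip(b, "ref_chrom", "ref_start", "ref_end")
  b <- clip(b, "qry_chrom", "qry_start", "qry_end")
  # a block swallowed by its neighbours on either side degenerates: drop it
  b <- b[b$ref_end - b$ref_start >= min_block & b$qry_end > b$qry_start, ]
  a <- a[a$block_id %in% b$block_id, ]
  data.table::setorderv(b, c("ref_chrom", "ref_start"))
  old_id <- b$block_id
  b$block_id <- seq_len(nrow(b))
  a$block_id <- b$block_id[match(a$block_id, old_id)]
  data.table::setattr(b, "anchors", a)
  b
}

#' Build a pairwise alignment map
#'
#' Runs [find_anchors()] and [chain_anchors()] and assembles the
#' `alignment_map` used by every downstream module: blocks, per-block
#' anchors, and the unaligned intervals of both genomes (the complement of
#' block extents plus the unbalanced excess of within-block gaps, which is
#' where species-specific insertions live).
#'
#' @inheritParams find_anchors
#' @inheritParams chain_anchors
#' @return An object of class `alignment_map`.
#' @export
build_map <- function(refG, qryG, k = 21L, max_gap = 20000L, min_block = 1000L) {
  rs <- genome_seqs(refG)
  qs <- genome_seqs(qryG)
  anchors <- find_anchors(rs, qs, k)
  blocks <- chain_anchors(anchors, max_gap = max_gap, min_block = min_block)
  a <- attr(blocks, "anchors")
  map <- structure(list(
    blocks = blocks, anchors = a,
    ref_len = vapply(rs, nchar, numeric(1)),
    qry_len = vapply(qs, nchar, numeric(1)),
    ref_seq = rs, qry_seq = qs,
    k = k, max_gap = max_gap, min_block = min_block
  ), class = "alignment_map")
  map$unaligned <- .unaligned_intervals(map)
  map
}

#' @export
print.alignment_map <- function(x, ...) {
  cat("alignment_map:", nrow(x$blocks), "blocks,",
      nrow(x$anchors), "anchors (k =", x$k, ")\n")
  s <- summarize_alignment(x, identity = FALSE)
  cat(sprintf("  aligned fraction: ref %.3f, qry %.3f\n",
              s$ref_aligned_fraction, s$qry_aligned_fraction))
  invisible(x)
}

# gap table: one row per consecutive anchor pair within a block
.block_gaps <- function(map) {
  a <- data.table::as.data.table(map$anchors)
  data.table::setorderv(a, c("block_id", "ref_start"))
  prev <- a[c(NA_integer_, seq_len(nrow(a) - 1L)), ]
  same <- !is.na(prev$block_id) & a$block_id == prev$block_id
  g <- data.table::data.table(
    block_id = a$block_id, ref_chrom = a$ref_chrom, qry_chrom = a$qry_chrom,
    strand = a$strand,
    rstart = prev$ref_end, rlen = a$ref_start - prev$ref_end,
    qstart = ifelse(a$strand == 1L, prev$qry_end, a$qry_end),
    qlen = ifelse(a$strand == 1L, a$qry_start - prev$qry_end,
                  prev$qry_start - a$qry_end))[same, ]
  g[g$rlen > 0 | g$qlen > 0, ]
}

# within-block unbalanced gap excess > 50 bp counts as unaligned sequence
.unaligned_intervals <- function(map, min_excess = 50L) {
  b <- map$blocks
  comp <- function(lens, chrom_col, s_col, e_col) {
    out <- list()
    for (ch in names(lens)) {
      bb <- b[b[[chrom_col]] == ch, ]
      ir <- IRanges::IRanges(start = bb[[s_col]] + 1L, end = bb[[e_col]])
      gap <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(lens[[ch]])),
                              IRanges::reduce(ir))
      if (length(gap))
        out[[ch]] <- data.table::data.table(chrom = ch,
                                            start = IRanges::start(gap) - 1,
                                            end = as.numeric(IRanges::end(gap)),
                                            where = "between")
    }
    data.table::rbindlist(out)
  }
  ref_un <- comp(map$ref_len, "ref_chrom", "ref_start", "ref_end")
  qry_un <- comp(map$qry_len, "qry_chrom", "qry_start", "qry_end")

  g <- .block_gaps(map)
  if (nrow(g)) {
    ex <- g[abs(g$rlen - g$qlen) > min_excess, ]
    if (nrow(ex)) {
      ref_side <- ex[ex$rlen > ex$qlen, ]
      qry_side <- ex[ex$qlen > ex$rlen, ]
      if (nrow(ref_side))
        ref_un <- rbind(ref_un, data.table::data.table(
          chrom = ref_side$ref_chrom,
          start = ref_side$rstart + floor(pmin(ref_side$rlen, ref_side$qlen) / 2),
          end = ref_side$rstart + floor(pmin(ref_side$rlen, ref_side$qlen) / 2) +
            (ref_side$rlen - ref_side$qlen),
          where = "within"))
      if (nrow(qry_side))
        qry_un <- rbind(qry_un, data.table::data.table(
          chrom = qry_side$qry_chrom,
          start = qry_side$qstart + floor(pmin(qry_side$rlen, qry_side$qlen) / 2),
          end = qry_side$qstart + floor(pmin(qry_side$rlen, qry_side$qlen) / 2) +
            (qry_side$qlen - qry_side$rlen),
          where = "within"))
    }
  }
  list(ref = ref_un, qry = qry_un)
}

#' Whole-genome alignment summary
#'
#' Reports the fraction of each genome that aligns uniquely (bp inside
#' blocks minus the unbalanced within-block gap excess, over genome bp) and
#' the length-weighted mean block identity. Identity is computed from exact
#' anchors plus alignment of the inter-anchor gap sequences: equal-length
#' gaps are compared position-wise; small unequal gaps (both sides <= 2 kb)
#' are globally aligned; larger unbalanced gaps count as unaligned.
#'
#' @param map An `alignment_map` from [build_map()].
#' @param identity Set `FALSE` to skip the identity computation.
#' @return List: `ref_aligned_fraction`, `qry_aligned_fraction`,
#'   `mean_block_identity`, `block_identity` (per block).
#' @export
summarize_alignment <- function(map, identity = TRUE) {
  stopifnot(inherits(map, "alignment_map"))
  b <- map$blocks
  un <- map$unaligned
  block_bp <- function(chrom_col, s_col, e_col, side) {
    inb <- sum(b[[e_col]] - b[[s_col]])
    within <- un[[side]]
    inb - if (nrow(within)) sum(within[within$where == "within", ]$end -
                                  within[within$where == "within", ]$start) else 0
  }
  res <- list(
    ref_aligned_fraction = block_bp("ref_chrom", "ref_start", "ref_end", "ref") /
      sum(map$ref_len),
    qry_aligned_fraction = block_bp("qry_chrom", "qry_start", "qry_end", "qry") /
      sum(map$qry_len))
  if (!identity) return(res)

  g <- .block_gaps(map)
  per_block <- data.table::data.table(block_id = b$block_id,
                                      matches = b$anchored_bp,
                                      cols = b$anchored_bp)
  if (nrow(g)) {
    eq <- g[g$rlen == g$qlen & g$rlen > 0, ]
    if (nrow(eq)) {
      eq$mm <- NA_real_
      for (key in unique(paste(eq$ref_chrom, eq$qry_chrom))) {
        sel <- paste(eq$ref_chrom, eq$qry_chrom) == key
        e2 <- eq[sel, ]
        eq$mm[sel] <- cpp_count_mismatches(map$ref_seq[[e2$ref_chrom[1]]],
                                           map$qry_seq[[e2$qry_chrom[1]]],
                                           e2$rstart, e2$qstart, e2$rlen,
                                           e2$strand)
      }
      agg <- eq[, list(matches = sum(rlen - mm), cols = sum(rlen)),
                by = "block_id"]
      i <- match(agg$block_id, per_block$block_id)
      per_block$matches[i] <- per_block$matches[i] + agg$matches
      per_block$cols[i] <- per_block$cols[i] + agg$cols
    }
    uneq <- g[g$rlen != g$qlen & g$rlen >= 1 & g$qlen >= 1 &
                pmax(g$rlen, g$qlen) <= 2000, ]
    for (i in seq_len(nrow(uneq))) {
      u <- uneq[i, ]
      rseq <- substr(map$ref_seq[[u$ref_chrom]], u$rstart + 1L, u$rstart + u$rlen)
      qseq <- substr(map$qry_seq[[u$qry_chrom]], u$qstart + 1L, u$qstart + u$qlen)
      if (u$strand == -1L) qseq <- revcomp_chr(qseq)
      al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rseq),
                                          Biostrings::DNAString(qseq),
                                          type = "global")
      j <- match(u$block_id, per_block$block_id)
      per_block$matches[j] <- per_block$matches[j] + Biostrings::nmatch(al)
      per_block$cols[j] <- per_block$cols[j] + max(u$rlen, u$qlen)
    }
  }
  per_block$identity <- ifelse(per_block$cols > 0,
                               per_block$matches / per_block$cols, NA_real_)
  res$block_identity <- per_block
  res$mean_block_identity <- sum(per_block$matches) / sum(per_block$cols)
  res
}

#' Project a reference interval through an alignment map
#'
#' Returns the orientation-corrected image of the interval under every
#' overlapping block, interpolating between anchors; unaligned positions
#' have no image. Intervals spanning multiple blocks come back as several
#' partial images flagged `split`.
#'
#' @param map An `alignment_map`.
#' @param chrom,start,end Interval (0-based half-open) in the `from` frame.
#' @param from `"ref"` (default) to project reference -> query, `"qry"` for
#'   the reverse.
#' @return data.table of images: `chrom`, `start`, `end`, `strand`
#'   (+1/-1), `block_id`, `covered` (bp of the source interval covered),
#'   `split` (logical). Zero rows when the interval is wholly unaligned.
#' @export
project_interval <- function(map, chrom, start, end, from = c("ref", "qry")) {
  from <- match.arg(from)
  lens <- if (from == "ref") map$ref_len else map$qry_len
  if (!chrom %in% names(lens)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > lens[[chrom]] || start > end)
    stop("interval outside chromosome bounds")
  b <- map$blocks
  cs <- paste0(from, "_chrom"); ss <- paste0(from, "_start"); es <- paste0(from, "_end")
  hit <- b[b[[cs]] == chrom & b[[ss]] < end & b[[es]] > start, ]
  if (!nrow(hit)) return(data.table::data.table(
    chrom = character(), start = numeric(), end = numeric(), strand = integer(),
    block_id = integer(), covered = numeric(), split = logical()))
  out <- vector("list", nrow(hit))
  for (i in seq_len(nrow(hit))) {
    blk <- hit[i, ]
    s <- max(start, blk[[ss]]); e <- min(end, blk[[es]])
    pr <- .block_projector(map, blk$block_id, from)
    p1 <- pr(s); p2 <- pr(e)
    out[[i]] <- data.table::data.table(
      chrom = if (from == "ref") blk$qry_chrom else blk$ref_chrom,
      start = min(p1, p2), end = max(p1, p2), strand = blk$strand,
      block_id = blk$block_id, covered = e - s,
      split = nrow(hit) > 1L || s > start || e < end)
  }
  data.table::rbindlist(out)
}

.block_projector <- function(map, block_id, from) {
  sel <- map$anchors$block_id == block_id   # plain vector: no column capture
  a <- map$anchors[sel, ]
  if (from == "ref") {
    x <- c(rbind(a$ref_start, a$ref_end))
    y <- if (a$strand[1] == 1L) c(rbind(a$qry_start, a$qry_end))
         else c(rbind(a$qry_end, a$qry_start))
  } else {
    x <- c(rbind(a$qry_start, a$qry_end))
    y <- if (a$strand[1] == 1L) c(rbind(a$ref_start, a$ref_end))
         else c(rbind(a$ref_end, a$ref_start))
  }
  o <- order(x)
  x <- x[o]; y <- y[o]
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  function(pos) stats::approx(x, y, xout = pos, rule = 2, ties = "ordered")$y
}
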