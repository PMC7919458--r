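#' Detect duplications from a pairwise alignment map
#'
#' A reference interval that fails to align uniquely (no unique anchors)
#' but whose sequence has two or more disjoint high-identity images in the
#' query is called a duplication that arose in the query lineage. Candidate
#' intervals are the inter-anchor and between-block reference gaps of at
#' least `min_len` bp; images are found by k-mer matching with
#' multiplicity, clustered by diagonal, and filtered by coverage and by a
#' diagonal identity estimate. Copies on one chromosome within
#' `tandem_gap` bp are tandem; anything else is dispersed.
#'
#' @param map An `alignment_map` (reference = ancestral-state genome).
#' @param min_len Minimum duplication length (default 100 bp).
#' @param tandem_gap Maximum copy spacing for the tandem arrangement
#'   (default 10 kb).
#' @param min_identity Minimum estimated identity of an image (default 0.9).
#' @param min_cov Minimum fraction of the candidate covered by an image's
#'   k-mer hits (default 0.5).
#' @param max_candidate Candidates longer than this are skipped (default
#'   50 kb; such regions are satellite-scale, not gene-scale duplications).
#' @return data.table of calls: `chrom`, `start`, `end` (reference frame),
#'   `copies`, `arrangement`, `qry_chroms`, `qry_starts`, `qry_ends`.
#' @export
detect_duplications <- function(map, min_len = 100L, tandem_gap = 10000L,
                                min_identity = 0.9, min_cov = 0.5,
                                max_candidate = 50000L) {
  cand <- .dup_candidates(map, min_len, max_candidate)
  out <- list()
  qnames <- names(map$qry_seq)
  if (!nrow(cand)) cand <- cand[0L, ]
  pats <- vapply(seq_len(nrow(cand)), function(i)
    substr(map$ref_seq[[cand$chrom[i]]], cand$start[i] + 1L, cand$end[i]),
    character(1))
  all_hits <- if (length(pats))
    data.table::as.data.table(cpp_kmer_hits(pats, unname(map$qry_seq), map$k))
  else data.table::data.table()
  empty_calls <- data.table::data.table(
    chrom = character(), start = numeric(), end = numeric(),
    copies = integer(), arrangement = character(), qry_chroms = character(),
    qry_starts = character(), qry_ends = character())
  if (!nrow(all_hits)) return(empty_calls)
  # cluster every candidate's hits at once: group by (candidate, subject
  # chromosome, strand, diagonal run)
  all_hits$diag <- ifelse(all_hits$strand == 1L,
                          all_hits$subj_pos - all_hits$pat_pos,
                          all_hits$subj_pos + all_hits$pat_pos)
  data.table::setorderv(all_hits, c("pat_i", "subj_chrom_i", "strand", "diag",
                                    "subj_pos"))
  grp <- cumsum(c(TRUE, diff(all_hits$diag) > 100 |
                    diff(all_hits$pat_i) != 0L |
                    diff(all_hits$subj_chrom_i) != 0L |
                    diff(all_hits$strand) != 0L))
  all_hits$grp <- if (nrow(all_hits)) grp else integer()
  k <- map$k
  imgs <- all_hits[, {
    pp <- sort(unique(pat_pos))
    list(pat_i = pat_i[1], chrom_i = subj_chrom_i[1], strand = strand[1],
         diag = stats::median(diag), qstart = min(subj_pos),
         qend = max(subj_pos) + k,
         cov_bp = sum(pmin(diff(c(pp, pp[length(pp)] + k)), k)),
         n_hits = .N)
  }, by = "grp"]
  imgs <- imgs[imgs$n_hits >= 3L, ]
  # candidates worth identity-checking: at least two image groups
  multi <- imgs[, list(n = .N), by = "pat_i"]
  cand_ids <- multi$pat_i[multi$n >= 2L]
  for (i in cand_ids) {
    ch <- cand$chrom[i]; cs <- cand$start[i]; ce <- cand$end[i]
    plen <- ce - cs
    img <- imgs[imgs$pat_i == i, ]
    img <- img[img$cov_bp >= min_cov * plen &
                 (img$qend - img$qstart) >= 0.5 * plen &
                 (img$qend - img$qstart) <= 1.5 * plen, ]
    if (nrow(img) < 2L) next
    img$identity <- vapply(seq_len(nrow(img)), function(j)
      .image_identity(map, ch, cs, qnames[img$chrom_i[j]], img[j, ]), numeric(1))
    img <- img[img$identity >= min_identity, ]
    if (nrow(img) < 2L) next
    # disjoint images only: merge overlapping ones
    data.table::setorderv(img, c("chrom_i", "qstart"))
    keep <- rep(TRUE, nrow(img))
    for (j in seq_len(nrow(img))[-1L])
      if (img$chrom_i[j] == img$chrom_i[j - 1L] &&
          img$qstart[j] < img$qend[j - 1L] - 0.2 * plen) keep[j] <- FALSE
    img <- img[keep, ]
    if (nrow(img) < 2L) next
    same_chrom <- length(unique(img$chrom_i)) == 1L
    gaps <- if (same_chrom && nrow(img) > 1L)
      img$qstart[-1L] - img$qend[-nrow(img)] else Inf
    arrangement <- if (same_chrom && all(gaps <= tandem_gap)) "tandem" else "dispersed"
    out[[length(out) + 1L]] <- data.table::data.table(
      chrom = ch, start = cs, end = ce, copies = nrow(img),
      arrangement = arrangement,
      qry_chroms = paste(qnames[img$chrom_i], collapse = ","),
      qry_starts = paste(round(img$qstart), collapse = ","),
      qry_ends = paste(round(img$qend), collapse = ","))
  }
  if (!length(out)) return(data.table::data.table(
    chrom = character(), start = numeric(), end = numeric(),
    copies = integer(), arrangement = character(), qry_chroms = character(),
    qry_starts = character(), qry_ends = character()))
  data.table::rbindlist(out)
}

.dup_candidates <- function(map, min_len, max_candidate, merge_gap = 300L) {
  g <- .block_gaps(map)
  gap_min <- max(50L, min_len %/% 2L)
  cand <- g[g$rlen >= gap_min, list(chrom = ref_chrom, start = rstart,
                                    end = rstart + rlen)]
  un <- map$unaligned$ref
  if (nrow(un)) {
    between <- un[un$where == "between" & un$end - un$start >= gap_min,
                  list(chrom, start, end)]
    cand <- rbind(cand, between)
  }
  # query-side insertions (the new copy) whose donor still aligns: match
  # the inserted query sequence back to the reference; its reference
  # image(s) are duplication candidates
  gq <- g[g$qlen >= gap_min & g$qlen - g$rlen >= gap_min, ]
  if (nrow(gq)) {
    qpats <- vapply(seq_len(nrow(gq)), function(i)
      substr(map$qry_seq[[gq$qry_chrom[i]]], gq$qstart[i] + 1L,
             gq$qstart[i] + gq$qlen[i]), character(1))
    qh <- data.table::as.data.table(
      cpp_kmer_hits(qpats, unname(map$ref_seq), map$k))
    if (nrow(qh)) {
      qh$diag <- ifelse(qh$strand == 1L, qh$subj_pos - qh$pat_pos,
                        qh$subj_pos + qh$pat_pos)
      data.table::setorderv(qh, c("pat_i", "subj_chrom_i", "strand", "diag",
                                  "subj_pos"))
      gqg <- cumsum(c(TRUE, diff(qh$diag) > 100 | diff(qh$pat_i) != 0L |
                        diff(qh$subj_chrom_i) != 0L | diff(qh$strand) != 0L))
      qh$grp <- gqg
      qimg <- qh[, list(chrom_i = subj_chrom_i[1], s = min(subj_pos),
                        e = max(subj_pos) + map$k, n = .N), by = "grp"]
      qimg <- qimg[qimg$n >= 3L & qimg$e - qimg$s >= gap_min, ]
      if (nrow(qimg))
        cand <- rbind(cand, data.table::data.table(
          chrom = names(map$ref_seq)[qimg$chrom_i],
          start = qimg$s, end = qimg$e))
    }
  }

  # exact duplications leave no divergence for anchors to stop at: the
  # flanking anchors extend through both copies and OVERLAP on the
  # reference; the overlapped reference interval is the duplicated unit
  aa <- data.table::as.data.table(map$anchors)
  if (nrow(aa) > 1L) {
    data.table::setorderv(aa, c("ref_chrom", "ref_start"))
    prev <- aa[c(NA_integer_, seq_len(nrow(aa) - 1L)), ]
    ov <- prev$ref_end - aa$ref_start
    sel <- which(!is.na(ov) & prev$ref_chrom == aa$ref_chrom &
                   ov >= gap_min & ov <= max_candidate)
    if (length(sel))
      cand <- rbind(cand, data.table::data.table(
        chrom = aa$ref_chrom[sel], start = aa$ref_start[sel],
        end = prev$ref_end[sel]))
  }
  if (!nrow(cand)) return(cand)
  # substitutions inside duplicated copies re-create unique k-mers, which
  # fragments one duplication into several inter-anchor gaps: merge
  # candidates separated by less than merge_gap before image search
  merged <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[cand$chrom == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(cc$start + 1L, cc$end),
                          min.gapwidth = merge_gap)
    merged[[ch]] <- data.table::data.table(
      chrom = ch, start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
  }
  cand <- data.table::rbindlist(merged)
  cand[cand$end - cand$start >= min_len & cand$end - cand$start <= max_candidate, ]
}

# identity estimate along the image's dominant diagonal
.image_identity <- function(map, ref_chrom, cs, qry_chrom, img) {
  plen <- img$qend - img$qstart
  if (img$strand == 1L) {
    p0 <- max(0, img$qstart - img$diag)
    L <- min(plen, nchar(map$ref_seq[[ref_chrom]]) - (cs + p0),
             nchar(map$qry_seq[[qry_chrom]]) - (p0 + img$diag))
    if (L < 30) return(0)
    mm <- cpp_count_mismatches(map$ref_seq[[ref_chrom]], map$qry_seq[[qry_chrom]],
                               cs + p0, p0 + img$diag, L, 1L)
  } else {
    p1 <- img$diag - img$qstart   # pattern pos pairing with image end
    p0 <- max(0, img$diag - img$qend)
    L <- min(p1 - p0, nchar(map$ref_seq[[ref_chrom]]) - (cs + p0))
    if (L < 30) return(0)
    qs <- img$diag - p0 - L + map$k
    qs <- max(0, qs)
    mm <- cpp_count_mismatches(map$ref_seq[[ref_chrom]], map$qry_seq[[qry_chrom]],
                               cs + p0, qs, L, -1L)
  }
  1 - mm / L
}

#' Restrict calls to euchromatin
#'
#' Keeps calls whose reference-frame midpoint lies in the `eu` compartment;
#' heterochromatic candidates are dominated by satellite arrays whose exact
#' tandem structure is not the gene-scale duplication signal of interest.
#'
#' @param calls Call table with `chrom`, `start`, `end`.
#' @param compartments Reference compartment table.
#' @return The euchromatic subset.
#' @export
filter_euchromatic <- function(calls, compartments) {
  if (!nrow(calls)) return(calls)
  mid <- (calls$start + calls$end) / 2
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    cc <- compartments[compartments$chrom == calls$chrom[i] &
                         compartments$name == "eu", ]
    any(cc$start <= mid[i] & cc$end > mid[i])
  }, logical(1))
  calls[keep, ]
}

#' Polarize per-taxon duplication calls onto branches
#'
#' Calls are merged across taxa by reciprocal overlap of their
#' reference-frame intervals. Calls shared by the whole ingroup and absent
#' from the reference taxon are stem candidates; candidates also present in
#' the outgroup are reassigned older/ambiguous (a single origin would have
#' to predate the split, or be a loss in the reference lineage); the
#' remainder are stem. Single-taxon calls go to that terminal branch.
#'
#' @param calls_by_taxon Named list (ingroup taxa) of call tables from
#'   [detect_duplications()], all against the same reference genome.
#' @param outgroup_calls Call table for the outgroup against the same
#'   reference.
#' @param phy A [phylogeny()].
#' @param recip Reciprocal overlap fraction for merging (default 0.5).
#' @return List: `events` (merged calls with `taxa`, `branch`, `status`),
#'   `n_ingroup_shared`, `n_outgroup_overlap`, `n_stem`.
#' @export
polarize_duplications <- function(calls_by_taxon, outgroup_calls, phy,
                                  recip = 0.5) {
  all_calls <- data.table::rbindlist(c(
    lapply(names(calls_by_taxon), function(t) {
      x <- data.table::copy(calls_by_taxon[[t]]); if (nrow(x)) x$taxon <- t; x
    }),
    list({ x <- data.table::copy(outgroup_calls)
           if (nrow(x)) x$taxon <- phy$outgroup; x })), fill = TRUE)
  if (!nrow(all_calls))
    return(list(events = data.table::data.table(), n_ingroup_shared = 0L,
                n_outgroup_overlap = 0L, n_stem = 0L))
  data.table::setorderv(all_calls, c("chrom", "start"))
  all_calls$event <- NA_integer_
  ev <- 0L
  for (i in seq_len(nrow(all_calls))) {
    if (!is.na(all_calls$event[i])) next
    ev <- ev + 1L
    all_calls$event[i] <- ev
    w1 <- all_calls$end[i] - all_calls$start[i]
    js <- which(is.na(all_calls$event) & all_calls$chrom == all_calls$chrom[i])
    for (j in js) {
      ov <- min(all_calls$end[i], all_calls$end[j]) -
        max(all_calls$start[i], all_calls$start[j])
      w2 <- all_calls$end[j] - all_calls$start[j]
      if (ov >= recip * w1 && ov >= recip * w2) all_calls$event[j] <- ev
    }
  }
  events <- all_calls[, list(
    chrom = chrom[1], start = min(start), end = max(end),
    arrangement = arrangement[1],
    taxa = paste(sort(unique(taxon)), collapse = ",")), by = "event"]
  tx <- strsplit(events$taxa, ",")
  in_all_ingroup <- vapply(tx, function(t) all(phy$ingroup %in% t), logical(1))
  in_outgroup <- vapply(tx, function(t) phy$outgroup %in% t, logical(1))
  n1 <- length(phy$ingroup)
  events$status <- ifelse(in_all_ingroup & !in_outgroup, "stem",
                   ifelse(in_all_ingroup & in_outgroup, "outgroup_shared",
                   ifelse(lengths(tx) == 1L & !in_outgroup, "terminal",
                   ifelse(lengths(tx) == 1L & in_outgroup, "outgroup_only",
                          "partial"))))
  events$branch <- NA_character_
  events$branch[events$status == "stem"] <- "stem"
  events$branch[events$status == "terminal"] <-
    unlist(tx[events$status == "terminal"])
  events$branch[events$status == "outgroup_only"] <- phy$outgroup
  list(events = events,
       n_ingroup_shared = sum(in_all_ingroup),
       n_outgroup_overlap = sum(in_all_ingroup & in_outgroup),
       n_stem = sum(events$status == "stem"))
}

#' Classify duplication calls by gene-model overlap
#'
#' Overlap classes are nested and the maximal attained class is reported:
#' `full_gene` (a complete transcript span, UTRs included, lies inside the
#' call) implies `full_CDS` (a complete coding sequence inside the call)
#' implies `exonic` (any exon bp overlapped); otherwise `intergenic`.
#'
#' @param calls Call table (reference frame).
#' @param genes Reference gene table (`gene_id`, `chrom`, `cds_start`,
#'   `cds_end`).
#' @param exons Reference exon table.
#' @return `calls` with an `overlap_class` column.
#' @export
classify_overlap <- function(calls, genes, exons) {
  calls <- data.table::as.data.table(calls)
  spans <- data.table::as.data.table(exons)[
    , list(chrom = chrom[1], tx_start = min(start), tx_end = max(end)),
    by = "gene_id"]
  spans <- merge(spans, genes[, list(gene_id, cds_start, cds_end)],
                 by = "gene_id")
  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- calls$start[i]; e <- calls$end[i]; ch <- calls$chrom[i]
    g <- spans[spans$chrom == ch, ]
    ex <- exons[exons$chrom == ch, ]
    if (nrow(g) && any(g$tx_start >= s & g$tx_end <= e)) cls[i] <- "full_gene"
    else if (nrow(g) && any(g$cds_start >= s & g$cds_end <= e)) cls[i] <- "full_CDS"
    else if (nrow(ex) && any(ex$start < e & ex$end > s)) cls[i] <- "exonic"
    else cls[i] <- "intergenic"
  }
  calls$overlap_class <- cls
  calls
}

#' X-chromosome enrichment of duplication calls
#'
#' One-sample proportion test of the X-linked call count against a null
#' proportion (e.g. the fraction of genes that are X-linked).
#'
#' @param calls Call table with a `chrom` column.
#' @param null_prop Null proportion of X-linked calls.
#' @param x_chrom Name of the X chromosome (default `"chrX"`).
#' @inheritParams prop_test_one_sample
#' @return List: `x_count`, `n`, and the `prop_test_result`.
#' @export
x_enrichment <- function(calls, null_prop, x_chrom = "chrX",
                         alternative = "two_sided", continuity = TRUE) {
  n <- nrow(calls)
  if (n == 0L) stop("no calls: X enrichment undefined")
  x <- sum(calls$chrom == x_chrom)
  list(x_count = x, n = n,
       test = prop_test_one_sample(x, n, null_prop, alternative = alternative,
                                   continuity = continuity))
}

#' Duplication fixation rate on a branch
#'
#' @param count Number of duplications assigned to the branch.
#' @param branch_myr Branch duration in Myr.
#' @return List: `rate` (per Myr), `years_per_gene`.
#' @export
duplication_rate <- function(count, branch_myr) {
  r <- rate_per_myr(count, branch_myr)
  list(rate = r$rate, years_per_gene = r$years_per_event)
}
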