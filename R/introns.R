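#' Conserved orthologous introns across taxa
#'
#' For every ortholog gene (shared `gene_id`, one isoform per gene) present
#' in all requested taxa with equal exon counts, an intron is retained when
#' both flanking exons are of similar length between taxa: the relative
#' difference `|a - b| / max(a, b)` must not exceed `max_diff` for every
#' non-reference taxon against the reference (`mode = "reference"`, the
#' default) or for every taxon pair (`mode = "all_pairs"`).
#'
#' @param genomes Named list of genome states (or lists with `exons`).
#' @param taxa Taxa to compare (default: all of `genomes`).
#' @param ref_taxon Reference taxon for the flanking-exon rule.
#' @param max_diff Maximum relative flanking-exon length difference
#'   (default 0.10).
#' @param mode `"reference"` or `"all_pairs"`.
#' @return Long-format data.table: `gene_id`, `intron_rank`, `taxon`,
#'   `chrom`, `start`, `end`, `length`.
#' @export
match_conserved_introns <- function(genomes, taxa = names(genomes),
                                    ref_taxon = taxa[1], max_diff = 0.10,
                                    mode = c("reference", "all_pairs")) {
  mode <- match.arg(mode)
  stopifnot(ref_taxon %in% taxa)
  exlen <- lapply(taxa, function(t) {
    e <- data.table::as.data.table(genomes[[t]]$exons)
    e$len <- e$end - e$start
    e
  })
  names(exlen) <- taxa
  intr <- lapply(taxa, function(t) state_introns(genomes[[t]]))
  names(intr) <- taxa

  common <- Reduce(intersect, lapply(exlen, function(e) unique(e$gene_id)))
  out <- list()
  for (gid in common) {
    ex_g <- lapply(exlen, function(e) e[e$gene_id == gid, ][order(exon_rank)])
    n_ex <- unique(vapply(ex_g, nrow, integer(1)))
    if (length(n_ex) != 1L || n_ex < 2L) next
    lens <- vapply(ex_g, function(e) e$len, numeric(n_ex))   # exon x taxon
    ok_pair <- function(a, b) abs(a - b) / pmax(a, b) <= max_diff
    for (ri in seq_len(n_ex - 1L)) {
      flanks <- lens[c(ri, ri + 1L), , drop = FALSE]
      keep <- if (mode == "reference") {
        all(vapply(setdiff(taxa, ref_taxon), function(t)
          all(ok_pair(flanks[, t], flanks[, ref_taxon])), logical(1)))
      } else {
        all(vapply(seq_along(taxa), function(i1)
          all(vapply(seq_along(taxa), function(i2)
            all(ok_pair(flanks[, i1], flanks[, i2])), logical(1))), logical(1)))
      }
      if (!keep) next
      for (t in taxa) {
        it <- intr[[t]][intr[[t]]$gene_id == gid & intr[[t]]$intron_rank == ri, ]
        if (nrow(it) != 1L) { keep <- FALSE; break }
        out[[length(out) + 1L]] <- data.table::data.table(
          gene_id = gid, intron_rank = ri, taxon = t, chrom = it$chrom,
          start = it$start, end = it$end, length = it$end - it$start)
      }
    }
  }
  if (!length(out)) return(data.table::data.table(
    gene_id = character(), intron_rank = integer(), taxon = character(),
    chrom = character(), start = numeric(), end = numeric(),
    length = numeric()))
  data.table::rbindlist(out)
}

#' Classify introns as complex or simple by repeat content
#'
#' An intron is complex when it overlaps a TE or complex-satellite
#' annotation by at least one bp, simple otherwise.
#'
#' @param introns Long-format intron table (one taxon's rows).
#' @param repeats That taxon's repeat table.
#' @return `introns` with a `class` column (`"complex"`/`"simple"`).
#' @export
classify_intron <- function(introns, repeats) {
  introns <- data.table::as.data.table(introns)
  rep_dt <- data.table::as.data.table(repeats)
  cls <- rep("simple", nrow(introns))
  for (ch in unique(introns$chrom)) {
    ii <- which(introns$chrom == ch)
    rr <- rep_dt[rep_dt$chrom == ch, ]
    if (!nrow(rr)) next
    ir <- IRanges::IRanges(introns$start[ii] + 1L, introns$end[ii])
    jr <- IRanges::reduce(IRanges::IRanges(rr$start + 1L, rr$end))
    cls[ii][IRanges::overlapsAny(ir, jr)] <- "complex"
  }
  introns$class <- cls
  introns
}

#' Paired comparison of conserved intron lengths between two species
#'
#' Computes per-intron length differences (`taxonA - taxonB`) over the
#' conserved set, optionally restricted by intron class and by the
#' reference-frame chromatin compartment, and runs a paired t test.
#' An intron counts as complex when it is complex in either species
#' (`class_rule = "either"`) or in both (`"both"`).
#'
#' @param conserved Long-format table from [match_conserved_introns()]
#'   with a `class` column per taxon row (see [classify_intron()]).
#' @param taxonA,taxonB Taxa to compare.
#' @param class `"all"`, `"complex"` or `"simple"`.
#' @param compartment `"all"`, `"eu"` or `"het"`; evaluated on the midpoint
#'   of the `compartment_taxon`'s intron copy.
#' @param compartments Compartment table of `compartment_taxon`.
#' @param compartment_taxon Taxon whose coordinates index the compartments
#'   (default `taxonA`).
#' @param class_rule `"either"` (default) or `"both"`.
#' @return List: `n`, `mean_diff`, `test` (a `paired_t_result`), plus the
#'   filters used. `NULL` when fewer than 2 paired introns remain.
#' @export
compare_intron_lengths <- function(conserved, taxonA, taxonB, class = "all",
                                   compartment = "all", compartments = NULL,
                                   compartment_taxon = taxonA,
                                   class_rule = c("either", "both")) {
  class_rule <- match.arg(class_rule)
  ci <- data.table::as.data.table(conserved)
  key <- function(t) ci[ci$taxon == t, ]
  a <- key(taxonA); b <- key(taxonB)
  m <- merge(a, b, by = c("gene_id", "intron_rank"), suffixes = c("_a", "_b"))
  if (class != "all") {
    if (!"class_a" %in% names(m))
      stop("run classify_intron() per taxon before filtering by class")
    is_complex <- if (class_rule == "either")
      m$class_a == "complex" | m$class_b == "complex"
    else m$class_a == "complex" & m$class_b == "complex"
    m <- if (class == "complex") m[is_complex, ] else m[!is_complex, ]
  }
  if (compartment != "all") {
    if (is.null(compartments))
      stop("'compartments' required for a compartment-restricted comparison")
    side <- if (compartment_taxon == taxonA) "_a" else "_b"
    mid <- (m[[paste0("start", side)]] + m[[paste0("end", side)]]) / 2
    keep <- logical(nrow(m))
    for (i in seq_len(nrow(m))) {
      cc <- compartments[compartments$chrom == m[[paste0("chrom", side)]][i], ]
      at <- cc$name[cc$start <= mid[i] & cc$end > mid[i]]
      keep[i] <- length(at) == 1L && at == compartment
    }
    m <- m[keep, ]
  }
  if (nrow(m) < 2L) return(NULL)
  diffs <- m$length_a - m$length_b
  list(taxonA = taxonA, taxonB = taxonB, class = class,
       compartment = compartment, n = nrow(m), mean_diff = mean(diffs),
       test = paired_t(diffs))
}
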