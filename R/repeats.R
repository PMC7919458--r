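#' Repeats fully contained in syntenic blocks
#'
#' Mirrors the containment step of the shared-TE pipeline: only repeats
#' whose interval lies 100 percent inside a single synteny block (overlap
#' fraction 1.0) are considered for cross-species sharing.
#'
#' @param repeats data.table of repeat annotations (`chrom`, `start`,
#'   `end`, `class`, `repeat_id`, ...).
#' @param map An `alignment_map`.
#' @param side `"ref"` if the repeats live in the map's reference genome,
#'   `"qry"` otherwise.
#' @return The contained subset of `repeats`.
#' @export
contained_repeats <- function(repeats, map, side = c("ref", "qry")) {
  side <- match.arg(side)
  b <- map$blocks
  cs <- paste0(side, "_chrom"); ss <- paste0(side, "_start"); es <- paste0(side, "_end")
  keep <- logical(nrow(repeats))
  for (ch in unique(repeats$chrom)) {
    ri <- which(repeats$chrom == ch)
    bb <- b[b[[cs]] == ch, ]
    if (!nrow(bb)) next
    for (i in ri)
      keep[i] <- any(bb[[ss]] <= repeats$start[i] & bb[[es]] >= repeats$end[i])
  }
  repeats[keep, ]
}

#' Shared repeat content between two species
#'
#' A repeat of genome A is shared with genome B when its projection through
#' the alignment map reciprocally overlaps a B repeat of the same class by
#' at least `recip` of each element's length.
#'
#' @param repeatsA Containment-filtered repeats of the map's reference
#'   genome.
#' @param repeatsB Containment-filtered repeats of the map's query genome.
#' @param mapAB `alignment_map` with A as reference, B as query.
#' @param recip Reciprocal overlap fraction (default 0.5).
#' @return data.table of element pairs: `id_a`, `id_b`, `class`,
#'   `shared_bp`.
#' @export
shared_repeat_content <- function(repeatsA, repeatsB, mapAB, recip = 0.5) {
  out <- list()
  rb <- data.table::as.data.table(repeatsB)
  for (i in seq_len(nrow(repeatsA))) {
    ra <- repeatsA[i, ]
    img <- project_interval(mapAB, ra$chrom, ra$start, ra$end, from = "ref")
    if (!nrow(img)) next
    lenA <- ra$end - ra$start
    cand <- rb[rb$class == ra$class, ]
    if (!nrow(cand)) next
    for (j in seq_len(nrow(img))) {
      hit <- cand[cand$chrom == img$chrom[j] &
                    cand$start < img$end[j] & cand$end > img$start[j], ]
      for (h in seq_len(nrow(hit))) {
        ov <- min(hit$end[h], img$end[j]) - max(hit$start[h], img$start[j])
        lenB <- hit$end[h] - hit$start[h]
        if (ov >= recip * lenA && ov >= recip * lenB)
          out[[length(out) + 1L]] <- data.table::data.table(
            id_a = ra$repeat_id, id_b = hit$repeat_id[h],
            class = ra$class, shared_bp = ov)
      }
    }
  }
  if (!length(out)) return(data.table::data.table(
    id_a = character(), id_b = character(), class = character(),
    shared_bp = numeric()))
  unique(data.table::rbindlist(out))
}

#' Assign focal-taxon repeats to phylogeny branch categories
#'
#' Pairwise set algebra on shared-element sets, all expressed in the focal
#' taxon's coordinate frame: an element shared with both other ingroup taxa
#' and with the reference taxon is complex-wide; shared with both ingroup
#' taxa but not the reference, ingroup-stem; shared with exactly one other
#' taxon, pair-shared; shared with none, taxon-specific. Sharing patterns
#' that include the reference plus a single ingroup taxon imply an ancestral
#' presence with subsequent loss and are folded into complex-wide.
#'
#' Categories describe detected sharing, not true absence: an element
#' assigned taxon-specific may simply have escaped detection elsewhere.
#'
#' @param focal_repeats Containment-filtered focal-taxon repeats.
#' @param shared Named list of pair tables from [shared_repeat_content()],
#'   one per partner taxon (focal as A).
#' @param focal,reference Taxon names.
#' @return data.table: `repeat_id`, `class`, `bp`, `partners`, `category`.
#' @export
assign_branches <- function(focal_repeats, shared, focal, reference) {
  partners <- names(shared)
  ingroup_partners <- setdiff(partners, reference)
  res <- data.table::data.table(
    repeat_id = focal_repeats$repeat_id, class = focal_repeats$class,
    bp = focal_repeats$end - focal_repeats$start)
  pat <- lapply(res$repeat_id, function(id)
    partners[vapply(partners, function(p) id %in% shared[[p]]$id_a, logical(1))])
  res$partners <- vapply(pat, paste, character(1), collapse = ",")
  res$category <- vapply(pat, function(p) {
    n_in <- length(intersect(p, ingroup_partners))
    has_ref <- reference %in% p
    if (n_in == length(ingroup_partners) && has_ref) "complex_wide"
    else if (n_in == length(ingroup_partners)) "ingroup_stem"
    else if (has_ref && n_in >= 1L) "complex_wide"   # presence + loss pattern
    else if (length(p) == 1L) paste0("pair_", p)
    else if (length(p) == 0L) paste0("specific_", focal)
    else "ingroup_stem"
  }, character(1))
  res
}

#' Composition of repeat classes per branch category
#'
#' @param assignment From [assign_branches()].
#' @param by_family Also break down by family (requires a `family` column
#'   via `repeats`).
#' @param repeats Optional repeat table to supply families.
#' @return data.table: `category`, `class`, `bp`, `n`, `prop` (within
#'   category; bp-weighted). Empty categories are absent rather than
#'   zero-filled.
#' @export
composition_summary <- function(assignment, by_family = FALSE, repeats = NULL) {
  a <- data.table::as.data.table(assignment)
  if (by_family) {
    if (is.null(repeats)) stop("'repeats' needed for a family breakdown")
    a <- merge(a, repeats[, list(repeat_id, family)], by = "repeat_id")
    out <- a[, list(bp = sum(bp), n = .N), by = c("category", "class", "family")]
  } else {
    out <- a[, list(bp = sum(bp), n = .N), by = c("category", "class")]
  }
  out[, prop := bp / sum(bp), by = "category"]
  data.table::setorderv(out, c("category", "class"))
  out[]
}

#' Exonic vs non-exonic repeat bases per category
#'
#' @param assignment From [assign_branches()].
#' @param repeats The focal-taxon repeat table (for coordinates).
#' @param exons Focal-taxon exon table (`chrom`, `start`, `end`).
#' @return data.table per category: `exonic_bp`, `non_exonic_bp`,
#'   `exonic_frac`.
#' @export
exonic_overlap <- function(assignment, repeats, exons) {
  a <- merge(data.table::as.data.table(assignment),
             repeats[, list(repeat_id, chrom, start, end)], by = "repeat_id")
  exu <- lapply(split(exons, exons$chrom), function(e)
    IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end)))
  a$exonic_bp <- vapply(seq_len(nrow(a)), function(i) {
    eu <- exu[[a$chrom[i]]]
    if (is.null(eu)) return(0)
    sum(IRanges::width(IRanges::intersect(
      IRanges::IRanges(a$start[i] + 1L, a$end[i]), eu)))
  }, numeric(1))
  out <- a[, list(bp = sum(bp), exonic_bp = sum(exonic_bp),
                  non_exonic_bp = sum(bp - exonic_bp)), by = "category"]
  out$exonic_frac <- out$exonic_bp / out$bp
  out[]
}

#' Full shared-TE branch analysis for one focal taxon
#'
#' Orchestrates the containment, pairwise sharing and branch-assignment
#' steps, restricted by default to euchromatic TEs (satellites excluded).
#'
#' @param genomes Named list of genome states.
#' @param maps Named list of `alignment_map`s with the focal taxon as
#'   reference, one per partner taxon.
#' @param focal,reference Taxon names.
#' @param euchromatin_only Restrict to repeats inside the `eu` compartment
#'   of their own taxon (default `TRUE`).
#' @param include_satellites Include satellite-class repeats in the set
#'   algebra (default `FALSE`).
#' @param recip Reciprocal overlap fraction.
#' @return List: `assignment`, `composition`, `exonic`, `contained`
#'   (focal), `shared` (pair tables).
#' @export
shared_te_analysis <- function(genomes, maps, focal, reference,
                               euchromatin_only = TRUE,
                               include_satellites = FALSE, recip = 0.5) {
  pick <- function(state) {
    r <- data.table::as.data.table(state$repeats)
    if (!include_satellites) r <- r[r$class != "satellite", ]
    if (euchromatin_only) {
      eu <- state$compartments[state$compartments$name == "eu", ]
      keep <- logical(nrow(r))
      for (i in seq_len(nrow(r))) {
        ee <- eu[eu$chrom == r$chrom[i], ]
        keep[i] <- any(ee$start <= r$start[i] & ee$end >= r$end[i])
      }
      r <- r[keep, ]
    }
    r
  }
  focal_rep <- pick(genomes[[focal]])
  shared <- list()
  contained_focal <- NULL
  for (p in names(maps)) {
    fa <- contained_repeats(focal_rep, maps[[p]], side = "ref")
    pb <- contained_repeats(pick(genomes[[p]]), maps[[p]], side = "qry")
    shared[[p]] <- shared_repeat_content(fa, pb, maps[[p]], recip = recip)
    contained_focal <- if (is.null(contained_focal)) fa else
      fa[fa$repeat_id %in% contained_focal$repeat_id, ]
  }
  assignment <- assign_branches(contained_focal, shared, focal, reference)
  list(assignment = assignment,
       composition = composition_summary(assignment),
       exonic = exonic_overlap(assignment, contained_focal,
                               genomes[[focal]]$exons),
       contained = contained_focal, shared = shared)
}
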