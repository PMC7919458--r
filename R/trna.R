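#' Isotype string of one chromosome's tRNA genes
#'
#' Sorts the genes by position and writes one character per gene: the
#' isotype's one-letter amino-acid code, lower-cased for predicted
#' pseudogenes. Cluster boundaries fall where the inter-gene distance
#' exceeds `cluster_gap`.
#'
#' @param trnas tRNA table of one taxon (`chrom`, `start`, `end`, `strand`,
#'   `isotype`, `anticodon`, `pseudogene`, `trna_id`).
#' @param chrom Chromosome to extract.
#' @param cluster_gap Inter-gene distance defining cluster breaks (default
#'   5 kb).
#' @return List: `string`, `genes` (the sorted rows with `string_pos`),
#'   `clusters` (integer cluster index per gene).
#' @export
build_isotype_string <- function(trnas, chrom, cluster_gap = 5000L) {
  sel <- trnas$chrom == chrom   # plain vector: avoids column-name capture
  g <- data.table::as.data.table(trnas)[sel, ]
  data.table::setorderv(g, "start")
  if (!nrow(g)) return(list(string = "", genes = g, clusters = integer()))
  iso <- g$isotype
  unknown <- !iso %in% GENETIC_CODE_AA
  if (any(unknown)) {
    warning(sum(unknown), " tRNA gene(s) with unknown isotype written as 'X'")
    iso[unknown] <- "X"
  }
  chars <- ifelse(g$pseudogene, tolower(iso), iso)
  g$string_pos <- seq_len(nrow(g))
  clusters <- cumsum(c(TRUE, g$start[-1L] - g$end[-nrow(g)] > cluster_gap))
  list(string = paste(chars, collapse = ""), genes = g, clusters = clusters)
}

#' Global alignment of two isotype strings
#'
#' Needleman-Wunsch on the isotype alphabet (case-insensitive scoring:
#' pseudogene lower-casing affects reporting only). Ties in the traceback
#' are broken deterministically: match/mismatch first, then gap in the
#' first string, then gap in the second.
#'
#' @param sA,sB Isotype strings.
#' @param match,mismatch,gap Scores (defaults +2/-1/-2).
#' @return List: `score`, `columns` (data.table `a_pos`, `b_pos`; `NA`
#'   marks a gap, positions are 1-based string offsets).
#' @export
align_isotype_strings <- function(sA, sB, match = 2, mismatch = -1, gap = -2) {
  a <- strsplit(toupper(sA), "")[[1]]
  b <- strsplit(toupper(sB), "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i + 1L, j + 1L] <- max(S[i, j] + if (a[i] == b[j]) match else mismatch,
                             S[i, j + 1L] + gap,
                             S[i + 1L, j] + gap)
  i <- n; j <- m
  ap <- integer(0); bp <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      ap <- c(i, ap); bp <- c(j, bp); i <- i - 1L; j <- j - 1L
    } else if (j > 0L && S[i + 1L, j + 1L] == S[i + 1L, j] + gap) {
      ap <- c(NA_integer_, ap); bp <- c(j, bp); j <- j - 1L   # gap in A
    } else {
      ap <- c(i, ap); bp <- c(NA_integer_, bp); i <- i - 1L   # gap in B
    }
  }
  list(score = S[n + 1L, m + 1L],
       columns = data.table::data.table(a_pos = ap, b_pos = bp))
}

# Anticodon-aware pairwise alignment used by the multi-taxon merge: same
# dynamic program as align_isotype_strings, but a mismatch is tolerable
# (-1) only when the two genes' anticodons differ by at most one base --
# the signature of a genuine anticodon shift -- and strongly penalized
# (-5) otherwise, so unrelated genes prefer gaps over stacking.
.align_trna_pair <- function(gA, gB, match = 2, gap = -2) {
  n <- nrow(gA); m <- nrow(gB)
  if (n == 0L || m == 0L)
    return(data.table::data.table(
      a_pos = c(seq_len(n), rep(NA_integer_, m)),
      b_pos = c(rep(NA_integer_, n), seq_len(m))))
  hamming3 <- function(a, b) {
    if (is.na(a) || is.na(b)) return(3L)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  sc <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc[i, j] <- if (gA$isotype[i] == gB$isotype[j]) match
                else if (hamming3(gA$anticodon[i], gB$anticodon[j]) <= 1L) -1
                else -5
  }
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n); S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i + 1L, j + 1L] <- max(S[i, j] + sc[i, j], S[i, j + 1L] + gap,
                             S[i + 1L, j] + gap)
  i <- n; j <- m; ap <- integer(0); bp <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + sc[i, j]) {
      ap <- c(i, ap); bp <- c(j, bp); i <- i - 1L; j <- j - 1L
    } else if (j > 0L && S[i + 1L, j + 1L] == S[i + 1L, j] + gap) {
      ap <- c(NA_integer_, ap); bp <- c(j, bp); j <- j - 1L
    } else {
      ap <- c(i, ap); bp <- c(NA_integer_, bp); i <- i - 1L
    }
  }
  data.table::data.table(a_pos = ap, b_pos = bp)
}

# Canonicalize gap placement inside runs of identical reference letters:
# taxon genes of the run's letter occupy the leftmost reference positions,
# surplus genes become insertions after the last matched position. Without
# this, different taxa make different (equal-scoring) gap choices inside
# homogeneous runs and ortholog columns drift apart.
.canonicalize_runs <- function(columns, a_chars, b_chars) {
  if (!length(b_chars)) return(columns)
  runs <- rle(b_chars)
  b_start <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  rows_b <- match(seq_along(b_chars), columns$b_pos)
  out_keep <- rep(TRUE, nrow(columns))
  new_rows <- list()
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    if (len < 1L) next
    bpos <- b_start[r]:(b_start[r] + len - 1L)
    r1 <- rows_b[bpos[1L]]; r2 <- rows_b[bpos[len]]
    rows <- r1:r2
    arows <- columns$a_pos[rows]
    amatch <- arows[!is.na(arows)]
    # skip runs containing a mismatch-aligned letter: not ours to rearrange
    if (any(a_chars[amatch] != runs$values[r])) next
    # also capture insertions of the same letter flanking the run
    r3 <- r2
    while (r3 < nrow(columns) && is.na(columns$b_pos[r3 + 1L]) &&
           a_chars[columns$a_pos[r3 + 1L]] == runs$values[r]) r3 <- r3 + 1L
    r0 <- r1
    while (r0 > 1L && is.na(columns$b_pos[r0 - 1L]) &&
           a_chars[columns$a_pos[r0 - 1L]] == runs$values[r]) r0 <- r0 - 1L
    rows <- r0:r3
    r1 <- r0
    agenes <- columns$a_pos[rows]
    agenes <- agenes[!is.na(agenes)]
    out_keep[rows] <- FALSE
    m <- min(length(agenes), len)
    sub <- data.table::data.table(
      a_pos = c(agenes[seq_len(m)],
                rep(NA_integer_, len - m),
                if (length(agenes) > m) agenes[(m + 1L):length(agenes)]),
      b_pos = c(bpos[seq_len(m)],
                if (len > m) bpos[(m + 1L):len],
                rep(NA_integer_, max(length(agenes) - m, 0L))))
    new_rows[[length(new_rows) + 1L]] <- list(at = r1, rows = sub)
  }
  if (!length(new_rows)) return(columns)
  repl <- list()
  for (nr in new_rows) repl[[as.character(nr$at)]] <- nr$rows
  pieces <- list()
  for (i in seq_len(nrow(columns))) {
    sub <- repl[[as.character(i)]]
    if (!is.null(sub)) pieces[[length(pieces) + 1L]] <- sub
    if (out_keep[i]) pieces[[length(pieces) + 1L]] <- columns[i, ]
  }
  data.table::rbindlist(pieces)
}

# exhaustive alignment score by enumeration of all alignments (test oracle
# for short strings; exponential)
align_score_bruteforce <- function(sA, sB, match = 2, mismatch = -1, gap = -2) {
  a <- strsplit(toupper(sA), "")[[1]]
  b <- strsplit(toupper(sB), "")[[1]]
  rec <- function(i, j) {
    if (i > length(a)) return(gap * (length(b) - j + 1L))
    if (j > length(b)) return(gap * (length(a) - i + 1L))
    max(rec(i + 1L, j + 1L) + if (a[i] == b[j]) match else mismatch,
        rec(i + 1L, j) + gap,
        rec(i, j + 1L) + gap)
  }
  rec(1L, 1L)
}

#' Positional tRNA orthology across taxa
#'
#' Builds per-chromosome isotype strings, aligns every taxon to the
#' reference taxon, and merges the pairwise alignments into multi-taxon
#' columns anchored on reference positions. Genes inserted relative to the
#' reference are aligned to each other (anchored on the longest inserted
#' run) and appear as reference-gap columns. Each input gene lands in
#' exactly one column.
#'
#' Columns are then called: `conserved` (all taxa present, identical
#' anticodon), `anticodon_shift`, `copy_gain` / `copy_loss` (polarized
#' against the outgroup by Dollo parsimony), `pseudogenized` (presence
#' conserved, pseudogene state differs). When pairwise alignment maps are
#' supplied, a column is flagged low-confidence if a member lies more than
#' `flank_tol` away from the synteny projection of its reference
#' counterpart.
#'
#' @param trna_tables Named list of per-taxon tRNA tables.
#' @param phy A [phylogeny()].
#' @param ref_taxon Anchor taxon (default the phylogeny's reference).
#' @param maps Optional named list of `alignment_map`s (reference -> taxon)
#'   for flank confirmation.
#' @param cluster_gap Cluster boundary distance.
#' @param flank_tol Maximum distance between a member and the projected
#'   reference position before the column is flagged (default 5 kb).
#' @return List: `columns` (one row per ortholog column with per-taxon
#'   `<taxon>_id`, `_iso`, `_ac` fields, `call`, `branch`,
#'   `low_confidence`), `shifts` (anticodon shift calls).
#' @export
trna_orthology <- function(trna_tables, phy, ref_taxon = phy$reference,
                           maps = NULL, cluster_gap = 5000L, flank_tol = 5000L) {
  taxa <- names(trna_tables)
  stopifnot(ref_taxon %in% taxa)
  others <- setdiff(taxa, ref_taxon)
  chroms <- sort(unique(unlist(lapply(trna_tables, function(x) unique(x$chrom)))))
  cols_all <- list()
  for (ch in chroms) {
    strs <- lapply(trna_tables, build_isotype_string, chrom = ch,
                   cluster_gap = cluster_gap)
    nref <- nrow(strs[[ref_taxon]]$genes)
    # per taxon: map from taxon string position -> (ref anchor, insertion rank)
    keys <- list()
    keys[[ref_taxon]] <- if (nref)
      data.table::data.table(pos = seq_len(nref), anchor = seq_len(nref), ins = 0L)
      else data.table::data.table(pos = integer(), anchor = integer(), ins = integer())
    for (t in others) {
      al <- .align_trna_pair(strs[[t]]$genes, strs[[ref_taxon]]$genes)
      al <- .canonicalize_runs(al, toupper(strsplit(strs[[t]]$string, "")[[1]]),
                               toupper(strsplit(strs[[ref_taxon]]$string, "")[[1]]))
      anchor <- integer(0); ins <- integer(0); pos <- integer(0)
      last_ref <- 0L; run <- 0L
      for (r in seq_len(nrow(al))) {
        if (!is.na(al$b_pos[r])) { last_ref <- al$b_pos[r]; run <- 0L }
        if (!is.na(al$a_pos[r])) {
          if (is.na(al$b_pos[r])) run <- run + 1L
          pos <- c(pos, al$a_pos[r])
          anchor <- c(anchor, if (is.na(al$b_pos[r])) last_ref else al$b_pos[r])
          ins <- c(ins, if (is.na(al$b_pos[r])) run else 0L)
        }
      }
      keys[[t]] <- data.table::data.table(pos = pos, anchor = anchor, ins = ins)
    }
    # columns: (anchor, ins) pairs; ins > 0 are reference-gap columns
    kk <- unique(data.table::rbindlist(
      lapply(keys, function(k) k[, list(anchor, ins)])))
    data.table::setorderv(kk, c("anchor", "ins"))
    for (r in seq_len(nrow(kk))) {
      row <- list(chrom = ch, anchor = kk$anchor[r], ins = kk$ins[r])
      for (t in taxa) {
        kt <- keys[[t]]
        hit <- kt$pos[kt$anchor == kk$anchor[r] & kt$ins == kk$ins[r]]
        g <- strs[[t]]$genes
        if (length(hit) == 1L && nrow(g)) {
          row[[paste0(t, "_id")]] <- g$trna_id[hit]
          row[[paste0(t, "_iso")]] <- g$isotype[hit]
          row[[paste0(t, "_ac")]] <- g$anticodon[hit]
          row[[paste0(t, "_pos")]] <- g$start[hit]
          row[[paste0(t, "_pseudo")]] <- g$pseudogene[hit]
        } else {
          row[[paste0(t, "_id")]] <- NA_character_
          row[[paste0(t, "_iso")]] <- NA_character_
          row[[paste0(t, "_ac")]] <- NA_character_
          row[[paste0(t, "_pos")]] <- NA_real_
          row[[paste0(t, "_pseudo")]] <- NA
        }
      }
      cols_all[[length(cols_all) + 1L]] <- data.table::as.data.table(row)
    }
  }
  columns <- data.table::rbindlist(cols_all, fill = TRUE)
  if (!nrow(columns)) return(list(columns = columns,
                                  shifts = data.table::data.table()))

  # Adjacent copy-number changes in different taxa can force the pairwise
  # aligner to stack unrelated genes (a mismatch costs less than two gaps).
  # A genuine anticodon shift is a point mutation, so a member whose
  # isotype differs from the reference member's AND whose anticodon is
  # more than one base away is misorthology, not a shift: it is split out
  # into its own column.
  hamming3 <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  extra <- list()
  for (i in seq_len(nrow(columns))) {
    r_iso <- columns[[paste0(ref_taxon, "_iso")]][i]
    r_ac <- columns[[paste0(ref_taxon, "_ac")]][i]
    if (is.na(r_iso)) next
    for (t in others) {
      t_iso <- columns[[paste0(t, "_iso")]][i]
      t_ac <- columns[[paste0(t, "_ac")]][i]
      if (is.na(t_iso) || t_iso == r_iso) next
      if (hamming3(t_ac, r_ac) <= 1L) next
      new_row <- columns[i, ]
      for (tt in taxa) for (f in c("_id", "_iso", "_ac", "_pos", "_pseudo")) {
        col <- paste0(tt, f)
        if (tt == t) {
          data.table::set(columns, i, col,
                          if (f == "_pos") NA_real_
                          else if (f == "_pseudo") NA else NA_character_)
        } else {
          data.table::set(new_row, 1L, col,
                          if (f == "_pos") NA_real_
                          else if (f == "_pseudo") NA else NA_character_)
        }
      }
      extra[[length(extra) + 1L]] <- new_row
    }
  }
  if (length(extra))
    columns <- rbind(columns, data.table::rbindlist(extra))
  # drop columns emptied by the splitting
  any_member <- rowSums(!is.na(as.matrix(
    columns[, paste0(taxa, "_id"), with = FALSE]))) > 0L
  columns <- columns[any_member, ]
  data.table::setorderv(columns, c("chrom", "anchor", "ins"))
  columns$column_id <- seq_len(nrow(columns))

  # calls
  present <- sapply(taxa, function(t) !is.na(columns[[paste0(t, "_id")]]))
  og <- phy$outgroup
  calls <- character(nrow(columns))
  branch <- rep(NA_character_, nrow(columns))
  for (i in seq_len(nrow(columns))) {
    pres <- taxa[present[i, ]]
    acs <- stats::na.omit(unlist(columns[i, paste0(taxa, "_ac"), with = FALSE]))
    if (length(pres) == length(taxa)) {
      if (length(unique(acs)) > 1L) calls[i] <- "anticodon_shift"
      else {
        ps <- unlist(columns[i, paste0(taxa, "_pseudo"), with = FALSE])
        calls[i] <- if (length(unique(stats::na.omit(ps))) > 1L)
          "pseudogenized" else "conserved"
      }
      next
    }
    if (og %in% pres) {
      # outgroup has the gene: absence is derived (a loss), unless Dollo
      # flips polarity (the "present" taxa are themselves one clade, i.e.
      # a gain on that branch)
      d <- dollo_branch(phy, derived = setdiff(taxa, pres), observed = taxa)
      calls[i] <- if (isTRUE(d$flipped)) "copy_gain" else "copy_loss"
    } else {
      d <- dollo_branch(phy, derived = pres, observed = taxa)
      calls[i] <- if (isTRUE(d$flipped)) "copy_loss" else "copy_gain"
    }
    branch[i] <- d$branch
  }
  columns$call <- calls
  columns$branch <- branch

  # flank confirmation by synteny projection
  columns$low_confidence <- FALSE
  if (!is.null(maps)) {
    for (i in seq_len(nrow(columns))) {
      rp <- columns[[paste0(ref_taxon, "_pos")]][i]
      if (is.na(rp)) next
      for (t in intersect(names(maps), taxa)) {
        tp <- columns[[paste0(t, "_pos")]][i]
        if (is.na(tp)) next
        img <- project_interval(maps[[t]], columns$chrom[i],
                                max(rp - 1000, 0), rp + 1000)
        if (!nrow(img)) { columns$low_confidence[i] <- TRUE; next }
        if (min(abs(c(img$start, img$end) - tp)) > flank_tol)
          columns$low_confidence[i] <- TRUE
      }
    }
  }
  shifts <- classify_shifts(columns, phy, taxa)
  list(columns = columns, shifts = shifts)
}

#' Classify anticodon shifts in ortholog columns
#'
#' A column whose members carry at least two distinct anticodons is a
#' shift: isoacceptor when every member shares the isotype (amino acid),
#' alloacceptor otherwise. The ancestral state is the outgroup's; the shift
#' is assigned to the Dollo branch of the taxa carrying the derived state,
#' or reported unpolarized when the outgroup is absent from the column.
#'
#' @param columns Column table from [trna_orthology()].
#' @param phy A [phylogeny()].
#' @param taxa Taxon names present in the columns.
#' @return data.table of shift calls: `column_id`, `chrom`, `kind`,
#'   `anc_isotype`, `anc_anticodon`, `der_isotype`, `der_anticodon`,
#'   `branch`.
#' @export
classify_shifts <- function(columns, phy, taxa = phy$taxa) {
  out <- list()
  og <- phy$outgroup
  for (i in seq_len(nrow(columns))) {
    iso <- stats::setNames(unlist(columns[i, paste0(taxa, "_iso"), with = FALSE]), taxa)
    ac <- stats::setNames(unlist(columns[i, paste0(taxa, "_ac"), with = FALSE]), taxa)
    obs <- taxa[!is.na(ac)]
    if (length(obs) < 2L || length(unique(ac[obs])) < 2L) next
    kind <- if (length(unique(iso[obs])) == 1L) "isoacceptor" else "alloacceptor"
    if (og %in% obs) {
      anc_ac <- ac[[og]]; anc_iso <- iso[[og]]
      derived <- obs[ac[obs] != anc_ac]
      d <- dollo_branch(phy, derived = derived, observed = obs)
      br <- d$branch
      der_ac <- paste(unique(ac[derived]), collapse = ",")
      der_iso <- paste(unique(iso[derived]), collapse = ",")
    } else {
      states <- table(ac[obs])
      anc_ac <- names(states)[which.max(states)]
      anc_iso <- iso[obs][ac[obs] == anc_ac][1]
      derived <- obs[ac[obs] != anc_ac]
      br <- NA_character_
      der_ac <- paste(unique(ac[derived]), collapse = ",")
      der_iso <- paste(unique(iso[derived]), collapse = ",")
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      column_id = columns$column_id[i], chrom = columns$chrom[i], kind = kind,
      anc_isotype = anc_iso, anc_anticodon = anc_ac,
      der_isotype = der_iso, der_anticodon = der_ac, branch = br)
  }
  if (!length(out)) return(data.table::data.table(
    column_id = integer(), chrom = character(), kind = character(),
    anc_isotype = character(), anc_anticodon = character(),
    der_isotype = character(), der_anticodon = character(),
    branch = character()))
  data.table::rbindlist(out)
}
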