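# Genome-state edit engine.
#
# A genome state bundles chromosome sequences with annotation tables and an
# edit log. Every structural edit goes through seq_insert / seq_delete /
# seq_invert, which update the sequence, every annotation table, the carried
# planted-event coordinates, and the op log in one step, so coordinates can
# always be lifted between the ancestral and any derived frame.
#
# Coordinates are 0-based half-open everywhere internally.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# tables holding (start, end) interval columns that move with sequence edits
.STATE_TABLES <- c("exons", "trnas", "repeats", "compartments", "events")

new_genome_state <- function(seq) {
  empty <- function(...) data.table::data.table(...)
  list(
    seq = as.list(seq),
    genes = empty(gene_id = character(), chrom = character(), strand = character(),
                  cds_start = numeric(), cds_end = numeric()),
    exons = empty(gene_id = character(), chrom = character(), strand = character(),
                  exon_rank = integer(), start = numeric(), end = numeric()),
    trnas = empty(trna_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), strand = character(), isotype = character(),
                  anticodon = character(), pseudogene = logical(),
                  cluster_id = character()),
    repeats = empty(repeat_id = character(), chrom = character(), start = numeric(),
                    end = numeric(), strand = character(), family = character(),
                    class = character()),
    compartments = empty(chrom = character(), start = numeric(), end = numeric(),
                         name = character()),
    events = empty(event_id = character(), type = character(), branch = character(),
                   chrom = character(), start = numeric(), end = numeric()),
    ops = empty(op = character(), chrom = character(), s = numeric(), e = numeric())
  )
}

chrom_len <- function(state, chrom) nchar(state$seq[[chrom]])

# deep copy: data.tables are modified by reference in the edit ops, so a
# branch must never share tables with its parent state
copy_state <- function(state) {
  for (nm in names(state))
    if (data.table::is.data.table(state[[nm]]))
      state[[nm]] <- data.table::copy(state[[nm]])
  state
}

# shift an interval pair for an insertion of `len` bp at `pos`
.ins_shift <- function(start, end, pos, len) {
  grow <- start < pos & end > pos
  move <- start >= pos
  start[move] <- start[move] + len
  end[move] <- end[move] + len
  end[grow] <- end[grow] + len
  list(start = start, end = end)
}

seq_insert <- function(state, chrom, pos, insseq) {
  len <- nchar(insseq)
  s <- state$seq[[chrom]]
  stopifnot(pos >= 0, pos <= nchar(s))
  state$seq[[chrom]] <- paste0(substr(s, 1L, pos), insseq,
                               substr(s, pos + 1L, nchar(s)))
  for (tb in .STATE_TABLES) {
    dt <- state[[tb]]
    idx <- which(dt$chrom == chrom)
    if (length(idx)) {
      up <- .ins_shift(dt$start[idx], dt$end[idx], pos, len)
      data.table::set(dt, idx, "start", up$start)
      data.table::set(dt, idx, "end", up$end)
    }
  }
  gi <- which(state$genes$chrom == chrom)
  if (length(gi)) {
    up <- .ins_shift(state$genes$cds_start[gi], state$genes$cds_end[gi], pos, len)
    data.table::set(state$genes, gi, "cds_start", up$start)
    data.table::set(state$genes, gi, "cds_end", up$end)
  }
  state$ops <- rbind(state$ops,
                     data.table::data.table(op = "ins", chrom = chrom,
                                            s = pos, e = pos + len))
  state
}

# coordinate map for deletion of [s, e): p -> p - clamp(p - s, 0, e - s)
.del_map <- function(p, s, e) p - pmin(pmax(p - s, 0), e - s)

seq_delete <- function(state, chrom, s, e) {
  x <- state$seq[[chrom]]
  stopifnot(s >= 0, e <= nchar(x), s < e)
  state$seq[[chrom]] <- paste0(substr(x, 1L, s), substr(x, e + 1L, nchar(x)))
  for (tb in .STATE_TABLES) {
    dt <- state[[tb]]
    idx <- which(dt$chrom == chrom)
    if (length(idx)) {
      ns <- .del_map(dt$start[idx], s, e)
      ne <- .del_map(dt$end[idx], s, e)
      data.table::set(dt, idx, "start", ns)
      data.table::set(dt, idx, "end", ne)
      if (tb %in% c("trnas", "repeats")) {
        gone <- idx[ns == ne]
        if (length(gone)) state[[tb]] <- dt[-gone]
      }
    }
  }
  gi <- which(state$genes$chrom == chrom)
  if (length(gi)) {
    data.table::set(state$genes, gi, "cds_start", .del_map(state$genes$cds_start[gi], s, e))
    data.table::set(state$genes, gi, "cds_end", .del_map(state$genes$cds_end[gi], s, e))
  }
  state$ops <- rbind(state$ops,
                     data.table::data.table(op = "del", chrom = chrom, s = s, e = e))
  state
}

seq_invert <- function(state, chrom, s, e) {
  x <- state$seq[[chrom]]
  stopifnot(s >= 0, e <= nchar(x), s < e)
  state$seq[[chrom]] <- paste0(substr(x, 1L, s),
                               revcomp_chr(substr(x, s + 1L, e)),
                               substr(x, e + 1L, nchar(x)))
  flip_strand <- c("+" = "-", "-" = "+", "." = ".")
  for (tb in .STATE_TABLES) {
    dt <- state[[tb]]
    idx <- which(dt$chrom == chrom & dt$start >= s & dt$end <= e)
    if (length(idx)) {
      ns <- s + e - dt$end[idx]
      ne <- s + e - dt$start[idx]
      data.table::set(dt, idx, "start", ns)
      data.table::set(dt, idx, "end", ne)
      if ("strand" %in% names(dt))
        data.table::set(dt, idx, "strand", unname(flip_strand[dt$strand[idx]]))
    }
  }
  gi <- which(state$genes$chrom == chrom &
                state$genes$cds_start >= s & state$genes$cds_end <= e)
  if (length(gi)) {
    ns <- s + e - state$genes$cds_end[gi]
    ne <- s + e - state$genes$cds_start[gi]
    data.table::set(state$genes, gi, "cds_start", ns)
    data.table::set(state$genes, gi, "cds_end", ne)
    data.table::set(state$genes, gi, "strand",
                    unname(flip_strand[state$genes$strand[gi]]))
  }
  state$ops <- rbind(state$ops,
                     data.table::data.table(op = "inv", chrom = chrom, s = s, e = e))
  state
}

# Lift an interval forward through an op log (ancestral -> derived frame).
lift_interval <- function(ops, chrom, start, end) {
  for (i in seq_len(nrow(ops))) {
    if (ops$chrom[i] != chrom) next
    op <- ops$op[i]; s <- ops$s[i]; e <- ops$e[i]
    if (op == "ins") {
      len <- e - s
      if (start >= s) { start <- start + len; end <- end + len }
      else if (end > s) end <- end + len
    } else if (op == "del") {
      start <- .del_map(start, s, e)
      end <- .del_map(end, s, e)
    } else if (op == "inv") {
      if (start >= s && end <= e) {
        ns <- s + e - end; ne <- s + e - start
        start <- ns; end <- ne
      }
      # intervals straddling an inversion boundary keep their outer extent
    }
  }
  c(start = start, end = end)
}

# Reverse lift (derived -> ancestral frame). Positions born inside inserted
# material collapse to the insertion point.
unlift_interval <- function(ops, chrom, start, end) {
  for (i in rev(seq_len(nrow(ops)))) {
    if (ops$chrom[i] != chrom) next
    op <- ops$op[i]; s <- ops$s[i]; e <- ops$e[i]
    if (op == "ins") {
      start <- .del_map(start, s, e)
      end <- .del_map(end, s, e)
    } else if (op == "del") {
      len <- e - s
      if (start >= s) start <- start + len
      if (end > s) end <- end + len
    } else if (op == "inv") {
      if (start >= s && end <= e) {
        ns <- s + e - end; ne <- s + e - start
        start <- ns; end <- ne
      }
    }
  }
  c(start = start, end = end)
}

# Positions (0-based) overlapped by any feature interval on `chrom`,
# as an IRanges for fast membership tests.
.feature_ranges <- function(state, chrom,
                            tables = c("exons", "trnas", "repeats", "events")) {
  parts <- lapply(tables, function(tb) {
    dt <- state[[tb]]
    sel <- which(dt$chrom == chrom & dt$end > dt$start)
    if (!length(sel)) return(NULL)
    dt <- dt[sel, ]
    IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  })
  ex <- state$exons[which(state$exons$chrom == chrom), ]
  if (nrow(ex)) {
    spans <- ex[, list(s = min(start), e = max(end)), by = "gene_id"]
    parts <- c(parts, list(IRanges::IRanges(start = spans$s + 1L, end = spans$e)))
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(IRanges::IRanges())
  IRanges::reduce(do.call(c, parts))
}

# TRUE if [s, e) neither cuts a feature boundary nor partially overlaps one:
# every feature is fully inside or fully outside.
.interval_clean <- function(feat, s, e) {
  if (length(feat) == 0L) return(TRUE)
  q <- IRanges::IRanges(start = s + 1L, end = e)
  hits <- IRanges::findOverlaps(q, feat)
  if (length(hits) == 0L) return(TRUE)
  f <- feat[S4Vectors::subjectHits(hits)]
  all(IRanges::start(f) > s & IRanges::end(f) <= e)
}
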