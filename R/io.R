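# Readers and writers for the touched formats.
#
# Internal coordinates are 0-based half-open everywhere. GFF3 is emitted
# 1-based closed per the standard; BED is 0-based half-open. The BED dialect
# carries the repeat family in the name column and the repeat class in a 7th
# column.

#' Write a genome state to disk
#'
#' Emits, per taxon directory: `genome.fa` (FASTA), `genes.gff3` (gene,
#' mRNA, exon, CDS and tRNA features), `repeats.bed` (BED6 + class column),
#' `compartments.bed` (BED6, name = eu|het), `trnas.tsv`.
#'
#' @param state A genome state.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(unlist(state$seq))
  names(seqs) <- names(state$seq)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"), width = 80L)
  write_gff3(state, file.path(dir, "genes.gff3"))
  write_bed(state$repeats[, list(chrom, start, end, name = family,
                                 score = 0L, strand, class)],
            file.path(dir, "repeats.bed"))
  write_bed(state$compartments[, list(chrom, start, end, name,
                                      score = 0L, strand = ".")],
            file.path(dir, "compartments.bed"))
  write_tsv(state$trnas, file.path(dir, "trnas.tsv"))
  invisible(dir)
}

#' Read per-taxon outputs back into a genome state
#'
#' Inverse of [write_genome_state()] for the fields the pipeline consumes.
#'
#' @param dir Directory written by [write_genome_state()].
#' @return A genome state (without edit log or carried events).
#' @export
read_genome_state <- function(dir) {
  seqs <- read_fasta(file.path(dir, "genome.fa"))
  state <- new_genome_state(seqs)
  g <- read_gff3(file.path(dir, "genes.gff3"))
  state$genes <- g$genes
  state$exons <- g$exons
  state$trnas <- read_tsv(file.path(dir, "trnas.tsv"))
  rep_bed <- read_bed(file.path(dir, "repeats.bed"), extra = "class")
  state$repeats <- rep_bed[, list(repeat_id = paste0("r", seq_len(nrow(rep_bed))),
                                  chrom, start, end, strand, family = name, class)]
  comp <- read_bed(file.path(dir, "compartments.bed"))
  state$compartments <- comp[, list(chrom, start, end, name)]
  state
}

#' @rdname read_genome_state
#' @param path A file path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_genome_state
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

write_gff3 <- function(state, path) {
  rows <- list("##gff-version 3")
  ex <- data.table::as.data.table(state$exons)
  data.table::setorderv(ex, c("chrom", "start"))
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, ]
    gmeta <- state$genes[state$genes$gene_id == gid, ]
    s0 <- min(e$start); e0 <- max(e$end)
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tsyntevo\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      e$chrom[1], s0 + 1L, e0, e$strand[1], gid)
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tsyntevo\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
      e$chrom[1], s0 + 1L, e0, e$strand[1], gid, gid)
    for (i in seq_len(nrow(e))) {
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tsyntevo\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1;rank=%d",
        e$chrom[i], e$start[i] + 1L, e$end[i], e$strand[i], gid, e$exon_rank[i])
    }
    if (nrow(gmeta)) {
      cs <- gmeta$cds_start[1]; ce <- gmeta$cds_end[1]
      cds <- e[e$end > cs & e$start < ce, ]
      for (i in seq_len(nrow(cds))) {
        rows[[length(rows) + 1L]] <- sprintf(
          "%s\tsyntevo\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s.t1",
          cds$chrom[i], max(cds$start[i], cs) + 1L, min(cds$end[i], ce),
          cds$strand[i], gid)
      }
    }
  }
  tr <- state$trnas
  for (i in seq_len(nrow(tr))) {
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tsyntevo\ttRNA\t%d\t%d\t.\t%s\t.\tID=%s;isotype=%s;anticodon=%s;pseudogene=%d;cluster=%s",
      tr$chrom[i], tr$start[i] + 1L, tr$end[i], tr$strand[i], tr$trna_id[i],
      tr$isotype[i], tr$anticodon[i], as.integer(tr$pseudogene[i]), tr$cluster_id[i])
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) stop("empty GFF3: ", path)
  f <- data.table::fread(text = ln, sep = "\t", header = FALSE,
    col.names = c("chrom", "source", "type", "start1", "end1", "score",
                  "strand", "phase", "attr"))
  bad <- which(f$start1 > f$end1 | f$start1 < 1L)
  if (length(bad)) stop("malformed GFF3 record at ", path, " line ", bad[1])
  gattr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  ex <- f[f$type == "exon", ]
  exons <- data.table::data.table(
    gene_id = sub("\\.t1$", "", gattr(ex$attr, "Parent")),
    chrom = ex$chrom, strand = ex$strand,
    exon_rank = as.integer(gattr(ex$attr, "rank")),
    start = ex$start1 - 1, end = as.numeric(ex$end1))
  cds <- f[f$type == "CDS", ]
  genes <- data.table::data.table(gene_id = character(), chrom = character(),
                                  strand = character(), cds_start = numeric(),
                                  cds_end = numeric())
  if (nrow(cds)) {
    cds$gene_id <- sub("\\.t1$", "", gattr(cds$attr, "Parent"))
    genes <- cds[, list(chrom = chrom[1], strand = strand[1],
                        cds_start = min(start1) - 1, cds_end = as.numeric(max(end1))),
                 by = "gene_id"]
  }
  tr <- f[f$type == "tRNA", ]
  trnas <- data.table::data.table(
    trna_id = gattr(tr$attr, "ID"), chrom = tr$chrom,
    start = tr$start1 - 1, end = as.numeric(tr$end1), strand = tr$strand,
    isotype = gattr(tr$attr, "isotype"), anticodon = gattr(tr$attr, "anticodon"),
    pseudogene = gattr(tr$attr, "pseudogene") == "1",
    cluster_id = gattr(tr$attr, "cluster"))
  list(genes = genes, exons = exons, trnas = trnas)
}

#' @rdname read_genome_state
#' @param dt Interval table with columns chrom, start, end (0-based
#'   half-open) plus name/score/strand and optional extra columns.
#' @export
write_bed <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_genome_state
#' @param extra Names for columns beyond BED6.
#' @export
read_bed <- function(path, extra = character(0)) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", extra)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) stop("malformed BED (needs >= 3 columns): ", path)
  data.table::setnames(dt, cols[seq_len(ncol(dt))])
  if (any(dt$end < dt$start) || any(dt$start < 0))
    stop("malformed BED interval in ", path)
  dt
}

#' @rdname read_genome_state
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname read_genome_state
#' @export
read_tsv <- function(path) data.table::fread(path, sep = "\t")

#' Write simulated complex outputs
#'
#' One directory per taxon (see [write_genome_state()]) plus `truth.tsv`,
#' the planted-event ledger with one row per (event, taxon) giving derived
#' coordinates, and `taxa.tsv`.
#'
#' @param sim A `sim_complex`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_outputs <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_complex"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (t in names(sim$genomes))
    write_genome_state(sim$genomes[[t]], file.path(outdir, t))
  taxa_of <- function(branch) paste(
    Filter(function(t) branch %in% taxon_path(sim$phylogeny, t),
           sim$phylogeny$taxa), collapse = ",")
  tt <- data.table::copy(sim$truth)
  tt$taxon_list <- vapply(tt$branch, taxa_of, character(1))
  write_tsv(tt[, list(event_id, type, branch, taxon_list, chrom,
                      start = anc_start, end = anc_end, payload)],
            file.path(outdir, "truth.tsv"))
  write_tsv(data.table::data.table(taxon = names(sim$genomes)),
            file.path(outdir, "taxa.tsv"))
  invisible(outdir)
}

#' Export an alignment map as PAF
#'
#' One PAF line per synteny block: query name/length/start/end, strand,
#' reference (target) name/length/start/end, residue matches (anchored bp),
#' alignment block length, mapping quality 255.
#'
#' @param map An `alignment_map`.
#' @param path Output path.
#' @export
write_paf <- function(map, path) {
  b <- map$blocks
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255",
                   b$qry_chrom, as.integer(map$qry_len[b$qry_chrom]),
                   as.integer(b$qry_start), as.integer(b$qry_end),
                   ifelse(b$strand == 1L, "+", "-"),
                   b$ref_chrom, as.integer(map$ref_len[b$ref_chrom]),
                   as.integer(b$ref_start), as.integer(b$ref_end),
                   as.integer(b$anchored_bp),
                   as.integer(b$ref_end - b$ref_start))
  writeLines(lines, path)
  invisible(path)
}
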