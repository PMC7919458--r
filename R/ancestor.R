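#' Simulate an ancestral genome
#'
#' Builds the root genome of the species complex: random background
#' chromosomes with a terminal (pericentromeric) heterochromatin compartment,
#' euchromatic protein-coding genes with exon/intron structure and CDS
#' bounds, tRNA genes grouped in clusters with isotype and anticodon written
#' into the sequence, heterochromatic satellite arrays, and ancestral TE
#' copies drawn from per-class family consensus sequences.
#'
#' @param cfg An [evolution_config()].
#' @return A genome state: a list with `seq` (named chromosome strings),
#'   annotation tables (`genes`, `exons`, `trnas`, `repeats`,
#'   `compartments`), the carried `events` table (empty here), the edit-op
#'   log `ops`, and the TE family/satellite monomer reference tables.
#' @export
simulate_ancestor <- function(cfg) {
  stopifnot(inherits(cfg, "evolution_config"))
  set.seed(substream_seed(cfg$seed, "ancestor"))

  chroms <- names(cfg$chrom_lengths)
  state <- new_genome_state(
    stats::setNames(lapply(cfg$chrom_lengths, random_dna), chroms))

  # compartments: euchromatic arm, then terminal heterochromatin
  comp <- data.table::rbindlist(lapply(chroms, function(ch) {
    L <- cfg$chrom_lengths[[ch]]
    eu_end <- round(L * (1 - cfg$het_fraction))
    data.table::data.table(chrom = ch,
                           start = c(0, eu_end), end = c(eu_end, L),
                           name = c("eu", "het"))
  }))
  state$compartments <- comp[comp$end > comp$start, ]

  # --- euchromatic slot layout: genes and tRNA clusters share the arm -----
  eu <- state$compartments[state$compartments$name == "eu", ]
  eu_len <- stats::setNames(eu$end - eu$start, eu$chrom)
  n_genes_c <- .proportional_counts(cfg$n_genes, eu_len)
  n_clust_c <- .proportional_counts(cfg$n_trna_clusters, eu_len)
  trnas_per_cluster <- .proportional_counts(cfg$n_trnas, rep(1, cfg$n_trna_clusters))

  gene_i <- 0L
  clust_i <- 0L
  for (ch in chroms) {
    nslot <- n_genes_c[[ch]] + n_clust_c[[ch]]
    if (nslot == 0L) next
    slot_w <- floor(eu_len[[ch]] / nslot)
    kind <- sample(c(rep("gene", n_genes_c[[ch]]), rep("trna", n_clust_c[[ch]])))
    for (k in seq_len(nslot)) {
      slot_start <- eu[eu$chrom == ch, ]$start[1] + (k - 1L) * slot_w
      if (kind[k] == "gene") {
        gene_i <- gene_i + 1L
        state <- .place_gene(state, cfg, ch, slot_start, slot_w,
                             sprintf("g%04d", gene_i))
      } else {
        clust_i <- clust_i + 1L
        state <- .place_trna_cluster(state, cfg, ch, slot_start, slot_w,
                                     sprintf("cl%02d", clust_i),
                                     trnas_per_cluster[clust_i])
      }
    }
  }

  # --- satellite arrays in heterochromatin --------------------------------
  het <- state$compartments[state$compartments$name == "het", ]
  state$sat_monomers <- data.table::data.table(family = character(),
                                               monomer = character())
  if (nrow(het) && cfg$n_satellites > 0L) {
    het_len <- stats::setNames(het$end - het$start, het$chrom)
    n_sat_c <- .proportional_counts(cfg$n_satellites, het_len)
    sat_i <- 0L
    for (ch in names(n_sat_c)) {
      ns <- n_sat_c[[ch]]
      if (ns == 0L) next
      h <- het[het$chrom == ch, ]
      slot_w <- floor((h$end - h$start) / ns)
      for (k in seq_len(ns)) {
        sat_i <- sat_i + 1L
        mono_len <- sample(cfg$satellite_monomer_range[1]:cfg$satellite_monomer_range[2], 1L)
        copies <- sample(cfg$satellite_copy_range[1]:cfg$satellite_copy_range[2], 1L)
        fam <- sprintf("sat%d_%02d", mono_len, sat_i)
        monomer <- random_dna(mono_len)
        arr <- paste(rep(monomer, copies), collapse = "")
        # het moves as earlier insertions grow the chromosome: recompute
        h_now <- state$compartments[state$compartments$chrom == ch &
                                      state$compartments$name == "het", ]
        pos <- h_now$start + (k - 1L) * slot_w +
          sample.int(max(slot_w - nchar(arr) - 1L, 1L), 1L)
        if (pos + nchar(arr) > h_now$end)
          stop("satellite placement failure: heterochromatin too small for ",
               "requested arrays")
        state <- seq_insert(state, ch, pos, arr)
        state$repeats <- rbind(state$repeats, data.table::data.table(
          repeat_id = sprintf("anc_sat_%03d", sat_i), chrom = ch,
          start = pos, end = pos + nchar(arr), strand = "+",
          family = fam, class = "satellite"))
        state$sat_monomers <- rbind(state$sat_monomers,
                                    data.table::data.table(family = fam, monomer = monomer))
      }
    }
  }

  # --- TE family consensus library ----------------------------------------
  fams <- data.table::rbindlist(lapply(names(cfg$ancestral_te_mix), function(cl) {
    data.table::data.table(
      family = sprintf("%s_fam%d", cl, seq_len(cfg$te_families_per_class)),
      class = cl,
      consensus = vapply(seq_len(cfg$te_families_per_class), function(i)
        random_dna(min(round(exp(cfg$te_length_meanlog[[cl]] +
                                   2.5 * cfg$te_length_sdlog[[cl]])), 20000L)),
        character(1)))
  }))
  state$te_families <- fams

  # --- ancestral TE copies -------------------------------------------------
  for (i in seq_len(cfg$ancestral_te_count)) {
    state <- .insert_te(state, cfg,
                        class_mix = cfg$ancestral_te_mix,
                        exonic = cfg$ancestral_te_exonic,
                        intronic = cfg$ancestral_te_intronic,
                        repeat_id = sprintf("anc_te_%04d", i))
  }

  state
}

# integer counts proportional to weights, preserving the total
.proportional_counts <- function(total, weights) {
  if (total == 0L) return(stats::setNames(rep(0L, length(weights)), names(weights)))
  raw <- total * weights / sum(weights)
  n <- floor(raw)
  rem <- total - sum(n)
  if (rem > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1L
  }
  stats::setNames(as.integer(n), names(weights))
}

.place_gene <- function(state, cfg, ch, slot_start, slot_w, gene_id) {
  n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
  ex_len <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2], n_ex, replace = TRUE)
  in_len <- sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
                   n_ex - 1L, replace = TRUE)
  span <- sum(ex_len) + sum(in_len)
  if (span + 200L > slot_w)
    stop("gene placement failure: requested gene density exceeds euchromatin ",
         "size (gene span ", span, " bp vs slot ", slot_w, " bp)")
  start <- slot_start + sample.int(slot_w - span - 100L, 1L)
  strand <- sample(c("+", "-"), 1L)
  starts <- start + cumsum(c(0L, head_int(ex_len, -1L) + in_len))
  ends <- starts + ex_len
  ranks <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  state$exons <- rbind(state$exons, data.table::data.table(
    gene_id = gene_id, chrom = ch, strand = strand, exon_rank = ranks,
    start = starts, end = ends))
  u5 <- sample(10:60, 1L); u3 <- sample(10:60, 1L)
  state$genes <- rbind(state$genes, data.table::data.table(
    gene_id = gene_id, chrom = ch, strand = strand,
    cds_start = start + min(u5, ex_len[1] - 10L),
    cds_end = ends[n_ex] - min(u3, ex_len[n_ex] - 10L)))
  state
}

.place_trna_cluster <- function(state, cfg, ch, slot_start, slot_w, cluster_id, n) {
  if (n == 0L) return(state)
  gene_len <- 72L
  gaps <- sample(100:600, n, replace = TRUE)
  span <- n * gene_len + sum(gaps)
  if (span + 100L > slot_w)
    stop("tRNA cluster placement failure: cluster span exceeds slot")
  pos <- slot_start + sample.int(slot_w - span - 50L, 1L)
  main_strand <- sample(c("+", "-"), 1L)
  for (j in seq_len(n)) {
    start <- pos + (j - 1L) * gene_len + sum(gaps[seq_len(j - 1L)])
    strand <- if (stats::runif(1) < 0.8) main_strand else setdiff(c("+", "-"), main_strand)
    aa <- sample(setdiff(unique(GENETIC_CODE_AA), "*"), 1L)
    anticodon <- sample(aa_anticodons(aa), 1L)
    id <- sprintf("%s_t%02d", cluster_id, j)
    state$trnas <- rbind(state$trnas, data.table::data.table(
      trna_id = id, chrom = ch, start = start, end = start + gene_len,
      strand = strand, isotype = aa, anticodon = anticodon,
      pseudogene = stats::runif(1) < 0.05, cluster_id = cluster_id))
    state <- write_anticodon(state, ch, start, start + gene_len, strand, anticodon)
  }
  state
}

# anticodon occupies offsets [33, 36) of the 72-bp gene, in gene orientation
write_anticodon <- function(state, ch, start, end, strand, anticodon) {
  s <- state$seq[[ch]]
  if (strand == "+") {
    substr(s, start + 34L, start + 36L) <- anticodon
  } else {
    substr(s, end - 35L, end - 33L) <- revcomp_chr(anticodon)
  }
  state$seq[[ch]] <- s
  state
}

read_anticodon <- function(state, ch, start, end, strand) {
  s <- state$seq[[ch]]
  if (strand == "+") substr(s, start + 34L, start + 36L)
  else revcomp_chr(substr(s, end - 35L, end - 33L))
}

# Insert one TE copy; returns the updated state with an attribute
# "last_te" = list(chrom, pos, len, class, family, target).
.insert_te <- function(state, cfg, class_mix, exonic, intronic, repeat_id,
                       strand = sample(c("+", "-"), 1L)) {
  cl <- sample(names(class_mix), 1L, prob = class_mix)
  fams <- state$te_families[state$te_families$class == cl, ]
  fam <- fams[sample.int(nrow(fams), 1L), ]
  len <- round(stats::rlnorm(1, cfg$te_length_meanlog[[cl]], cfg$te_length_sdlog[[cl]]))
  len <- max(100L, min(len, nchar(fam$consensus)))
  teseq <- mutate_seq(substr(fam$consensus, 1L, len), cfg$te_copy_noise)
  if (strand == "-") teseq <- revcomp_chr(teseq)

  u <- stats::runif(1)
  target <- if (u < exonic && nrow(state$exons)) "exonic"
            else if (u < exonic + intronic) "intronic"
            else "intergenic"
  pos <- NULL
  if (target == "exonic") {
    ex <- state$exons[sample.int(nrow(state$exons), 1L), ]
    pos <- list(chrom = ex$chrom,
                p = ex$start + sample.int(max(ex$end - ex$start - 20L, 1L), 1L) + 10L)
  } else if (target == "intronic") {
    intr <- state_introns(state)
    intr <- intr[intr$end - intr$start > 40L, ]
    if (nrow(intr)) {
      it <- intr[sample.int(nrow(intr), 1L), ]
      pos <- list(chrom = it$chrom,
                  p = it$start + sample.int(it$end - it$start - 20L, 1L) + 10L)
    } else target <- "intergenic"
  }
  if (is.null(pos)) {
    target <- "intergenic"
    for (try in 1:50) {
      ch <- sample(names(state$seq), 1L,
                   prob = vapply(state$seq, nchar, numeric(1)))
      p <- sample.int(nchar(state$seq[[ch]]) - 1L, 1L)
      feat <- .feature_ranges(state, ch)
      if (length(feat) == 0L || !any(IRanges::overlapsAny(
            IRanges::IRanges(p + 1L, p + 1L), feat))) {
        pos <- list(chrom = ch, p = p)
        break
      }
    }
    if (is.null(pos)) return(state)   # could not place; caller may warn
  }
  state <- seq_insert(state, pos$chrom, pos$p, teseq)
  state$repeats <- rbind(state$repeats, data.table::data.table(
    repeat_id = repeat_id, chrom = pos$chrom, start = pos$p,
    end = pos$p + nchar(teseq), strand = strand, family = fam$family, class = cl))
  attr(state, "last_te") <- list(chrom = pos$chrom, pos = pos$p, len = nchar(teseq),
                                 class = cl, family = fam$family, target = target)
  state
}

# random substitutions at a given per-base probability (sequence decay noise)
mutate_seq <- function(x, p) {
  if (p <= 0) return(x)
  n <- nchar(x)
  k <- stats::rbinom(1, n, p)
  if (k == 0) return(x)
  pos <- sample.int(n, k)
  r <- charToRaw(x)
  cur <- rawToChar(r[pos], multiple = TRUE)
  new <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), character(1))
  r[pos] <- charToRaw(paste(new, collapse = ""))
  rawToChar(r)
}

#' Enumerate introns of a genome state
#'
#' Introns are the gaps between consecutive exons of a gene; `intron_rank`
#' follows transcription order (rank 1 is nearest the 5' end).
#'
#' @param state A genome state.
#' @return data.table: `gene_id`, `chrom`, `strand`, `intron_rank`, `start`,
#'   `end`.
#' @export
state_introns <- function(state) {
  ex <- data.table::as.data.table(state$exons)
  if (!nrow(ex)) return(data.table::data.table(
    gene_id = character(), chrom = character(), strand = character(),
    intron_rank = integer(), start = numeric(), end = numeric()))
  data.table::setorderv(ex, c("gene_id", "start"))
  intr <- ex[, {
    if (.N < 2L) NULL
    else {
      s <- end[-.N]; e <- start[-1L]
      rk <- if (strand[1] == "+") seq_len(.N - 1L) else rev(seq_len(.N - 1L))
      list(chrom = chrom[1], strand = strand[1], intron_rank = rk,
           start = s, end = e)
    }
  }, by = "gene_id"]
  intr[intr$end > intr$start, ]
}

head_int <- function(x, n) utils::head(x, n)
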