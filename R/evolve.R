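#' Evolve an ancestral genome along the species phylogeny
#'
#' Applies per-branch structural events (TE insertions, inversions, tandem
#' and dispersed duplications, satellite expansions/contractions, tRNA
#' cluster mutations, intron indels) followed by Jukes-Cantor substitutions,
#' along every root-to-tip path of the phylogeny. Event counts are Poisson
#' with mean rate x branch Myr x genome Mb; every (branch, event type) draws
#' from its own named RNG substream, so outputs are byte-reproducible and
#' changing one rate leaves other draws untouched. Events that cannot be
#' placed after bounded retries are skipped with a warning and excluded from
#' the truth ledger.
#'
#' @param ancestor A genome state from [simulate_ancestor()].
#' @param phy A [phylogeny()]; branch names must include the config's rate
#'   names.
#' @param cfg The [evolution_config()] used for the ancestor.
#' @return A list of class `sim_complex`: `genomes` (named genome states,
#'   one per taxon), `truth` (the planted-event ledger with ancestral-frame
#'   coordinates and payloads), `phylogeny`, `config`.
#' @export
evolve_tree <- function(ancestor, phy, cfg) {
  stopifnot(inherits(phy, "phylogeny"), inherits(cfg, "evolution_config"))
  env <- new.env(parent = emptyenv())
  env$streams <- list()
  env$truth <- list()
  env$counter <- 0L

  stem_state <- apply_branch(ancestor, "stem", phy, cfg, env)
  genomes <- list()
  for (t in phy$ingroup) genomes[[t]] <- apply_branch(stem_state, t, phy, cfg, env)
  genomes[[phy$reference]] <- apply_branch(ancestor, phy$reference, phy, cfg, env)
  genomes[[phy$outgroup]] <- apply_branch(ancestor, phy$outgroup, phy, cfg, env)

  truth <- if (length(env$truth)) data.table::rbindlist(env$truth)
           else data.table::data.table(event_id = character(), type = character(),
                                       branch = character(), chrom = character(),
                                       anc_start = numeric(), anc_end = numeric(),
                                       payload = character())
  structure(list(genomes = genomes, truth = truth, phylogeny = phy, config = cfg),
            class = "sim_complex")
}

#' @export
print.sim_complex <- function(x, ...) {
  cat("sim_complex:", length(x$genomes), "taxa (",
      paste(names(x$genomes), collapse = ", "), ")\n")
  cat("  planted events:", nrow(x$truth), "\n")
  if (nrow(x$truth)) print(table(x$truth$branch, x$truth$type))
  invisible(x)
}

# evaluate expr under the named RNG substream, preserving other streams
with_stream <- function(env, seed, tag, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  if (is.null(env$streams[[tag]])) set.seed(substream_seed(seed, tag))
  else assign(".Random.seed", env$streams[[tag]], globalenv())
  res <- expr
  env$streams[[tag]] <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (had) assign(".Random.seed", old, globalenv())
  res
}

.EVENT_TYPES <- c("te_insertion", "inversion", "tandem_dup", "dispersed_dup",
                  "satellite_change", "trna_dup", "trna_del", "trna_anticodon",
                  "intron_indel")

.event_rate <- function(cfg, type, branch) {
  r <- switch(type,
    te_insertion = cfg$te_rate, inversion = cfg$inversion_rate,
    tandem_dup = cfg$tandem_dup_rate, dispersed_dup = cfg$dispersed_dup_rate,
    satellite_change = cfg$satellite_change_rate, trna_dup = cfg$trna_dup_rate,
    trna_del = cfg$trna_del_rate, trna_anticodon = cfg$trna_anticodon_rate,
    intron_indel = cfg$intron_indel_rate)
  branch_rate(r, branch)
}

apply_branch <- function(state, branch, phy, cfg, env) {
  state <- copy_state(state)
  dur <- phy$branches[[branch]]
  mb <- sum(vapply(state$seq, nchar, numeric(1))) / 1e6

  counts <- vapply(.EVENT_TYPES, function(ty)
    with_stream(env, cfg$seed, paste0(branch, ":", ty, ":count"),
                stats::rpois(1L, .event_rate(cfg, ty, branch) * dur * mb)),
    numeric(1))
  queue <- rep(.EVENT_TYPES, counts)
  queue <- with_stream(env, cfg$seed, paste0(branch, ":order"),
                       if (length(queue)) sample(queue) else queue)

  for (ty in queue) {
    res <- with_stream(env, cfg$seed, paste0(branch, ":", ty),
                       apply_event(state, ty, branch, cfg))
    if (is.null(res)) {
      warning("branch ", branch, ": could not place ", ty, " event; skipped",
              call. = FALSE)
      next
    }
    state <- res$state
    if (!is.null(res$truth)) {
      env$counter <- env$counter + 1L
      res$truth$event_id <- sprintf("ev%04d", env$counter)
      # carried coordinates ride along with the state
      state$events <- rbind(state$events, data.table::data.table(
        event_id = res$truth$event_id, type = res$truth$type, branch = branch,
        chrom = res$truth$chrom, start = res$carried[1], end = res$carried[2]))
      env$truth[[length(env$truth) + 1L]] <- res$truth
    }
  }

  with_stream(env, cfg$seed, paste0(branch, ":subs"),
              apply_substitutions(state, branch, cfg, dur))
}

apply_event <- function(state, type, branch, cfg) {
  switch(type,
    te_insertion = ev_te_insertion(state, branch, cfg),
    inversion = ev_inversion(state, branch, cfg),
    tandem_dup = ev_tandem_dup(state, branch, cfg),
    dispersed_dup = ev_dispersed_dup(state, branch, cfg),
    satellite_change = ev_satellite_change(state, branch, cfg),
    trna_dup = ev_trna_dup(state, branch, cfg),
    trna_del = ev_trna_del(state, branch, cfg),
    trna_anticodon = ev_trna_anticodon(state, branch, cfg),
    intron_indel = ev_intron_indel(state, branch, cfg))
}

.truth_row <- function(state, type, branch, chrom, start, end, payload) {
  anc <- unlift_interval(state$ops, chrom, start, end)
  data.table::data.table(event_id = NA_character_, type = type, branch = branch,
                         chrom = chrom, anc_start = anc[[1]], anc_end = anc[[2]],
                         payload = payload)
}

ev_te_insertion <- function(state, branch, cfg) {
  mix <- if (branch == "stem") cfg$te_class_mix$stem else cfg$te_class_mix$default
  n0 <- nrow(state$repeats)
  state2 <- .insert_te(state, cfg, class_mix = mix,
                       exonic = cfg$te_exonic, intronic = cfg$te_intronic,
                       repeat_id = sprintf("%s_te_%04d", branch, n0 + 1L))
  info <- attr(state2, "last_te")
  if (nrow(state2$repeats) == n0) return(NULL)
  attr(state2, "last_te") <- NULL
  payload <- sprintf("class=%s;family=%s;len=%d;target=%s",
                     info$class, info$family, info$len, info$target)
  tr <- .truth_row(state, "te_insertion", branch, info$chrom,
                   info$pos, info$pos, payload)
  list(state = state2, truth = tr, carried = c(info$pos, info$pos + info$len))
}

# compartment-weighted placement of a clean interval; NULL after 50 tries
.sample_clean_interval <- function(state, cfg, len_range, het_weighted = TRUE,
                                   eu_only = FALSE, log_uniform = TRUE,
                                   forbid_trna = TRUE) {
  comp <- state$compartments
  if (eu_only) comp <- comp[comp$name == "eu", ]
  w <- (comp$end - comp$start) *
    ifelse(het_weighted & comp$name == "het", cfg$het_multiplier, 1)
  for (try in 1:50) {
    ci <- sample.int(nrow(comp), 1L, prob = w)
    seg <- comp[ci, ]
    L <- if (log_uniform) round(exp(stats::runif(1, log(len_range[1]), log(len_range[2]))))
         else round(stats::runif(1, len_range[1], len_range[2]))
    L <- min(L, seg$end - seg$start - 2L)
    if (L < len_range[1]) next
    s <- seg$start + sample.int(seg$end - seg$start - L, 1L)
    e <- s + L
    feat <- .feature_ranges(state, seg$chrom)
    if (!.interval_clean(feat, s, e)) next
    if (forbid_trna) {
      tr <- state$trnas[state$trnas$chrom == seg$chrom, ]
      if (nrow(tr) && any(tr$start < e & tr$end > s)) next
    }
    return(list(chrom = seg$chrom, s = s, e = e, compartment = seg$name))
  }
  NULL
}

ev_inversion <- function(state, branch, cfg) {
  iv <- .sample_clean_interval(state, cfg, cfg$inversion_length_range,
                               het_weighted = TRUE, forbid_trna = FALSE)
  if (is.null(iv)) return(NULL)
  tr <- .truth_row(state, "inversion", branch, iv$chrom, iv$s, iv$e,
                   sprintf("compartment=%s;len=%d", iv$compartment, iv$e - iv$s))
  state <- seq_invert(state, iv$chrom, iv$s, iv$e)
  list(state = state, truth = tr, carried = c(iv$s, iv$e))
}

ev_tandem_dup <- function(state, branch, cfg) {
  copies <- if (stats::runif(1) < cfg$tandem_extra_copy_prob) 3L else 2L
  L <- round(stats::rlnorm(1, cfg$tandem_dup_meanlog, cfg$tandem_dup_sdlog))
  iv <- .sample_clean_interval(state, cfg, c(max(100L, L), max(101L, L + 1L)),
                               het_weighted = FALSE, eu_only = TRUE,
                               log_uniform = FALSE)
  if (is.null(iv)) return(NULL)
  len <- iv$e - iv$s
  donor_seq <- substr(state$seq[[iv$chrom]], iv$s + 1L, iv$e)
  tr <- .truth_row(state, "tandem_dup", branch, iv$chrom, iv$s, iv$e,
                   sprintf("copies=%d;len=%d", copies, len))
  inner <- state$repeats[state$repeats$chrom == iv$chrom &
                           state$repeats$start >= iv$s & state$repeats$end <= iv$e, ]
  state <- seq_insert(state, iv$chrom, iv$e,
                      paste(rep(donor_seq, copies - 1L), collapse = ""))
  if (nrow(inner)) {
    for (j in seq_len(copies - 1L)) {
      cp <- data.table::copy(inner)
      cp$start <- cp$start + j * len
      cp$end <- cp$end + j * len
      cp$repeat_id <- paste0(cp$repeat_id, "_tdup", j)
      state$repeats <- rbind(state$repeats, cp)
    }
  }
  list(state = state, truth = tr, carried = c(iv$s, iv$e + (copies - 1L) * len))
}

ev_dispersed_dup <- function(state, branch, cfg) {
  L <- round(stats::rlnorm(1, cfg$tandem_dup_meanlog, cfg$tandem_dup_sdlog))
  iv <- .sample_clean_interval(state, cfg, c(max(100L, L), max(101L, L + 1L)),
                               het_weighted = FALSE, eu_only = TRUE,
                               log_uniform = FALSE)
  if (is.null(iv)) return(NULL)
  len <- iv$e - iv$s
  donor_seq <- substr(state$seq[[iv$chrom]], iv$s + 1L, iv$e)
  rc <- stats::runif(1) < 0.5
  if (rc) donor_seq <- revcomp_chr(donor_seq)
  acc <- NULL
  for (try in 1:50) {
    ch <- sample(names(state$seq), 1L, prob = vapply(state$seq, nchar, numeric(1)))
    p <- sample.int(nchar(state$seq[[ch]]) - 1L, 1L)
    if (ch == iv$chrom && p >= iv$s - 100 && p <= iv$e + 100) next
    feat <- .feature_ranges(state, ch)
    if (length(feat) && any(IRanges::overlapsAny(IRanges::IRanges(p + 1L, p + 1L), feat)))
      next
    acc <- list(chrom = ch, p = p)
    break
  }
  if (is.null(acc)) return(NULL)
  tr <- .truth_row(state, "dispersed_dup", branch, iv$chrom, iv$s, iv$e,
                   sprintf("len=%d;acc_chrom=%s;acc_pos=%d;revcomp=%d",
                           len, acc$chrom, acc$p, as.integer(rc)))
  inner <- state$repeats[state$repeats$chrom == iv$chrom &
                           state$repeats$start >= iv$s & state$repeats$end <= iv$e, ]
  state <- seq_insert(state, acc$chrom, acc$p, donor_seq)
  if (nrow(inner) && !rc) {
    cp <- data.table::copy(inner)
    cp$start <- acc$p + (cp$start - iv$s)
    cp$end <- acc$p + (cp$end - iv$s)
    cp$repeat_id <- paste0(cp$repeat_id, "_ddup")
    state$repeats <- rbind(state$repeats, cp)
  }
  list(state = state, truth = tr, carried = c(iv$s, iv$e))
}

ev_satellite_change <- function(state, branch, cfg) {
  sats <- state$repeats[state$repeats$class == "satellite", ]
  if (!nrow(sats)) return(NULL)
  row <- sats[sample.int(nrow(sats), 1L), ]
  mono <- state$sat_monomers$monomer[state$sat_monomers$family == row$family]
  if (!length(mono)) return(NULL)
  m <- nchar(mono[1])
  copies <- floor((row$end - row$start) / m)
  expand <- stats::runif(1) < 0.5
  if (!expand && copies < 10L) expand <- TRUE
  if (expand) {
    k <- sample(5:30, 1L)
    at <- row$start + m * sample.int(max(copies - 1L, 1L), 1L)
    tr <- .truth_row(state, "satellite_change", branch, row$chrom, at, at,
                     sprintf("family=%s;delta_copies=%d", row$family, k))
    state <- seq_insert(state, row$chrom, at, paste(rep(mono[1], k), collapse = ""))
    carried <- c(at, at + k * m)
  } else {
    k <- sample(3:min(15L, copies - 5L), 1L)
    i0 <- sample.int(copies - k, 1L)
    s <- row$start + m * i0
    e <- s + m * k
    tr <- .truth_row(state, "satellite_change", branch, row$chrom, s, e,
                     sprintf("family=%s;delta_copies=%d", row$family, -k))
    state <- seq_delete(state, row$chrom, s, e)
    carried <- c(s, s)
  }
  list(state = state, truth = tr, carried = carried)
}

ev_trna_dup <- function(state, branch, cfg) {
  if (!nrow(state$trnas)) return(NULL)
  g <- state$trnas[sample.int(nrow(state$trnas), 1L), ]
  gene_seq <- substr(state$seq[[g$chrom]], g$start + 1L, g$end)
  spacer <- random_dna(sample(50:200, 1L))
  tr <- .truth_row(state, "trna_change", branch, g$chrom, g$end, g$end,
                   sprintf("kind=dup;trna=%s;isotype=%s;anticodon=%s",
                           g$trna_id, g$isotype, g$anticodon))
  ins <- paste0(spacer, gene_seq)
  state <- seq_insert(state, g$chrom, g$end, ins)
  new_start <- g$end + nchar(spacer)
  state$trnas <- rbind(state$trnas, data.table::data.table(
    trna_id = paste0(g$trna_id, "_", branch, "dup"), chrom = g$chrom,
    start = new_start, end = new_start + (g$end - g$start), strand = g$strand,
    isotype = g$isotype, anticodon = g$anticodon, pseudogene = g$pseudogene,
    cluster_id = g$cluster_id))
  list(state = state, truth = tr, carried = c(new_start, new_start + (g$end - g$start)))
}

ev_trna_del <- function(state, branch, cfg) {
  if (nrow(state$trnas) < 2L) return(NULL)
  g <- state$trnas[sample.int(nrow(state$trnas), 1L), ]
  tr <- .truth_row(state, "trna_change", branch, g$chrom, g$start, g$end,
                   sprintf("kind=del;trna=%s;isotype=%s;anticodon=%s",
                           g$trna_id, g$isotype, g$anticodon))
  state <- seq_delete(state, g$chrom, g$start, g$end)
  list(state = state, truth = tr, carried = c(g$start, g$start))
}

ev_trna_anticodon <- function(state, branch, cfg) {
  cand <- state$trnas[!state$trnas$pseudogene, ]
  if (!nrow(cand)) return(NULL)
  g <- cand[sample.int(nrow(cand), 1L), ]
  nb <- anticodon_neighbors(g$anticodon)
  want_allo <- stats::runif(1) < cfg$trna_allo_prob
  pool <- if (want_allo) nb$allo else nb$iso
  if (!length(pool)) pool <- if (want_allo) nb$iso else nb$allo
  if (!length(pool)) return(NULL)
  new_ac <- sample(pool, 1L)
  new_iso <- anticodon_to_aa(new_ac)
  kind <- if (new_iso == g$isotype) "iso" else "allo"
  tr <- .truth_row(state, "trna_change", branch, g$chrom, g$start, g$end,
                   sprintf("kind=anticodon_%s;trna=%s;anc=%s:%s;der=%s:%s",
                           kind, g$trna_id, g$isotype, g$anticodon, new_iso, new_ac))
  state <- write_anticodon(state, g$chrom, g$start, g$end, g$strand, new_ac)
  ri <- which(state$trnas$trna_id == g$trna_id)
  data.table::set(state$trnas, ri, "anticodon", new_ac)
  data.table::set(state$trnas, ri, "isotype", new_iso)
  list(state = state, truth = tr, carried = c(g$start, g$end))
}

ev_intron_indel <- function(state, branch, cfg) {
  intr <- state_introns(state)
  intr <- intr[intr$end - intr$start >= 80L, ]
  if (!nrow(intr)) return(NULL)
  it <- intr[sample.int(nrow(intr), 1L), ]
  insertion <- stats::runif(1) < branch_rate(cfg$intron_indel_ins_prob, branch)
  len <- min(stats::rgeom(1L, 1 / branch_rate(cfg$intron_indel_mean, branch)) + 1L,
             cfg$intron_indel_max)
  width <- it$end - it$start
  if (insertion) {
    p <- it$start + 8L + sample.int(width - 16L, 1L)
    tr <- .truth_row(state, "intron_indel", branch, it$chrom, p, p,
                     sprintf("gene=%s;intron=%d;delta=%d", it$gene_id,
                             it$intron_rank, len))
    state <- seq_insert(state, it$chrom, p, random_dna(len))
    carried <- c(p, p + len)
  } else {
    len <- min(len, width - 70L)
    if (len < 1L) return(NULL)
    s <- it$start + 8L + sample.int(width - 16L - len, 1L)
    tr <- .truth_row(state, "intron_indel", branch, it$chrom, s, s + len,
                     sprintf("gene=%s;intron=%d;delta=%d", it$gene_id,
                             it$intron_rank, -len))
    state <- seq_delete(state, it$chrom, s, s + len)
    carried <- c(s, s)
  }
  list(state = state, truth = tr, carried = carried)
}

apply_substitutions <- function(state, branch, cfg, dur) {
  p <- branch_rate(cfg$sub_rate, branch) * dur
  if (p <= 0) return(state)
  for (ch in names(state$seq)) {
    L <- nchar(state$seq[[ch]])
    n <- stats::rbinom(1L, L, p)
    if (n == 0L) next
    pos <- sample.int(L, n)          # 1-based
    # keep planted breakpoints (+/-5 bp) and tRNA genes substitution-free
    ev <- state$events[state$events$chrom == ch, ]
    tr <- state$trnas[state$trnas$chrom == ch, ]
    forb <- IRanges::IRanges()
    if (nrow(ev)) forb <- c(forb,
      IRanges::IRanges(start = pmax(c(ev$start, ev$end) - 4L, 1L),
                       end = c(ev$start, ev$end) + 6L))
    if (nrow(tr)) forb <- c(forb, IRanges::IRanges(tr$start + 1L, tr$end))
    if (length(forb)) {
      forb <- IRanges::reduce(forb)
      keep <- !IRanges::overlapsAny(IRanges::IRanges(pos, pos), forb)
      pos <- pos[keep]
    }
    if (!length(pos)) next
    r <- charToRaw(state$seq[[ch]])
    cur <- rawToChar(r[pos], multiple = TRUE)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    new <- BASES[(match(cur, BASES) - 1L + shift) %% 4L + 1L]
    r[pos] <- charToRaw(paste(new, collapse = ""))
    state$seq[[ch]] <- rawToChar(r)
  }
  state
}

#' Derived coordinates of planted events in a given taxon
#'
#' For taxa carrying an event, coordinates come from the carried event table
#' of that taxon's genome state (exact). For non-carriers the ancestral-frame
#' interval is lifted forward through the taxon's edit log, giving the
#' position of the ancestral-state locus.
#'
#' @param sim A `sim_complex` from [evolve_tree()].
#' @param taxon Taxon name.
#' @return data.table: `event_id`, `type`, `branch`, `chrom`, `start`,
#'   `end`, `carried` (logical).
#' @export
truth_coords <- function(sim, taxon) {
  stopifnot(inherits(sim, "sim_complex"))
  g <- sim$genomes[[taxon]]
  if (is.null(g)) stop("unknown taxon: ", taxon)
  path <- taxon_path(sim$phylogeny, taxon)
  tt <- sim$truth
  out <- data.table::data.table(event_id = tt$event_id, type = tt$type,
                                branch = tt$branch, chrom = tt$chrom,
                                start = NA_real_, end = NA_real_,
                                carried = tt$branch %in% path)
  carried_idx <- match(tt$event_id, g$events$event_id)
  for (i in seq_len(nrow(tt))) {
    if (out$carried[i] && !is.na(carried_idx[i])) {
      out$start[i] <- g$events$start[carried_idx[i]]
      out$end[i] <- g$events$end[carried_idx[i]]
    } else {
      lifted <- lift_interval(g$ops, tt$chrom[i], tt$anc_start[i], tt$anc_end[i])
      out$start[i] <- lifted[[1]]
      out$end[i] <- lifted[[2]]
    }
  }
  out
}

#' Convenience driver: simulate the full species complex
#'
#' @param cfg An [evolution_config()] (default defaults).
#' @param phy A [phylogeny()] (default [simcomplex_phylogeny()]).
#' @return See [evolve_tree()].
#' @export
simulate_complex <- function(cfg = evolution_config(),
                             phy = simcomplex_phylogeny()) {
  evolve_tree(simulate_ancestor(cfg), phy, cfg)
}
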