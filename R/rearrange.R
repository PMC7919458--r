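#' Signed block permutation of a pairwise alignment map
#'
#' Blocks are numbered along the reference; the query's block order and
#' orientations give, per chromosome, a signed permutation whose identity
#' corresponds to perfect collinearity.
#'
#' @param map An `alignment_map` from [build_map()].
#' @return Object of class `signed_permutation`: a named list (one signed
#'   integer vector per reference chromosome) with attributes `topology`
#'   (`"linear"`) and `block_map` (block id per permutation element).
#' @export
blocks_to_permutation <- function(map) {
  b <- data.table::as.data.table(map$blocks)
  b <- b[b$ref_chrom == b$qry_chrom, ]   # translocated blocks are excluded
  if (nrow(b) < nrow(map$blocks))
    message(nrow(map$blocks) - nrow(b), " translocated block(s) excluded")
  data.table::setorderv(b, c("ref_chrom", "ref_start"))
  b[, elem := seq_len(.N), by = "ref_chrom"]
  perms <- lapply(split(b, b$ref_chrom), function(x) {
    q <- x[order(x$qry_start), ]
    stats::setNames(as.integer(q$elem * q$strand), q$block_id)
  })
  structure(perms, class = "signed_permutation", topology = "linear")
}

#' Count breakpoints of a signed permutation
#'
#' An adjacency `(a, b)` is conserved when `b == a + 1` in signed terms;
#' chromosome ends are capped with sentinels per the standard convention.
#'
#' @param perm A `signed_permutation` or a plain signed integer vector.
#' @return Integer breakpoint count (summed over chromosomes).
#' @export
count_breakpoints <- function(perm) {
  vecs <- if (inherits(perm, "signed_permutation")) unclass(perm) else list(perm)
  sum(vapply(vecs, function(v) {
    n <- length(v)
    if (n == 0L) return(0L)
    s <- c(0L, as.integer(v), n + 1L)
    sum(s[-1L] != s[-length(s)] + 1L)
  }, integer(1)))
}

#' Call inversions from a signed permutation
#'
#' Each maximal run of sign-reversed, order-reversed blocks (consecutive
#' negative entries whose reference ranks descend by one) becomes a single
#' inversion call spanning the run's reference extent.
#'
#' @param perm From [blocks_to_permutation()].
#' @param map The `alignment_map` the permutation came from (for reference
#'   coordinates).
#' @return data.table of calls: `chrom`, `start`, `end`, `n_blocks`,
#'   `blocks` (comma-separated block ids).
#' @export
call_inversions <- function(perm, map) {
  stopifnot(inherits(perm, "signed_permutation"))
  out <- list()
  for (ch in names(perm)) {
    v <- perm[[ch]]
    ids <- as.integer(names(v))
    i <- 1L
    while (i <= length(v)) {
      if (v[i] < 0L) {
        j <- i
        while (j < length(v) && v[j + 1L] < 0L && v[j + 1L] == v[j] + 1L) j <- j + 1L
        run_ids <- ids[i:j]
        bb <- map$blocks[map$blocks$block_id %in% run_ids, ]
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = ch, start = min(bb$ref_start), end = max(bb$ref_end),
          n_blocks = j - i + 1L, blocks = paste(run_ids, collapse = ","))
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out)) return(data.table::data.table(
    chrom = character(), start = numeric(), end = numeric(),
    n_blocks = integer(), blocks = character()))
  data.table::rbindlist(out)
}

# genome representation for DCJ: list of signed integer vectors, one per
# chromosome. Extremities: marker m has tail 2m-1 and head 2m.
.dcj_neighbors <- function(genome, n, topology) {
  nb <- integer(2L * n)           # 0 = telomere
  for (chrom in genome) {
    ends <- lapply(chrom, function(g)
      if (g > 0L) c(2L * g - 1L, 2L * g) else c(2L * abs(g), 2L * abs(g) - 1L))
    k <- length(ends)
    for (i in seq_len(k - 1L)) {
      a <- ends[[i]][2L]; b <- ends[[i + 1L]][1L]
      nb[a] <- b; nb[b] <- a
    }
    if (topology == "circular") {
      a <- ends[[k]][2L]; b <- ends[[1L]][1L]
      nb[a] <- b; nb[b] <- a
    }
  }
  nb
}

#' DCJ distance between two genomes
#'
#' Double-cut-and-join distance via the adjacency graph:
#' `d = N - (C + I/2)` with `N` markers, `C` cycles and `I` odd paths
#' (`I = 0` for fully circular genomes).
#'
#' @param genomeA,genomeB Lists of signed integer chromosome vectors (or a
#'   single vector each); marker sets must agree.
#' @param topology `"linear"` or `"circular"`.
#' @return Integer DCJ distance.
#' @export
dcj_distance <- function(genomeA, genomeB, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.list(genomeA)) genomeA <- list(genomeA)
  if (!is.list(genomeB)) genomeB <- list(genomeB)
  genomeA <- lapply(genomeA, as.integer)
  genomeB <- lapply(genomeB, as.integer)
  mA <- sort(abs(unlist(genomeA))); mB <- sort(abs(unlist(genomeB)))
  if (!identical(mA, mB) || anyDuplicated(mA))
    stop("genomes must carry the same marker set, each marker once")
  n <- length(mA)
  if (n == 0L) return(0L)
  nbA <- .dcj_neighbors(genomeA, n, topology)
  nbB <- .dcj_neighbors(genomeB, n, topology)
  seen <- logical(2L * n)
  C <- 0L; I <- 0L
  for (x0 in seq_len(2L * n)) {
    if (seen[x0]) next
    # walk the component of the extremity graph (A-matching + B-matching)
    comp <- x0
    seen[x0] <- TRUE
    frontier <- x0
    while (length(frontier)) {
      nxt <- integer(0)
      for (x in frontier) for (y in c(nbA[x], nbB[x])) {
        if (y > 0L && !seen[y]) { seen[y] <- TRUE; comp <- c(comp, y); nxt <- c(nxt, y) }
      }
      frontier <- nxt
    }
    open_ends <- sum(nbA[comp] == 0L) + sum(nbB[comp] == 0L)
    if (open_ends == 0L) C <- C + 1L
    else if (length(comp) %% 2L == 1L) I <- I + 1L
  }
  as.integer(n - (C + I / 2))
}

#' DCJ distance by brute-force breadth-first search
#'
#' Independent oracle: explores genome space under single DCJ operations
#' from `genomeA` until `genomeB` is reached, never using the adjacency
#' graph. Feasible for a handful of markers only.
#'
#' @inheritParams dcj_distance
#' @return Integer DCJ distance.
#' @export
dcj_distance_bfs <- function(genomeA, genomeB, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.list(genomeA)) genomeA <- list(genomeA)
  if (!is.list(genomeB)) genomeB <- list(genomeB)
  n <- length(unlist(genomeA))
  pa <- .dcj_partner_vec(genomeA, n, topology)
  pb <- .dcj_partner_vec(genomeB, n, topology)
  res <- cpp_dcj_bfs(pa, topology == "linear")
  hit <- which(apply(res$partner, 1L, function(r) all(r == pb)))
  if (!length(hit)) stop("target genome unreachable (different topology class?)")
  res$distance[hit[1L]]
}

# partner encoding for the BFS: partner[extremity] in 1..2n, 0 = telomere
.dcj_partner_vec <- function(genome, n, topology) {
  nb <- .dcj_neighbors(genome, n, topology)
  as.integer(nb)
}

#' Precomputed BFS distance table from one source genome
#'
#' Runs the brute-force BFS once and returns a lookup closure, so that
#' thousands of target genomes can be checked against the closed-form
#' distance without repeating the search.
#'
#' @inheritParams dcj_distance
#' @param genomeA Source genome.
#' @return `function(genomeB)` returning the BFS distance (or `NA` if the
#'   target was not reachable).
#' @export
dcj_bfs_table <- function(genomeA, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.list(genomeA)) genomeA <- list(genomeA)
  n <- length(unlist(genomeA))
  pa <- .dcj_partner_vec(genomeA, n, topology)
  res <- cpp_dcj_bfs(pa, topology == "linear")
  keys <- apply(res$partner, 1L, paste, collapse = ",")
  env <- new.env(parent = emptyenv(), size = length(keys))
  for (i in seq_along(keys)) assign(keys[i], res$distance[i], envir = env)
  function(genomeB) {
    if (!is.list(genomeB)) genomeB <- list(genomeB)
    key <- paste(.dcj_partner_vec(genomeB, n, topology), collapse = ",")
    if (!exists(key, envir = env, inherits = FALSE)) return(NA_integer_)
    get(key, envir = env, inherits = FALSE)
  }
}

#' Classify calls by chromatin compartment
#'
#' A call takes the compartment of its midpoint; calls spanning a
#' eu/het boundary are conservatively labelled `het`.
#'
#' @param calls data.table with `chrom`, `start`, `end`.
#' @param compartments data.table with `chrom`, `start`, `end`, `name`
#'   (values `eu`/`het`) partitioning each chromosome.
#' @return `calls` with a `compartment` column appended.
#' @export
classify_compartment <- function(calls, compartments) {
  calls <- data.table::as.data.table(calls)
  comp <- data.table::as.data.table(compartments)
  res <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cc <- comp[comp$chrom == calls$chrom[i], ]
    mid <- (calls$start[i] + calls$end[i]) / 2
    at <- cc[cc$start <= mid & cc$end > mid, ]
    if (!nrow(at)) stop("call midpoint outside annotated chromosome: ",
                        calls$chrom[i], ":", mid)
    over <- cc[cc$start < calls$end[i] & cc$end > calls$start[i], ]
    res[i] <- if (length(unique(over$name)) > 1L) "het" else at$name[1L]
  }
  calls$compartment <- res
  calls
}

#' Multi-taxon inversion analysis against a common reference
#'
#' Calls inversions in every query taxon from its pairwise map to the
#' reference, merges calls across taxa by reciprocal overlap into candidate
#' events, scores each event's orientation state in every taxon (including
#' the outgroup) by projecting the reference interval through that taxon's
#' own map, polarizes events onto branches by Dollo parsimony, and labels
#' chromatin compartments.
#'
#' @param maps Named list of `alignment_map`s, reference -> taxon, covering
#'   at least the ingroup and the outgroup.
#' @param phy A [phylogeny()].
#' @param compartments Reference-frame compartment table (optional).
#' @param recip Reciprocal-overlap fraction merging calls across taxa
#'   (default 0.5).
#' @param min_project Minimum projected fraction below which a taxon's
#'   state is `missing` (default 0.5).
#' @return List: `events` (one row per event: interval, per-taxon states,
#'   `branch`, `ambiguous`, `compartment`), `calls` (raw per-taxon calls),
#'   `presence` (the state matrix).
#' @export
inversion_analysis <- function(maps, phy, compartments = NULL,
                               recip = 0.5, min_project = 0.5) {
  stopifnot(inherits(phy, "phylogeny"))
  calls <- data.table::rbindlist(lapply(names(maps), function(t) {
    m <- maps[[t]]
    cl <- call_inversions(blocks_to_permutation(m), m)
    if (nrow(cl)) cl$taxon <- t
    cl
  }), fill = TRUE)
  if (!nrow(calls))
    return(list(events = data.table::data.table(), calls = calls,
                presence = data.table::data.table()))

  # merge calls into events by reciprocal overlap in the reference frame
  data.table::setorderv(calls, c("chrom", "start"))
  calls$event <- NA_integer_
  ev <- 0L
  for (i in seq_len(nrow(calls))) {
    if (!is.na(calls$event[i])) next
    ev <- ev + 1L
    calls$event[i] <- ev
    w1 <- calls$end[i] - calls$start[i]
    for (j in seq_len(nrow(calls))[-i]) {
      if (!is.na(calls$event[j]) || calls$chrom[j] != calls$chrom[i]) next
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      w2 <- calls$end[j] - calls$start[j]
      if (ov >= recip * w1 && ov >= recip * w2) calls$event[j] <- ev
    }
  }

  events <- calls[, list(chrom = chrom[1], start = min(start), end = max(end),
                         taxa = paste(sort(unique(taxon)), collapse = ",")),
                  by = "event"]
  score_taxa <- names(maps)
  states <- matrix("missing", nrow(events), length(phy$taxa),
                   dimnames = list(NULL, phy$taxa))
  states[, phy$reference] <- "ancestral"
  for (i in seq_len(nrow(events))) {
    for (t in score_taxa) {
      if (t %in% strsplit(events$taxa[i], ",")[[1]]) { states[i, t] <- "derived"; next }
      img <- project_interval(maps[[t]], events$chrom[i], events$start[i],
                              events$end[i])
      w <- events$end[i] - events$start[i]
      if (!nrow(img) || sum(img$covered) < min_project * w) next
      neg <- sum(img$covered[img$strand == -1L]) / sum(img$covered)
      states[i, t] <- if (neg >= 0.5) "derived" else "ancestral"
    }
  }
  pol <- polarize_events(states, phy)
  events$branch <- pol$branch
  events$ambiguous <- pol$ambiguous
  for (t in phy$taxa) events[[paste0("state_", t)]] <- states[, t]
  if (!is.null(compartments)) events <- classify_compartment(events, compartments)
  list(events = events, calls = calls, presence = states)
}
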