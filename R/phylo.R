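#' Four-taxon-plus-outgroup species phylogeny
#'
#' Describes the fixed tree topology used throughout: an ingroup trio with a
#' shared stem branch, a reference taxon splitting from the trio at the root,
#' and an outgroup attached by its own root edge. Branch durations are in
#' millions of years.
#'
#' @param ingroup Character vector of exactly three ingroup taxon names.
#' @param reference Reference taxon name (the coordinate frame for most
#'   comparisons).
#' @param outgroup Outgroup taxon name.
#' @param durations Named numeric vector of branch durations in Myr. Names
#'   must be the three ingroup taxa, `"stem"`, the reference taxon, and the
#'   outgroup taxon. All durations must be positive.
#' @return An object of class `phylogeny`: a list with `taxa`, `ingroup`,
#'   `reference`, `outgroup`, `branches` (named durations) and `branch_taxa`
#'   (leaf set descending from each branch).
#' @seealso [simcomplex_phylogeny()] for the default instance.
#' @export
phylogeny <- function(ingroup, reference, outgroup, durations) {
  if (length(ingroup) != 3L) stop("'ingroup' must name exactly three taxa")
  if (length(reference) != 1L || length(outgroup) != 1L)
    stop("'reference' and 'outgroup' must each name one taxon")
  taxa <- c(ingroup, reference, outgroup)
  if (anyDuplicated(taxa)) stop("taxon names must be distinct")
  branch_names <- c(ingroup, "stem", reference, outgroup)
  if (!setequal(names(durations), branch_names))
    stop("'durations' must be named by: ", paste(branch_names, collapse = ", "))
  durations <- durations[branch_names]
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("all branch durations must be positive")
  branch_taxa <- c(
    stats::setNames(as.list(ingroup), ingroup),
    list(stem = ingroup),
    stats::setNames(list(reference), reference),
    stats::setNames(list(outgroup), outgroup)
  )
  structure(list(
    taxa = taxa, ingroup = ingroup, reference = reference, outgroup = outgroup,
    branches = durations, branch_taxa = branch_taxa
  ), class = "phylogeny")
}

#' Default phylogeny of the simulated species complex
#'
#' An ingroup trio (`dsim`, `dmau`, `dsec`) that radiated ~0.25 Myr ago, a
#' reference taxon (`dmel`) that split from the trio lineage ~2.5 Myr ago
#' (leaving a 2.25-Myr ingroup stem), and an outgroup (`dyak`) on a 5-Myr
#' root edge.
#'
#' @return A [phylogeny()] object.
#' @export
simcomplex_phylogeny <- function() {
  phylogeny(
    ingroup = c("dsim", "dmau", "dsec"),
    reference = "dmel",
    outgroup = "dyak",
    durations = c(dsim = 0.25, dmau = 0.25, dsec = 0.25,
                  stem = 2.25, dmel = 2.5, dyak = 5)
  )
}

#' Root-to-tip branch path for a taxon
#'
#' @param phy A [phylogeny()] object.
#' @param taxon Taxon name.
#' @return Character vector of branch names from the root to the taxon.
#' @export
taxon_path <- function(phy, taxon) {
  stopifnot(inherits(phy, "phylogeny"))
  if (!taxon %in% phy$taxa) stop("unknown taxon: ", taxon)
  if (taxon %in% phy$ingroup) c("stem", taxon) else taxon
}

#' @export
print.phylogeny <- function(x, ...) {
  cat("Phylogeny: ((", paste(x$ingroup, collapse = ","), ")stem, ",
      x$reference, "); outgroup ", x$outgroup, "\n", sep = "")
  cat("Branch durations (Myr):\n")
  print(x$branches)
  invisible(x)
}

#' Dollo assignment of a derived character to a single branch
#'
#' Finds the unique branch consistent with a single origin of the derived
#' state and no regain. If the derived taxa are exactly the leaf set of one
#' branch, the event is assigned there; if instead the *ancestral-like* taxa
#' form a branch's leaf set, the character polarity is flipped (the observed
#' "derived" state is in fact ancestral and the event occurred on that
#' branch, e.g. an inversion shared by the ingroup and the outgroup but not
#' the reference taxon maps to the reference terminal branch). Taxa with
#' missing state are unconstrained. Anything else needs two or more origins
#' and is returned as ambiguous.
#'
#' @param phy A [phylogeny()] object.
#' @param derived Character vector of taxa showing the derived state.
#' @param observed Character vector of taxa with a non-missing state
#'   (defaults to all taxa). Must contain `derived`.
#' @return A list with `branch` (name or `NA`), `flipped` (logical: polarity
#'   was inverted) and `ambiguous` (logical).
#' @export
dollo_branch <- function(phy, derived, observed = phy$taxa) {
  stopifnot(inherits(phy, "phylogeny"))
  derived <- intersect(derived, observed)
  if (length(derived) == 0L)
    return(list(branch = NA_character_, flipped = FALSE, ambiguous = TRUE))
  fits <- function(target) {
    hit <- vapply(phy$branch_taxa,
                  function(lv) setequal(intersect(lv, observed), target) &&
                    length(intersect(lv, observed)) > 0L,
                  logical(1))
    names(phy$branch_taxa)[hit]
  }
  direct <- fits(derived)
  if (length(direct) > 0L) {
    # nested leaf sets can both fit when some taxa are missing; take the
    # most recent (smallest) branch, ambiguous on ties
    sizes <- lengths(phy$branch_taxa[direct])
    best <- direct[sizes == min(sizes)]
    return(list(branch = if (length(best) == 1L) best else NA_character_,
                flipped = FALSE, ambiguous = length(best) != 1L))
  }
  anc <- setdiff(observed, derived)
  flip <- fits(anc)
  if (length(flip) > 0L) {
    sizes <- lengths(phy$branch_taxa[flip])
    best <- flip[sizes == min(sizes)]
    return(list(branch = if (length(best) == 1L) best else NA_character_,
                flipped = TRUE, ambiguous = length(best) != 1L))
  }
  list(branch = NA_character_, flipped = FALSE, ambiguous = TRUE)
}

#' Polarize a presence matrix of derived events onto tree branches
#'
#' Applies [dollo_branch()] to each row of an event-by-taxon state matrix.
#'
#' @param mat A data.frame/matrix with one row per event and one column per
#'   taxon (including the outgroup); entries in
#'   `c("derived", "ancestral", "missing")`.
#' @param phy A [phylogeny()] object.
#' @return A data.table with columns `event`, `branch`, `flipped`,
#'   `ambiguous`. All-missing rows are skipped with a warning.
#' @export
polarize_events <- function(mat, phy) {
  stopifnot(inherits(phy, "phylogeny"))
  mat <- as.data.frame(mat)
  taxa <- intersect(colnames(mat), phy$taxa)
  if (!phy$outgroup %in% colnames(mat))
    stop("presence matrix must include the outgroup column '", phy$outgroup, "'")
  out <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    st <- unlist(mat[i, taxa])
    obs <- taxa[st != "missing"]
    if (length(obs) == 0L) {
      warning("event row ", i, " has no observed states; skipped")
      out[[i]] <- data.table::data.table(event = i, branch = NA_character_,
                                         flipped = NA, ambiguous = NA)
      next
    }
    res <- dollo_branch(phy, derived = taxa[st == "derived"], observed = obs)
    out[[i]] <- data.table::data.table(event = i, branch = res$branch,
                                       flipped = res$flipped,
                                       ambiguous = res$ambiguous)
  }
  data.table::rbindlist(out)
}
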