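# Standard genetic code on the anticodon alphabet.
#
# Anticodons are written 5'->3' in DNA letters; the decoded codon is their
# reverse complement. Used both when planting anticodon mutations and when
# classifying observed shifts as isoacceptor (same amino acid) or
# alloacceptor (different amino acid).

GENETIC_CODE_DNA <- stats::setNames(
  unlist(strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")),
  {
    b <- c("T", "C", "A", "G")
    paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  }
)
GENETIC_CODE_AA <- unname(GENETIC_CODE_DNA)

revcomp_triplet <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(b)
    paste(rev(b), collapse = ""), character(1)))
}

#' Amino acid decoded by an anticodon
#'
#' @param anticodon Character vector of 3-mers over A/C/G/T (5'->3').
#' @return One-letter amino-acid codes (`"*"` for anticodons whose cognate
#'   codon is a stop).
#' @export
anticodon_to_aa <- function(anticodon) {
  stopifnot(all(nchar(anticodon) == 3L))
  unname(GENETIC_CODE_DNA[revcomp_triplet(anticodon)])
}

# all anticodons decoding a given amino acid
aa_anticodons <- function(aa) {
  codons <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == aa]
  revcomp_triplet(codons)
}

# single-base variants of an anticodon, split into isoacceptor (same amino
# acid) and alloacceptor (different amino acid, excluding stop-decoders)
anticodon_neighbors <- function(anticodon) {
  vars <- character(0)
  for (i in 1:3) for (b in setdiff(BASES, substr(anticodon, i, i))) {
    v <- anticodon
    substr(v, i, i) <- b
    vars <- c(vars, v)
  }
  aa0 <- anticodon_to_aa(anticodon)
  aa <- anticodon_to_aa(vars)
  list(iso = vars[aa == aa0], allo = vars[aa != aa0 & aa != "*"])
}
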