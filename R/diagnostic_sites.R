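#' Find species-diagnostic dinucleotide site pairs on an alignment
#'
#' Given aligned mitochondrial (or other) sequences of two species, finds
#' pairs of alignment sites at which each species is internally fixed for a
#' dinucleotide and the two species differ at both nucleotides of both
#' sites. Such site pairs anchor species-specific primer 3' ends, letting a
#' single PCR distinguish the species (here, the collared vs brown lemming
#' assay, in which amplicon length then separates the genera).
#'
#' A column is eligible only if every sequence of a species carries the
#' same unambiguous base there; within-species polymorphism or ambiguity
#' codes make the consensus ambiguous and the site ineligible.
#'
#' @param seqs_a,seqs_b character vectors of aligned sequences (equal
#'   alignment length across all sequences), one per species.
#' @param separation_range length-2 integer vector: admissible number of
#'   nucleotides strictly between the two dinucleotide sites.
#' @return data frame sorted by leftmost position with columns `pos1`,
#'   `pos2` (0-based alignment coordinates of each dinucleotide start),
#'   `separation`, and the per-species dinucleotides `a1`, `b1`, `a2`,
#'   `b2`.
#' @examples
#' a <- c("AATTGGCCAAGGTTAA")
#' b <- c("AACCGGCCAAGGCCAA")
#' find_diagnostic_site_pairs(a, b, c(0, 12))
#' @export
find_diagnostic_site_pairs <- function(seqs_a, seqs_b,
                                       separation_range = c(0L, 100L)) {
  seqs_a <- toupper(as.character(seqs_a)); seqs_b <- toupper(as.character(seqs_b))
  if (length(seqs_a) < 1 || length(seqs_b) < 1)
    stop("need at least one sequence per species")
  L <- unique(nchar(c(seqs_a, seqs_b)))
  if (length(L) != 1) stop("alignment lengths unequal")
  ma <- do.call(rbind, strsplit(seqs_a, ""))
  mb <- do.call(rbind, strsplit(seqs_b, ""))
  fixed_base <- function(col) {
    u <- unique(col)
    if (length(u) == 1 && u %in% c("A", "C", "G", "T")) u else NA_character_
  }
  ca <- apply(ma, 2, fixed_base)
  cb <- apply(mb, 2, fixed_base)
  # dinucleotide site at column j (1-based) spans j, j+1
  ok <- !is.na(ca) & !is.na(cb) & ca != cb
  site <- which(ok[-L] & ok[-1])                 # both positions diagnostic
  if (length(site) < 2)
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      separation = integer(0), a1 = character(0),
                      b1 = character(0), a2 = character(0), b2 = character(0)))
  pairs <- expand.grid(i = site, k = site)
  pairs <- pairs[pairs$i < pairs$k, , drop = FALSE]
  sep <- pairs$k - pairs$i - 2L                  # bases strictly between
  keep <- sep >= separation_range[1] & sep <= separation_range[2]
  pairs <- pairs[keep, , drop = FALSE]; sep <- sep[keep]
  din <- function(cons, j) paste0(cons[j], cons[j + 1])
  out <- data.frame(
    pos1 = pairs$i - 1L, pos2 = pairs$k - 1L, separation = sep,
    a1 = vapply(pairs$i, function(j) din(ca, j), ""),
    b1 = vapply(pairs$i, function(j) din(cb, j), ""),
    a2 = vapply(pairs$k, function(j) din(ca, j), ""),
    b2 = vapply(pairs$k, function(j) din(cb, j), ""))
  out <- out[order(out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
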