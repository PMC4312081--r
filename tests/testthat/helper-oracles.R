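# Hand-rolled, dependency-free oracles used to cross-check the package's
# implementations on small inputs.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# mismatches of `primer` (IUPAC) against `seq` (ACGT) at a given 1-based
# offset; ungapped.
bf_mismatches_at <- function(primer, seq, at) {
  pc <- strsplit(primer, "")[[1]]
  sc <- strsplit(seq, "")[[1]][at:(at + nchar(primer) - 1)]
  sum(!mapply(function(p, s) s %in% IUPAC_SETS[[p]], pc, sc))
}

# minimum-mismatch scan of a primer over a sequence; returns data frame of
# all offsets with <= max_mm mismatches.
bf_primer_scan <- function(primer, seq, max_mm) {
  L <- nchar(seq); k <- nchar(primer)
  hits <- list()
  for (at in seq_len(L - k + 1)) {
    mm <- bf_mismatches_at(primer, seq, at)
    if (mm <= max_mm)
      hits[[length(hits) + 1]] <- data.frame(start = at, end = at + k - 1,
                                             mm = mm)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(start = integer(0), end = integer(0), mm = integer(0))
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# exhaustive all-column-pairs diagnostic-site scan (the independent route
# to find_diagnostic_site_pairs)
bf_site_pairs <- function(seqs_a, seqs_b, sep_range) {
  ma <- do.call(rbind, strsplit(toupper(seqs_a), ""))
  mb <- do.call(rbind, strsplit(toupper(seqs_b), ""))
  L <- ncol(ma)
  fixed <- function(m, j) {
    u <- unique(m[, j]); if (length(u) == 1 && u %in% c("A","C","G","T")) u else NA
  }
  diag_col <- vapply(seq_len(L), function(j) {
    a <- fixed(ma, j); b <- fixed(mb, j)
    !is.na(a) && !is.na(b) && a != b
  }, logical(1))
  starts <- which(diag_col[-L] & diag_col[-1])
  out <- list()
  for (i in starts) for (k in starts) {
    if (k <= i) next
    sep <- k - i - 2L
    if (sep >= sep_range[1] && sep <= sep_range[2])
      out[[length(out) + 1]] <- c(pos1 = i - 1L, pos2 = k - 1L, sep = sep)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# write a small lineage-tagged FASTA
write_tiny_fasta <- function(path, ids, seqs, family, genus = NULL,
                             species = NULL, division = NULL) {
  lines <- character(0)
  for (i in seq_along(ids)) {
    tags <- c(
      if (!is.null(division) && !is.na(division[i])) paste0("division=", division[i], ";"),
      if (!is.na(family[i])) paste0("family=", family[i], ";"),
      if (!is.null(genus) && !is.na(genus[i])) paste0("genus=", genus[i], ";"),
      if (!is.null(species) && !is.na(species[i])) paste0("species=", species[i], ";"))
    lines <- c(lines, paste0(">", ids[i], " ", paste(tags, collapse = " ")),
               seqs[i])
  }
  writeLines(lines, path)
  path
}

# random composition profiles for property tests
random_profiles <- function(n, k, alpha = 1) {
  m <- lemmingdiet::rdirichlet(n, rep(alpha, k))
  colnames(m) <- paste0("t", seq_len(k))
  rownames(m) <- paste0("s", seq_len(n))
  m
}

# Table 2 of the source system: printed availability, use, w, SE and
# significance class per species/family (used as golden fixtures).
table2 <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
species family avail use w se cls
collared Fabaceae 0.013 0.003 0.2 0.5 (-)
collared Juncaceae 0.113 0.018 0.2 0.1 -
collared Poaceae 0.054 0.124 2.2 2.4 0
collared Rosaceae 0.043 0.005 0.1 0.2 -
collared Salicaceae 0.713 0.839 1.2 0.2 0
brown Fabaceae 0.013 0.010 0.8 1.9 0
brown Juncaceae 0.113 0.029 0.3 0.2 -
brown Poaceae 0.056 0.091 1.6 1.7 0
brown Polygonaceae 0.008 0.049 6.5 19 0
brown Rosaceae 0.043 0.048 1.1 1.7 0
brown Salicaceae 0.713 0.727 1.0 0.2 0
brown Saxifragaceae 0.004 0.036 8.4 33 0
brown Aulacomniaceae 0.027 0.334 16.1 28 0
brown Dicranaceae 0.015 0.062 4.1 8.3 0
brown Polytrichaceae 0.267 0.501 1.9 0.8 0
")
  # rows whose printed rounded inputs are inconsistent with the printed
  # ratio (rounding of the unprinted availability/use) are flagged
  df$ratio_consistent <- !(df$species == "collared" & df$family == "Poaceae") &
    !(df$species == "brown" & df$family %in%
        c("Polygonaceae", "Saxifragaceae", "Aulacomniaceae"))
  df
}
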