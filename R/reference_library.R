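#' Define a primer pair for in-silico PCR
#'
#' A primer pair is a named forward/reverse pair of IUPAC nucleotide strings
#' with a per-primer mismatch budget. The reverse primer is given in its
#' conventional 5'->3' orientation and is reverse-complemented internally
#' when searched on the template strand.
#'
#' @param name marker label, e.g. `"g-h"`.
#' @param forward,reverse IUPAC nucleotide strings (5'->3').
#' @param max_mismatch maximum mismatches tolerated, separately for each
#'   primer (ungapped).
#' @return an object of class `primer_pair`.
#' @seealso [trnl_primers()] for the standard plant P6-loop presets.
#' @export
primer_pair <- function(name, forward, reverse, max_mismatch = 5L) {
  iupac <- "^[ACGTRYSWKMBDHVN]+$"
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!nzchar(forward) || !grepl(iupac, forward))
    stop("forward primer empty or not IUPAC: ", forward)
  if (!nzchar(reverse) || !grepl(iupac, reverse))
    stop("reverse primer empty or not IUPAC: ", reverse)
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  structure(list(name = name, forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Standard trnL (UAA) intron primer pairs
#'
#' The two complementary plant P6-loop primer pairs used for herbivore diet
#' metabarcoding: `g-h`, which performs well on seed plants but is biased
#' against bryophytes, and `c-h`, universal for plants and therefore able to
#' quantify the moss fraction of a diet.
#'
#' @param max_mismatch mismatch budget per primer (default 5).
#' @return named list of [primer_pair()] objects.
#' @export
trnl_primers <- function(max_mismatch = 5L) {
  list(
    "g-h" = primer_pair("g-h", "GGGCAATCCTGAGCCAA", "CCATTGAGTCTCTGCACCTATC",
                        max_mismatch),
    "c-h" = primer_pair("c-h", "CGAAATCGGTAGACGCTACG", "CCATTGAGTCTCTGCACCTATC",
                        max_mismatch)
  )
}

#' Read a plant reference library from FASTA
#'
#' Headers carry the taxonomic lineage as `key=value` tags separated by
#' semicolons, e.g. `>ref001 division=Bryophyta; family=Polytrichaceae;
#' genus=Polytrichum; species=Polytrichum hyperboreum`. Records whose
#' lineage violates the rank hierarchy (genus without family, species
#' without genus) or that lack a family tag are skipped and counted.
#'
#' @param path FASTA file path.
#' @param lineage_keys named character vector mapping the ranks
#'   `division`, `family`, `genus`, `species` to the header tag names used
#'   in the file.
#' @return an object of class `ref_library`: a list with `records` (data
#'   frame: record_id, division, family, genus, species, sequence) and
#'   `n_skipped`.
#' @export
read_reference_fasta <- function(path,
                                 lineage_keys = c(division = "division",
                                                  family = "family",
                                                  genus = "genus",
                                                  species = "species")) {
  if (!file.exists(path)) stop("cannot read reference FASTA: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  headers <- names(seqs)
  parse_one <- function(h) {
    parts <- strsplit(h, "\\s+", perl = TRUE)[[1]]
    id <- parts[1]
    rest <- sub("^\\S+\\s*", "", h)
    tags <- strsplit(rest, ";")[[1]]
    tags <- tags[grepl("=", tags, fixed = TRUE)]
    kv <- do.call(rbind, strsplit(trimws(tags), "=", fixed = TRUE))
    vals <- if (is.null(kv)) character(0) else setNames(trimws(kv[, 2]), trimws(kv[, 1]))
    get <- function(rank) {
      v <- vals[lineage_keys[[rank]]]
      if (is.na(v) || !nzchar(v)) NA_character_ else unname(v)
    }
    data.frame(record_id = id, division = get("division"),
               family = get("family"), genus = get("genus"),
               species = get("species"), stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, lapply(headers, parse_one))
  recs$sequence <- toupper(gsub("-", "", as.character(seqs)))
  ok <- !is.na(recs$family) & nchar(recs$sequence) > 0 &
    !(is.na(recs$genus) & !is.na(recs$species))
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(n_skipped, " record(s) with malformed lineage skipped")
  recs <- recs[ok, , drop = FALSE]
  if (nrow(recs) == 0) stop("no valid records in ", path)
  rownames(recs) <- NULL
  structure(list(records = recs, n_skipped = n_skipped,
                 index = NULL, primers = NULL),
            class = "ref_library")
}

#' Build a reference library object from a records data frame
#'
#' Programmatic counterpart of [read_reference_fasta()], used by the
#' synthetic-data generator and tests.
#'
#' @param records data frame with columns record_id, family, sequence and
#'   optionally division, genus, species.
#' @return a `ref_library` object.
#' @export
ref_library <- function(records) {
  for (col in c("division", "genus", "species"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  stopifnot(all(c("record_id", "family", "sequence") %in% names(records)))
  records$sequence <- toupper(records$sequence)
  structure(list(records = records[, c("record_id", "division", "family",
                                       "genus", "species", "sequence")],
                 n_skipped = 0L, index = NULL, primers = NULL),
            class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat("Reference library:", nrow(x$records), "records")
  if (x$n_skipped) cat(" (", x$n_skipped, " skipped)", sep = "")
  cat("\n  families:", length(unique(x$records$family)),
      " genera:", length(unique(stats::na.omit(x$records$genus))),
      " species:", length(unique(stats::na.omit(x$records$species))), "\n")
  if (!is.null(x$index))
    cat("  amplicon index (", x$primers$name, "): ",
        length(unique(x$index$amplicon)), " distinct amplicons from ",
        nrow(x$index), " records; ", x$n_no_amplicon,
        " record(s) without primer hit\n", sep = "")
  invisible(x)
}

# Leftmost ungapped primer hit with <= max_mismatch mismatches.
# IUPAC ambiguity codes are honoured on the primer side only.
# Returns list(start, end, n_hits) or NULL.
.primer_hits <- function(primer, subject, max_mismatch, from = 1L) {
  m <- Biostrings::matchPattern(primer, subject,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE,
                                fixed = c(pattern = FALSE, subject = TRUE))
  s <- BiocGenerics::start(m); e <- BiocGenerics::end(m)
  keep <- s >= from
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0) return(NULL)
  list(start = s[1], end = e[1], n_hits = length(s))
}

#' In-silico PCR over a reference library
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on each record (ungapped, IUPAC-aware on the primer side, at most
#' `max_mismatch` mismatches per primer) and extracts the intervening
#' insert as that record's amplicon. Records without a valid primer pair
#' are excluded and counted; records with multiple possible hit pairs are
#' flagged and the leftmost pair is used.
#'
#' @param lib a `ref_library`.
#' @param primers a [primer_pair()].
#' @return the library with an `index` data frame (amplicon, record_id,
#'   division, family, genus, species), `n_no_amplicon`, and
#'   `flagged_records` (ids with ambiguous hit pairs).
#' @export
in_silico_pcr <- function(lib, primers) {
  stopifnot(inherits(lib, "ref_library"), inherits(primers, "primer_pair"))
  fwd <- Biostrings::DNAString(primers$forward)
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))
  recs <- lib$records
  amp <- character(nrow(recs)); hit <- logical(nrow(recs))
  flagged <- character(0)
  for (i in seq_len(nrow(recs))) {
    subj <- Biostrings::DNAString(recs$sequence[i])
    f <- .primer_hits(fwd, subj, primers$max_mismatch)
    if (is.null(f)) next
    r <- .primer_hits(rev_rc, subj, primers$max_mismatch, from = f$end + 1L)
    if (is.null(r)) next
    hit[i] <- TRUE
    amp[i] <- substr(recs$sequence[i], f$end + 1L, r$start - 1L)
    if (f$n_hits > 1L || r$n_hits > 1L) flagged <- c(flagged, recs$record_id[i])
  }
  index <- cbind(data.frame(amplicon = toupper(amp[hit]),
                            stringsAsFactors = FALSE),
                 recs[hit, c("record_id", "division", "family", "genus",
                             "species")])
  rownames(index) <- NULL
  lib$index <- index
  lib$primers <- primers
  lib$n_no_amplicon <- sum(!hit)
  lib$flagged_records <- flagged
  lib
}

#' Export the amplicon index as a data frame / TSV
#'
#' One row per (amplicon, lineage) combination.
#'
#' @param lib a `ref_library` after [in_silico_pcr()].
#' @param path optional TSV output path; if `NULL` the data frame is
#'   returned only.
#' @return data frame with columns amplicon, family, genus, species.
#' @export
amplicon_index_table <- function(lib, path = NULL) {
  if (is.null(lib$index)) stop("run in_silico_pcr() first")
  tab <- unique(lib$index[, c("amplicon", "family", "genus", "species")])
  tab <- tab[order(tab$amplicon, tab$family), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' Write a reference library to FASTA
#'
#' Headers use the `id key=value; ...` dialect read by
#' [read_reference_fasta()]; sequences are wrapped at 80 columns.
#'
#' @param lib a `ref_library`.
#' @param path output path.
#' @export
write_reference_fasta <- function(lib, path) {
  r <- lib$records
  tag <- function(key, val) ifelse(is.na(val), "", paste0(key, "=", val, ";"))
  hdr <- trimws(paste(r$record_id,
                      tag("division", r$division), tag("family", r$family),
                      tag("genus", r$genus), tag("species", r$species)))
  x <- Biostrings::DNAStringSet(r$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
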