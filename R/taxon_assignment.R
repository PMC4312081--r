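#' Read a per-sample sequence-variant table
#'
#' @param path TSV with columns sample_id, marker, sequence, reads.
#' @return data frame of variants.
#' @export
read_variants_tsv <- function(path) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "marker", "sequence", "reads") %in% names(v)))
  v$sequence <- toupper(v$sequence)
  if (any(v$reads < 0)) stop("negative read counts")
  v
}

# Best ungapped identity between two sequences whose lengths differ by at
# most a few bases: slide the shorter along the longer and score matches
# over the shorter length.
.ungapped_identity <- function(x, y) {
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  ls <- length(cx); ll <- length(cy)
  best <- 0L
  for (off in 0:(ll - ls)) {
    m <- sum(cx == cy[(off + 1):(off + ls)])
    if (m > best) best <- m
  }
  best / ls
}

# Lowest common ancestor over the three reported ranks.
.lca <- function(lineages) {
  one <- function(col) {
    u <- unique(lineages[[col]])
    if (length(u) == 1 && !is.na(u)) u else NA_character_
  }
  fam <- one("family"); gen <- one("genus"); sp <- one("species")
  if (!is.na(sp) && !is.na(gen) && !is.na(fam))
    list(family = fam, genus = gen, species = sp, rank = "species")
  else if (!is.na(gen) && !is.na(fam))
    list(family = fam, genus = gen, species = NA_character_, rank = "genus")
  else if (!is.na(fam))
    list(family = fam, genus = NA_character_, species = NA_character_,
         rank = "family")
  else
    list(family = NA_character_, genus = NA_character_,
         species = NA_character_, rank = "unidentified")
}

#' Assign sequence variants to taxa via the amplicon index
#'
#' Exact matches against the index are resolved first; remaining variants
#' are compared ungapped against index keys within +/-3 bases of their
#' length and assigned to the best-identity hit(s) when identity (over the
#' shorter length) reaches `identity_threshold`. Where several references
#' match equally well, the lineage is resolved to the lowest taxonomic rank
#' on which all of them agree (lowest common ancestor over family, genus,
#' species). Variants with no admissible match are marked unidentified.
#'
#' @param variants data frame (sample_id, marker, sequence, reads).
#' @param lib a `ref_library` after [in_silico_pcr()].
#' @param identity_threshold minimum identity for non-exact assignment.
#' @param length_slack admissible index-key length difference for fuzzy
#'   matching (default 3).
#' @return the variants data frame with columns family, genus, species,
#'   rank (family/genus/species/unidentified) and status (`"kept"`).
#' @export
assign_variants <- function(variants, lib, identity_threshold = 0.95,
                            length_slack = 3L) {
  if (is.null(lib$index) || nrow(lib$index) == 0)
    stop("empty amplicon index; run in_silico_pcr() first")
  idx <- lib$index
  keys <- unique(idx$amplicon)
  key_len <- nchar(keys)
  by_key <- split(idx[, c("family", "genus", "species")], idx$amplicon)
  resolve <- function(seqq) {
    if (seqq %in% keys) return(.lca(by_key[[seqq]]))
    cand <- keys[abs(key_len - nchar(seqq)) <= length_slack]
    if (length(cand) == 0)
      return(.lca(data.frame(family = NA_character_, genus = NA_character_,
                             species = NA_character_)))
    ident <- vapply(cand, .ungapped_identity, numeric(1), y = seqq)
    best <- max(ident)
    if (best < identity_threshold)
      return(list(family = NA_character_, genus = NA_character_,
                  species = NA_character_, rank = "unidentified"))
    hits <- cand[ident >= best - 1e-12]
    .lca(do.call(rbind, by_key[hits]))
  }
  res <- lapply(variants$sequence, resolve)
  variants$family <- vapply(res, `[[`, "", "family")
  variants$genus <- vapply(res, `[[`, "", "genus")
  variants$species <- vapply(res, `[[`, "", "species")
  variants$rank <- vapply(res, `[[`, "", "rank")
  variants$status <- "kept"
  variants
}

#' Define the local flora of a study site
#'
#' @param families,genera,species character vectors of taxa recorded at the
#'   site.
#' @param congener_map named character vector mapping species absent from
#'   the site to the congeneric species known to be present (values must be
#'   in `species`).
#' @return object of class `local_flora`.
#' @export
local_flora <- function(families = character(0), genera = character(0),
                        species = character(0),
                        congener_map = character(0)) {
  if (length(congener_map) && !all(congener_map %in% species))
    stop("congener_map values must be species present in the local flora")
  structure(list(families = families, genera = genera, species = species,
                 congener_map = congener_map), class = "local_flora")
}

#' Read a local-flora whitelist from TSV
#'
#' @param path TSV with columns rank (family/genus/species), name, and
#'   optional local_replacement (for species absent at the site whose
#'   sequences should be reassigned to a local congener).
#' @return a [local_flora()] object.
#' @export
read_local_flora_tsv <- function(path) {
  f <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rank", "name") %in% names(f)))
  repl <- f$local_replacement %||% rep(NA_character_, nrow(f))
  cm <- setNames(repl[f$rank == "species" & !is.na(repl) & nzchar(repl)],
                 f$name[f$rank == "species" & !is.na(repl) & nzchar(repl)])
  present <- is.na(repl) | !nzchar(repl)
  local_flora(families = f$name[f$rank == "family"],
              genera = f$name[f$rank == "genus"],
              species = f$name[f$rank == "species" & present],
              congener_map = cm)
}

#' Clean assignments against the local flora
#'
#' Assignments to families or genera not recorded at the study site are
#' treated as identification errors or contamination and removed from all
#' downstream counts. Species-level assignments to a species absent from
#' the site but whose genus has a designated local congener are reassigned
#' to that congener; species absent with no designated congener are demoted
#' to genus rank.
#'
#' @param assignments output of [assign_variants()].
#' @param flora a [local_flora()].
#' @return same-length data frame with updated status
#'   (kept / removed_absent_taxon / reassigned_congener); the removed read
#'   fraction is attached as attribute `removed_fraction`.
#' @export
filter_by_local_flora <- function(assignments, flora) {
  stopifnot(inherits(flora, "local_flora"))
  a <- assignments
  if (!length(flora$families) && !length(flora$genera) &&
      !length(flora$species)) {
    warning("empty local flora: nothing removed")
    attr(a, "removed_fraction") <- 0
    return(a)
  }
  for (i in seq_len(nrow(a))) {
    if (a$rank[i] == "unidentified") next
    if (!(a$family[i] %in% flora$families)) {
      a$status[i] <- "removed_absent_taxon"; next
    }
    if (a$rank[i] %in% c("genus", "species") &&
        !(a$genus[i] %in% flora$genera)) {
      a$status[i] <- "removed_absent_taxon"; next
    }
    if (a$rank[i] == "species" && !(a$species[i] %in% flora$species)) {
      repl <- flora$congener_map[a$species[i]]
      if (!is.na(repl)) {
        a$species[i] <- unname(repl)
        a$status[i] <- "reassigned_congener"
      } else {
        a$species[i] <- NA_character_
        a$rank[i] <- "genus"
      }
    }
  }
  removed <- sum(a$reads[a$status == "removed_absent_taxon"])
  attr(a, "removed_fraction") <- if (sum(a$reads) > 0) removed / sum(a$reads) else 0
  a
}

#' Aggregate assigned reads to a taxonomic rank
#'
#' Reads of kept and reassigned variants are summed per (sample, marker,
#' taxon); variants unresolved at the requested rank fall into an
#' `"unidentified"` bucket; removed variants are dropped.
#'
#' @param assignments filtered assignments.
#' @param rank one of `"family"`, `"genus"`, `"species"`.
#' @return long data frame: sample_id, marker, taxon, reads.
#' @export
aggregate_to_rank <- function(assignments, rank = "family") {
  rank <- match.arg(rank, c("family", "genus", "species"))
  a <- assignments[assignments$status != "removed_absent_taxon", , drop = FALSE]
  taxon <- a[[rank]]
  taxon[is.na(taxon)] <- "unidentified"
  if (nrow(a) == 0)
    return(data.frame(sample_id = character(0), marker = character(0),
                      taxon = character(0), reads = numeric(0)))
  out <- aggregate(reads ~ sample_id + marker + taxon,
                   data = data.frame(sample_id = a$sample_id,
                                     marker = a$marker, taxon = taxon,
                                     reads = a$reads),
                   FUN = sum)
  out[order(out$sample_id, out$marker, out$taxon), , drop = FALSE]
}

#' Read-weighted taxonomic resolution summary
#'
#' Proportion of (non-removed) reads identified at the family, genus and
#' species ranks, optionally after excluding one or more families — used in
#' practice to show how a low-resolution dominant family (Salicaceae for
#' the g-h marker) depresses genus- and species-level resolution.
#'
#' @param assignments assignments (filtered or not).
#' @param exclude_families character vector of families to drop before
#'   computing.
#' @return named numeric vector: family, genus, species proportions.
#' @export
resolution_summary <- function(assignments, exclude_families = character(0)) {
  a <- assignments[assignments$status != "removed_absent_taxon", , drop = FALSE]
  if (length(exclude_families))
    a <- a[is.na(a$family) | !(a$family %in% exclude_families), , drop = FALSE]
  tot <- sum(a$reads)
  if (tot == 0) stop("no reads in scope")
  at <- function(ranks) sum(a$reads[a$rank %in% ranks]) / tot
  c(family = at(c("family", "genus", "species")),
    genus = at(c("genus", "species")),
    species = at("species"))
}
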