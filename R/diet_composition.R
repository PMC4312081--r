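#' Per-marker family proportions
#'
#' Converts one sample's family read counts for one marker into diet
#' proportions, optionally restricted to a taxonomic group first. For the
#' seed-plant-biased g-h marker the vascular restriction discards the few
#' bryophyte reads before normalizing.
#'
#' @param counts named numeric vector of reads per family.
#' @param groups named character vector mapping each family to
#'   `"vascular"` (ferns included) or `"bryophyte"`.
#' @param restrict `"all"`, `"vascular"` or `"bryophyte"`.
#' @param sample_id,marker optional labels used in error messages.
#' @return named proportions summing to 1 over the restricted family set.
#' @export
marker_family_proportions <- function(counts, groups, restrict = "all",
                                      sample_id = NULL, marker = NULL) {
  restrict <- match.arg(restrict, c("all", "vascular", "bryophyte"))
  if (any(counts < 0)) stop("negative counts")
  miss <- setdiff(names(counts), names(groups))
  if (length(miss)) stop("families without group tag: ",
                         paste(miss, collapse = ", "))
  if (restrict != "all")
    counts <- counts[groups[names(counts)] == restrict]
  tot <- sum(counts)
  if (tot <= 0)
    stop("zero in-scope reads",
         if (!is.null(sample_id)) paste0(" for sample ", sample_id),
         if (!is.null(marker)) paste0(", marker ", marker))
  counts / tot
}

#' Fuse the two trnL markers into one diet profile
#'
#' Combines, for one sample, the vascular-plant resolution of the g-h
#' marker with the vascular:bryophyte balance of the universal c-h marker:
#' the g-h vascular family proportions are multiplied by the overall
#' vascular read fraction V of the c-h marker, and the c-h bryophyte family
#' proportions (renormalized within bryophytes) fill the remaining 1 - V.
#' If the g-h amplification failed (zero usable vascular reads), the c-h
#' vascular family proportions are used directly.
#'
#' @param gh named numeric read counts per family for the g-h marker (may
#'   be empty or all-zero).
#' @param ch named numeric read counts per family for the c-h marker.
#' @param groups family -> group ("vascular"/"bryophyte") map.
#' @param sample_id optional label for error messages.
#' @return named proportions over the union of families, summing to 1,
#'   with attribute `gh_failed` indicating the fallback path.
#' @export
fuse_markers <- function(gh, ch, groups, sample_id = NULL) {
  if (sum(ch) <= 0) {
    if (sum(gh) <= 0) stop("both markers empty",
                           if (!is.null(sample_id)) paste0(" for ", sample_id))
    stop("c-h marker empty", if (!is.null(sample_id)) paste0(" for ", sample_id),
         "; vascular:bryophyte split undefined")
  }
  ch_grp <- groups[names(ch)]
  V <- sum(ch[ch_grp == "vascular"]) / sum(ch)
  gh_failed <- sum(gh[groups[names(gh)] == "vascular"]) <= 0
  vasc <- if (!gh_failed) {
    marker_family_proportions(gh, groups, "vascular", sample_id, "g-h")
  } else if (V > 0) {
    marker_family_proportions(ch, groups, "vascular", sample_id, "c-h")
  } else numeric(0)
  bryo <- if (V < 1) {
    marker_family_proportions(ch, groups, "bryophyte", sample_id, "c-h")
  } else numeric(0)
  out <- c(vasc * V, bryo * (1 - V))
  out <- out[out >= 0]
  structure(out, gh_failed = gh_failed)
}

#' Build fused diet profiles for all samples
#'
#' Drives [fuse_markers()] over a long count table (as produced by
#' [aggregate_to_rank()]) holding both markers, returning the sample x
#' family composition matrix on the union family universe.
#'
#' @param counts_long data frame: sample_id, marker, taxon, reads, with
#'   markers named in `gh_marker` / `ch_marker`.
#' @param groups family -> group map.
#' @param gh_marker,ch_marker marker labels (defaults `"g-h"`, `"c-h"`).
#' @param include_unidentified if `FALSE` (default) the `"unidentified"`
#'   bucket is dropped before computing proportions.
#' @return numeric matrix (samples x families), rows summing to 1.
#' @export
diet_profiles <- function(counts_long, groups, gh_marker = "g-h",
                          ch_marker = "c-h", include_unidentified = FALSE) {
  if (!include_unidentified)
    counts_long <- counts_long[counts_long$taxon != "unidentified", , drop = FALSE]
  samples <- unique(counts_long$sample_id)
  fams <- sort(intersect(unique(counts_long$taxon), names(groups)))
  out <- matrix(0, length(samples), length(fams),
                dimnames = list(samples, fams))
  for (s in samples) {
    sub <- counts_long[counts_long$sample_id == s, , drop = FALSE]
    gv <- sub[sub$marker == gh_marker, ]
    cv <- sub[sub$marker == ch_marker, ]
    gh <- setNames(gv$reads, gv$taxon)
    ch <- setNames(cv$reads, cv$taxon)
    p <- fuse_markers(gh, ch, groups, sample_id = s)
    out[s, names(p)] <- p
  }
  out
}

#' Aggregate a diet profile over broader groups
#'
#' Sums family proportions into labelled groups (e.g. dicot / monocot /
#' moss clades); the result sums to whatever the input summed to and is
#' invariant to family ordering.
#'
#' @param p named proportions per family.
#' @param by named character vector family -> group label.
#' @return named numeric vector of group proportions.
#' @export
aggregate_profile <- function(p, by) {
  miss <- setdiff(names(p), names(by))
  if (length(miss)) stop("families without tag: ", paste(miss, collapse = ", "))
  tapply(unname(p), factor(by[names(p)]), sum)[]
}

#' Population mean diet over a set of profiles
#'
#' Unweighted arithmetic mean per family (each pellet sample carries equal
#' weight), built on the union family universe with absent families filled
#' as 0. This is the q_j entering trophic niche width, individual
#' specialization and the use side of selection ratios.
#'
#' @param profiles numeric matrix (samples x families) with rows summing
#'   to 1, or a list of named proportion vectors.
#' @param tol tolerance on each row's sum.
#' @return object of class `composition_matrix`: list with `profiles`
#'   (matrix) and `population_mean` (named vector summing to 1).
#' @export
population_mean_diet <- function(profiles, tol = 1e-6) {
  m <- as_profile_matrix(profiles)
  if (nrow(m) == 0) stop("no profiles")
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad)) stop(sum(bad), " profile(s) do not sum to 1")
  structure(list(profiles = m, population_mean = colMeans(m)),
            class = "composition_matrix")
}

#' Coerce profiles to a common-universe matrix
#'
#' @param profiles matrix, data frame, `composition_matrix`, or list of
#'   named proportion vectors (unioned, absentees filled with 0).
#' @return numeric matrix, samples in rows.
#' @export
as_profile_matrix <- function(profiles) {
  if (inherits(profiles, "composition_matrix")) return(profiles$profiles)
  if (is.matrix(profiles)) return(profiles)
  if (is.data.frame(profiles)) return(as.matrix(profiles))
  fams <- sort(unique(unlist(lapply(profiles, names))))
  m <- t(vapply(profiles, expand_to, numeric(length(fams)), taxa = fams))
  colnames(m) <- fams
  if (!is.null(names(profiles))) rownames(m) <- names(profiles)
  m
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("Composition matrix:", nrow(x$profiles), "samples x",
      ncol(x$profiles), "families\n")
  mp <- sort(x$population_mean, decreasing = TRUE)
  cat("  population mean (top):",
      paste0(names(head(mp, 4)), " ", round(head(mp, 4), 3), collapse = ", "),
      "\n")
  invisible(x)
}
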