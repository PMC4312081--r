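#' Availability proportions from biomass quadrats
#'
#' Converts per-quadrat family biomass (g/m2) into availability
#' proportions within a taxonomic group. Each quadrat's in-group biomass
#' (after removing excluded families) is normalized to proportions; the
#' table holds the across-quadrat mean and variance per family. Vascular
#' plants and mosses are sampled with different field techniques, so
#' availability is only comparable within a group; use and availability
#' each sum to 1 within the group.
#'
#' A family abundant but never eaten (Ericaceae, i.e. Cassiope tetragona,
#' 58% of vascular biomass at the study site) is typically excluded, since
#' keeping it would push the selection ratios of every other family
#' upwards.
#'
#' @param quadrats data frame: one row per quadrat with columns `plot_id`,
#'   `habitat`, and one numeric biomass column per family.
#' @param groups family -> group map (`"vascular"` / `"bryophyte"`).
#' @param group which group to tabulate.
#' @param exclude families removed before normalization.
#' @return object of class `availability_table`: list with `pi` (mean
#'   proportions, summing to 1), `var_pi` (across-quadrat variances),
#'   `n_quadrats`, `group`, `excluded`.
#' @export
availability_proportions <- function(quadrats, groups,
                                     group = c("vascular", "bryophyte"),
                                     exclude = character(0)) {
  group <- match.arg(group)
  fam_cols <- setdiff(names(quadrats), c("plot_id", "habitat"))
  fams <- fam_cols[groups[fam_cols] == group & !(fam_cols %in% exclude)]
  if (length(fams) == 0) stop("no families of group '", group, "' in table")
  b <- as.matrix(quadrats[, fams, drop = FALSE])
  if (any(b < 0)) stop("negative biomass")
  tot <- rowSums(b)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " quadrat(s) with zero in-group biomass dropped")
    b <- b[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (nrow(b) < 2) stop("need >= 2 usable quadrats")
  p <- b / tot
  structure(list(pi = colMeans(p), var_pi = apply(p, 2, var),
                 n_quadrats = nrow(b), group = group, excluded = exclude),
            class = "availability_table")
}

#' @export
print.availability_table <- function(x, ...) {
  cat("Availability (", x$group, ", n = ", x$n_quadrats, " quadrats",
      if (length(x$excluded)) paste0(", excluding ",
                                     paste(x$excluded, collapse = ", ")),
      "):\n", sep = "")
  print(round(sort(x$pi, decreasing = TRUE), 3))
  invisible(x)
}

#' Restrict diet profiles to a group and renormalize
#'
#' Prepares the use side of a selection analysis: keeps only the families
#' of the requested group (minus exclusions), renormalizes each sample's
#' proportions to 1, and drops samples with no reads in scope.
#'
#' @param profiles samples x families proportion matrix.
#' @param groups family -> group map.
#' @param group `"vascular"` or `"bryophyte"`.
#' @param exclude families dropped before renormalization.
#' @return matrix of renormalized use profiles.
#' @export
restrict_profiles <- function(profiles, groups,
                              group = c("vascular", "bryophyte"),
                              exclude = character(0)) {
  group <- match.arg(group)
  m <- as_profile_matrix(profiles)
  fams <- colnames(m)[groups[colnames(m)] == group & !(colnames(m) %in% exclude)]
  m <- m[, fams, drop = FALSE]
  tot <- rowSums(m)
  if (any(tot == 0))
    warning(sum(tot == 0), " sample(s) with no in-group diet dropped")
  m <- m[tot > 0, , drop = FALSE]
  m / rowSums(m)
}

#' Manly selection ratios with sampled availability
#'
#' The selection ratio of food item i is w_i = mean use / mean
#' availability; w > 1 indicates selection, w < 1 avoidance. Both use
#' (diet proportions over n_o pellet samples) and availability
#' (proportions over n_pi quadrats) are sample means, so the variance of
#' the ratio carries both sampling components (delta method for a ratio
#' of independent means):
#' Var(w_i) = s2_o / (n_o pi^2) + o^2 s2_pi / (n_pi pi^4).
#'
#' Families present in the diet but never found in the availability
#' quadrats (pi = 0) get class `"NC"`: selection cannot be calculated.
#'
#' @param use matrix of use profiles restricted and renormalized with
#'   [restrict_profiles()] under the same group and exclusions as `avail`.
#' @param avail an [availability_proportions()] table.
#' @return data frame of class `selection_result`: family, pi, use (mean),
#'   w, se, cls.
#' @export
manly_selection <- function(use, avail) {
  stopifnot(inherits(avail, "availability_table"))
  use <- as_profile_matrix(use)
  fams <- union(colnames(use), names(avail$pi))
  n_o <- nrow(use)
  o_bar <- expand_to(colMeans(use), fams)
  s2_o <- expand_to(apply(use, 2, var), fams)
  pi_bar <- expand_to(avail$pi, fams)
  s2_pi <- expand_to(avail$var_pi, fams)
  w <- ifelse(pi_bar > 0, o_bar / pi_bar, NA_real_)
  se <- ifelse(pi_bar > 0,
               sqrt(s2_o / (n_o * pi_bar^2) +
                    o_bar^2 * s2_pi / (avail$n_quadrats * pi_bar^4)),
               NA_real_)
  cls <- ifelse(pi_bar == 0 & o_bar > 0, "NC",
                mapply(classify_selection, w, se))
  cls[pi_bar == 0 & o_bar == 0] <- "0"
  out <- data.frame(family = fams, pi = pi_bar, use = o_bar,
                    w = w, se = se, cls = cls, row.names = NULL)
  out <- out[order(-out$use), , drop = FALSE]
  class(out) <- c("selection_result", "data.frame")
  out
}

#' Significance class of a selection ratio
#'
#' Maps (w, SE) to the symbols used in selection tables via a z-score
#' against neutrality, z = |w - 1| / SE: `+`/`-` for |z| > 1.96 (clear
#' selection/avoidance), `(+)`/`(-)` for 1.28 < z <= 1.96 (tendency), and
#' `0` otherwise. A zero SE with w != 1 yields the unparenthesized sign.
#' The 1.96/1.28 thresholds correspond to two-sided 5% and ~20% levels
#' and were calibrated to reproduce published selection tables.
#'
#' @param w selection ratio (>= 0).
#' @param se its standard error (>= 0).
#' @return one of `"-"`, `"(-)"`, `"0"`, `"(+)"`, `"+"`.
#' @export
classify_selection <- function(w, se) {
  if (is.na(w) || is.na(se)) return(NA_character_)
  if (se < 0) stop("se must be >= 0")
  sgn <- if (w > 1) "+" else "-"
  if (se == 0) return(if (w == 1) "0" else sgn)
  z <- abs(w - 1) / se
  if (z > 1.96) sgn
  else if (z > 1.28) paste0("(", sgn, ")")
  else "0"
}

#' @export
print.selection_result <- function(x, digits = 3, ...) {
  y <- x
  y$pi <- round(y$pi, digits); y$use <- round(y$use, digits)
  y$w <- round_half_up(y$w, 1); y$se <- signif(y$se, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
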