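#' Schoener's diet overlap index
#'
#' O = 1 - 0.5 * sum_j |p_j - q_j| over the union of taxa: 0 for disjoint
#' diets, 1 for identical diets. Symmetric in its arguments, and equal to
#' sum_j min(p_j, q_j).
#'
#' @param p,q named proportion vectors (each summing to 1 within `tol`).
#' @param tol tolerance on each profile's sum; the default is strict, but
#'   a looser value (e.g. 0.02) accommodates profiles re-assembled from
#'   rounded published percentages.
#' @return the overlap value in \[0, 1\].
#' @export
schoener_overlap <- function(p, q, tol = 1e-6) {
  check_proportions(p, tol, "p"); check_proportions(q, tol, "q")
  taxa <- union(names(p), names(q))
  if (is.null(names(p)) || is.null(names(q))) {
    if (length(p) != length(q)) stop("unnamed profiles of unequal length")
    pe <- p; qe <- q
  } else {
    pe <- expand_to(p, taxa); qe <- expand_to(q, taxa)
  }
  max(0, min(1, 1 - 0.5 * sum(abs(pe - qe))))
}

#' Drop taxa from a profile and renormalize
#'
#' Used e.g. to recompute overlap excluding a dominant family
#' (Salicaceae), isolating how much of the overlap that family alone
#' carries.
#'
#' @param p named proportion vector.
#' @param excluded character vector of taxa to drop (their total share
#'   must be < 1).
#' @return renormalized proportions over the remaining taxa.
#' @export
exclude_and_renormalize <- function(p, excluded) {
  keep <- !(names(p) %in% excluded)
  s <- sum(p[keep])
  if (s <= 0) stop("exclusion removes all mass")
  p[keep] / s
}

#' Trophic niche width (Shannon entropy)
#'
#' TNW = -sum_j q_j log(q_j) of the population mean diet, with
#' 0 * log(0) := 0. In natural log units (nats) by default.
#'
#' @param q named proportion vector (population diet).
#' @param base logarithm base (`exp(1)` for nats).
#' @param tol tolerance on the sum.
#' @return entropy in \[0, log(K)\].
#' @export
trophic_niche_width <- function(q, base = exp(1), tol = 1e-6) {
  check_proportions(q, tol, "q")
  qq <- q[q > 0]
  -sum(qq * log(qq)) / log(base)
}

#' Individual specialization index
#'
#' IS = mean over individuals of the Schoener overlap between each
#' individual's diet and the population mean diet (each pellet sample is
#' treated as one individual). IS = 1 means every individual eats the
#' population diet; lower values indicate individual specialization.
#'
#' @param cm a [population_mean_diet()] result, or a profile matrix /
#'   list of profiles (>= 2 individuals).
#' @param tol row-sum tolerance.
#' @return IS in (0, 1].
#' @export
individual_specialization <- function(cm, tol = 1e-6) {
  if (!inherits(cm, "composition_matrix")) cm <- population_mean_diet(cm, tol)
  m <- cm$profiles
  if (nrow(m) < 2) stop("need at least two individuals")
  q <- cm$population_mean
  mean(vapply(seq_len(nrow(m)),
              function(i) 1 - 0.5 * sum(abs(m[i, ] - q)), numeric(1)))
}

#' Resampled individual specialization
#'
#' Recomputes IS on repeated random subsamples of individuals (drawn
#' without replacement, each subsample using its own subsample mean diet),
#' to make IS comparable between groups of unequal sample size — e.g.
#' resampling the larger species down to the smaller species' n.
#'
#' @param cm profiles (see [individual_specialization()]).
#' @param n_sub subsample size (<= number of individuals).
#' @param n_rep number of replicates.
#' @param seed integer seed for reproducibility.
#' @return list with `mean`, `sd`, and the replicate `values`.
#' @export
resampled_is <- function(cm, n_sub, n_rep = 100, seed = 1) {
  m <- if (inherits(cm, "composition_matrix")) cm$profiles else as_profile_matrix(cm)
  n <- nrow(m)
  if (n_sub > n) stop("n_sub exceeds the number of individuals")
  if (n_rep < 1) stop("n_rep must be >= 1")
  set.seed(seed)
  vals <- vapply(seq_len(n_rep), function(r) {
    idx <- sample.int(n, n_sub)
    individual_specialization(m[idx, , drop = FALSE])
  }, numeric(1))
  list(mean = mean(vals), sd = if (n_rep > 1) sd(vals) else 0, values = vals)
}

#' One-way ANOVA on rank-transformed data
#'
#' Values are replaced by mid-ranks over the pooled sample and a one-way
#' fixed-effects F-test is run on the ranks — the robust test used when
#' variances are heterogeneous and residuals non-normal, as is typical for
#' diet proportions.
#'
#' @param values numeric measurements.
#' @param groups factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 observations each.
#' @return list with `F`, `df` (numerator, denominator) and `p`.
#' @export
rank_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  r <- rank(values)            # mid-ranks on ties
  fit <- anova(lm(r ~ groups))
  list(F = fit[1, "F value"], df = c(fit[1, "Df"], fit[2, "Df"]),
       p = fit[1, "Pr(>F)"])
}

#' Aligned rank transform test for a two-factor interaction
#'
#' Tests the A x B interaction nonparametrically: observations are aligned
#' for the interaction by removing the estimated main effects
#' (Y - rowmean_a - colmean_b + grand mean, cell-mean based), the aligned
#' values are ranked, and a two-way ANOVA with interaction is fitted on
#' the ranks; the interaction F and p are returned.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors; every cell must be non-empty
#'   with >= 2 replicates.
#' @return list with `F`, `df` and `p` for the interaction; constant data
#'   yield F = 0, p = 1.
#' @export
aligned_rank_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("each factor needs >= 2 levels (empty cell or single-level factor)")
  cells <- table(a, b)
  if (any(cells == 0)) stop("empty cell in the two-factor layout")
  if (any(cells < 2)) stop("every cell needs >= 2 replicates")
  cm <- tapply(values, list(a, b), mean)
  am <- rowMeans(cm); bm <- colMeans(cm); gm <- mean(cm)
  aligned <- values - am[a] - bm[b] + gm
  if (all(abs(aligned - aligned[1]) < 1e-12))
    return(list(F = 0, df = c((nlevels(a) - 1) * (nlevels(b) - 1),
                              length(values) - nlevels(a) * nlevels(b)),
                p = 1))
  r <- rank(aligned)
  fit <- anova(lm(r ~ a * b))
  i <- which(rownames(fit) == "a:b")
  list(F = fit[i, "F value"], df = c(fit[i, "Df"], fit["Residuals", "Df"]),
       p = fit[i, "Pr(>F)"])
}
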