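#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with halves rounded up (away from
#' zero), the convention used when comparing against values printed in
#' ecological tables. Base R's `round()` rounds halves to even, which
#' disagrees with printed tables for values such as 0.25.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Draw from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha concentration vector (all > 0 entries; zeros allowed and
#'   yield structural zeros in the draws).
#' @return an `n` x `length(alpha)` matrix with rows summing to 1.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(0, n, k)
  pos <- alpha > 0
  x[, pos] <- matrix(rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
                     n, sum(pos))
  sw <- rowSums(x)
  if (any(sw == 0)) stop("Dirichlet draw with all-zero concentration")
  x / sw
}

# Named-vector helper: align x onto the name universe `taxa`, filling 0.
expand_to <- function(x, taxa) {
  out <- setNames(numeric(length(taxa)), taxa)
  if (length(x)) out[names(x)] <- x
  out
}

check_proportions <- function(p, tol = 1e-6, what = "profile") {
  if (any(p < 0)) stop(what, " contains negative proportions")
  s <- sum(p)
  if (abs(s - 1) > tol)
    stop(what, " does not sum to 1 (sum = ", format(s), ", tol = ", tol, ")")
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
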