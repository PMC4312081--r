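#' Read a quadrat availability table
#'
#' @param path TSV with columns plot_id, habitat and one biomass column
#'   (g/m2) per family.
#' @return data frame suitable for [availability_proportions()].
#' @export
read_availability_tsv <- function(path) {
  q <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("plot_id", "habitat") %in% names(q)))
  q
}

#' Write a samples-by-families composition matrix as TSV
#'
#' @param profiles matrix from [diet_profiles()] (sample ids in
#'   rownames).
#' @param path output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  df <- data.frame(sample_id = rownames(profiles), profiles,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a composition matrix written by [write_profiles_tsv()]
#'
#' @param path TSV path.
#' @return numeric matrix with sample ids as rownames.
#' @export
read_profiles_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  m
}
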