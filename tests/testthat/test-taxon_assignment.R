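# a tiny hand-built index: two Salix species share an amplicon, a Poa
# species has its own, a Pinus genus-level record exercises flora removal
toy_library <- function() {
  pr <- primer_pair("toy", "ACGTACGTAA", "TTGGCCAATT", max_mismatch = 0)
  recs <- data.frame(
    record_id = c("s1", "s2", "p1", "pin"),
    family = c("Salicaceae", "Salicaceae", "Poaceae", "Pinaceae"),
    genus = c("Salix", "Salix", "Poa", "Pinus"),
    species = c("Salix arctica", "Salix herbacea", "Poa arctica", NA),
    sequence = NA)
  amps <- c("ATCGATCGATCG", "ATCGATCGATCG", "GGCCGGCCTTAA", "TTAACCGGTTAA")
  recs$sequence <- paste0(pr$forward, amps, revcomp(pr$reverse))
  in_silico_pcr(ref_library(recs), pr)
}

test_that("exact matches resolve to the lowest common ancestor", {
  lib <- toy_library()
  v <- data.frame(sample_id = "a", marker = "toy",
                  sequence = c("GGCCGGCCTTAA", "ATCGATCGATCG"),
                  reads = c(5, 10))
  a <- assign_variants(v, lib)
  # unique species -> species rank
  expect_equal(a$rank[1], "species")
  expect_equal(a$species[1], "Poa arctica")
  # two congeneric references share the amplicon -> genus rank
  expect_equal(a$rank[2], "genus")
  expect_equal(a$genus[2], "Salix")
  expect_true(is.na(a$species[2]))
})

test_that("fuzzy matching respects the identity threshold and no-match yields unidentified", {
  lib <- toy_library()
  v <- data.frame(sample_id = "a", marker = "toy",
                  sequence = c("GGCCGGCCTTAT",      # 1 sub: identity 11/12
                               "AAAAAAAAAAAA"),     # nothing close
                  reads = c(3, 2))
  a <- assign_variants(v, lib, identity_threshold = 0.90)
  expect_equal(a$family[1], "Poaceae")
  expect_equal(a$rank[2], "unidentified")
  # at a stricter threshold the 1-substitution variant fails too
  a2 <- assign_variants(v, lib, identity_threshold = 0.95)
  expect_equal(a2$rank[1], "unidentified")
})

test_that("assignment recovers the source family of noisy synthetic variants", {
  tr <- generate_truth("bylot-like", seed = 21)
  lib <- generate_reference_library(tr, seed = 21)
  lib_gh <- in_silico_pcr(lib, trnl_primers()[["g-h"]])
  sim <- generate_sample_counts(tr, c(Dicrostonyx = 10, Lemmus = 20),
                                lib = lib, error_rate = 0.01, seed = 22)
  v <- sim$variants[sim$variants$marker == "g-h", ]
  expect_gt(nrow(v), 500)
  a <- assign_variants(v, lib_gh, identity_threshold = 0.95)
  acc <- sum(a$reads[!is.na(a$family) & a$family == a$true_family]) /
    sum(a$reads)
  expect_gte(acc, 0.95)
})

test_that("local-flora filtering removes absent taxa and reassigns congeners", {
  flora <- local_flora(
    families = c("Salicaceae", "Poaceae"),
    genera = c("Salix", "Poa"),
    species = c("Salix arctica", "Poa arctica"),
    congener_map = c("Salix lanata" = "Salix arctica"))
  a <- data.frame(
    sample_id = "a", marker = "toy", sequence = c("x1", "x2", "x3", "x4"),
    reads = c(7, 10, 20, 3),
    family = c("Pinaceae", "Salicaceae", "Salicaceae", "Poaceae"),
    genus = c("Pinus", "Salix", "Salix", "Poa"),
    species = c(NA, "Salix lanata", "Salix arctica", "Poa arctica"),
    rank = c("genus", "species", "species", "species"),
    status = "kept")
  f <- filter_by_local_flora(a, flora)
  expect_equal(f$status, c("removed_absent_taxon", "reassigned_congener",
                           "kept", "kept"))
  expect_equal(f$species[2], "Salix arctica")
  expect_equal(f$genus[2], "Salix")      # genus and family untouched
  expect_equal(attr(f, "removed_fraction"), 7 / 40)
  # all-local assignments are a no-op
  f2 <- filter_by_local_flora(a[3:4, ], flora)
  expect_equal(f2$status, c("kept", "kept"))
  expect_equal(attr(f2, "removed_fraction"), 0)
  # empty flora removes nothing, with a warning
  expect_warning(f3 <- filter_by_local_flora(a, local_flora()), "empty")
  expect_equal(attr(f3, "removed_fraction"), 0)
})

test_that("flora TSV round-trip drives the same filtering", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rank\tname\tlocal_replacement",
               "family\tSalicaceae\t",
               "genus\tSalix\t",
               "species\tSalix arctica\t",
               "species\tSalix lanata\tSalix arctica"), f)
  flora <- read_local_flora_tsv(f)
  expect_equal(unname(flora$congener_map["Salix lanata"]), "Salix arctica")
  expect_false("Salix lanata" %in% flora$species)
})

test_that("rank aggregation is additive and conserves reads", {
  a <- data.frame(
    sample_id = "a", marker = "toy", sequence = paste0("v", 1:4),
    reads = c(10, 5, 7, 4),
    family = c("Salicaceae", "Salicaceae", "Pinaceae", NA),
    genus = c("Salix", "Salix", "Pinus", NA),
    species = c(NA, NA, NA, NA),
    rank = c("genus", "genus", "genus", "unidentified"),
    status = c("kept", "kept", "removed_absent_taxon", "kept"))
  tab <- aggregate_to_rank(a, "family")
  expect_equal(tab$reads[tab$taxon == "Salicaceae"], 15)
  expect_false("Pinaceae" %in% tab$taxon)
  expect_equal(tab$reads[tab$taxon == "unidentified"], 4)
  # conservation: kept + removed = total in
  expect_equal(sum(tab$reads) + 7, sum(a$reads))
})

test_that("with zero sequencing error the family table equals the generator truth", {
  tr <- generate_truth("bylot-like", seed = 31)
  lib <- generate_reference_library(tr, seed = 31)
  lib_gh <- in_silico_pcr(lib, trnl_primers()[["g-h"]])
  sim <- generate_sample_counts(tr, c(Dicrostonyx = 4, Lemmus = 6),
                                lib = lib, error_rate = 0, seed = 32)
  v <- sim$variants[sim$variants$marker == "g-h", ]
  a <- assign_variants(v, lib_gh)
  tab <- aggregate_to_rank(a, "family")
  truth_tab <- aggregate(reads ~ sample_id + taxon,
                         data = sim$family_counts[
                           sim$family_counts$marker == "g-h", ], FUN = sum)
  m <- merge(tab[tab$taxon != "unidentified", ], truth_tab,
             by = c("sample_id", "taxon"), all = TRUE)
  expect_true(all(!is.na(m$reads.x) & !is.na(m$reads.y)))
  expect_equal(m$reads.x, m$reads.y)
})

test_that("filtering and aggregation are invariant to variant order", {
  tr <- generate_truth("bylot-like", seed = 41)
  lib <- generate_reference_library(tr, seed = 41)
  lib_gh <- in_silico_pcr(lib, trnl_primers()[["g-h"]])
  sim <- generate_sample_counts(tr, c(Dicrostonyx = 3, Lemmus = 3),
                                lib = lib, error_rate = 0.01, seed = 42)
  v <- sim$variants[sim$variants$marker == "g-h", ]
  a1 <- aggregate_to_rank(assign_variants(v, lib_gh), "family")
  set.seed(1)
  v2 <- v[sample(nrow(v)), ]
  a2 <- aggregate_to_rank(assign_variants(v2, lib_gh), "family")
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("resolution summary is read-weighted and honours exclusions", {
  a <- data.frame(
    sample_id = "a", marker = "toy", sequence = paste0("v", 1:2),
    reads = c(50, 50),
    family = c("Salicaceae", "Poaceae"),
    genus = c(NA, "Poa"), species = c(NA, "Poa arctica"),
    rank = c("family", "species"), status = "kept")
  rs <- resolution_summary(a)
  expect_equal(unname(rs), c(1.0, 0.5, 0.5))
  # all-species case
  rs2 <- resolution_summary(a[2, , drop = FALSE])
  expect_equal(unname(rs2), c(1, 1, 1))
  # excluding the low-resolution family lifts genus/species resolution
  rs3 <- resolution_summary(a, exclude_families = "Salicaceae")
  expect_equal(unname(rs3), c(1, 1, 1))
  expect_error(resolution_summary(a[0, ]), "no reads")
})

test_that("read conservation holds per sample through assignment and filtering", {
  tr <- generate_truth("bylot-like", seed = 51)
  lib <- generate_reference_library(tr, seed = 51)
  lib_ch <- in_silico_pcr(lib, trnl_primers()[["c-h"]])
  sim <- generate_sample_counts(tr, c(Dicrostonyx = 3, Lemmus = 3),
                                lib = lib, error_rate = 0.02, seed = 52)
  v <- sim$variants[sim$variants$marker == "c-h", ]
  a <- assign_variants(v, lib_ch)
  flora <- local_flora(families = unique(tr$families$family),
                       genera = unique(lib$records$genus),
                       species = unique(lib$records$species))
  f <- filter_by_local_flora(a, flora)
  tab <- aggregate_to_rank(f, "family")
  for (s in unique(v$sample_id)) {
    reads_in <- sum(v$reads[v$sample_id == s])
    kept <- sum(tab$reads[tab$sample_id == s])
    removed <- sum(f$reads[f$sample_id == s &
                             f$status == "removed_absent_taxon"])
    expect_equal(kept + removed, reads_in)
  }
})
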