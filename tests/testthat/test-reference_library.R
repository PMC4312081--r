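test_that("FASTA reference records parse with lineage tags", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_tiny_fasta(f, c("r1", "r2", "r3"),
                   c("ACGTACGT", "GGGTTTCC", "TTTTAAAA"),
                   family = c("Salicaceae", "Poaceae", "Polytrichaceae"),
                   genus = c("Salix", "Poa", NA),
                   species = c("Salix arctica", NA, NA),
                   division = c("Spermatophyta", "Spermatophyta", "Bryophyta"))
  lib <- read_reference_fasta(f)
  expect_s3_class(lib, "ref_library")
  expect_equal(nrow(lib$records), 3)
  expect_equal(lib$n_skipped, 0)
  expect_equal(lib$records$species[1], "Salix arctica")
  expect_true(is.na(lib$records$genus[3]))
})

test_that("records with malformed lineage are skipped and counted", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_tiny_fasta(f, c("ok", "nofam"), c("ACGT", "ACGT"),
                   family = c("Salicaceae", NA),
                   genus = c("Salix", "Pinus"))
  expect_warning(lib <- read_reference_fasta(f), "skipped")
  expect_equal(nrow(lib$records), 1)
  expect_equal(lib$n_skipped, 1)
})

test_that("a bryophyte-scale synthetic library round-trips through FASTA with exact rank bookkeeping", {
  tr <- generate_truth("bylot-like", seed = 11)
  lib <- generate_reference_library(tr, genera_per_family = 5,
                                    species_per_genus = 4)
  tc <- attr(lib, "truth_counts")
  expect_equal(nrow(lib$records), tc$records)
  expect_equal(length(unique(lib$records$family)), tc$families)
  expect_equal(length(unique(lib$records$genus)), tc$genera)
  expect_equal(length(unique(lib$records$species)), tc$species)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(lib, f)
  lib2 <- read_reference_fasta(f)
  expect_equal(lib2$records, lib$records)
})

test_that("in-silico PCR extracts the between-primer insert exactly", {
  pr <- primer_pair("toy", "ACGTACGTAA", "TTGGCCAATT", max_mismatch = 0)
  insert <- "ATCG"
  seqq <- paste0(pr$forward, insert, revcomp(pr$reverse))
  lib <- ref_library(data.frame(record_id = "r1", family = "Salicaceae",
                                sequence = seqq))
  out <- in_silico_pcr(lib, pr)
  expect_equal(out$index$amplicon, "ATCG")
  expect_equal(out$n_no_amplicon, 0)
})

test_that("a primer with more mismatches than the budget excludes the record", {
  pr <- primer_pair("toy", "AAAAAAAAAAAA", "CCCCCCCCCCCC", max_mismatch = 5)
  fwd_6mm <- "CCCCCCAAAAAA"   # 6 mismatches vs the all-A forward primer
  expect_equal(bf_mismatches_at(pr$forward, fwd_6mm, 1), 6)
  # every other offset carries >= 6 mismatches too (at most 6 A's per window)
  seqq <- paste0(fwd_6mm, "TTTTTTTT", revcomp(pr$reverse))
  lib <- ref_library(data.frame(record_id = "r1", family = "Poaceae",
                                sequence = seqq))
  out <- in_silico_pcr(lib, pr)
  expect_equal(nrow(out$index), 0)
  expect_equal(out$n_no_amplicon, 1)
})

test_that("mismatch tolerance agrees with a brute-force scan and is monotone", {
  tr <- generate_truth("bylot-like", seed = 5)
  lib <- generate_reference_library(tr, mutate_frac = 0.10, mutate_n = 3,
                                    seed = 42)
  pr5 <- trnl_primers(5)[["g-h"]]
  pr2 <- trnl_primers(2)[["g-h"]]
  out5 <- in_silico_pcr(lib, pr5)
  out2 <- in_silico_pcr(lib, pr2)
  # 3 planted substitutions stay within a 5-mismatch budget
  expect_equal(out5$n_no_amplicon, 0)
  # at budget 2, exactly the records whose true mismatch count exceeds 2
  # (computed by the brute-force scanner) drop out
  rc_rev <- revcomp(pr2$reverse)
  bf_retained <- vapply(seq_len(nrow(lib$records)), function(i) {
    s <- lib$records$sequence[i]
    f <- bf_primer_scan(pr2$forward, s, 2)
    if (nrow(f) == 0) return(FALSE)
    r <- bf_primer_scan(rc_rev, s, 2)
    any(r$start > min(f$end))
  }, logical(1))
  expect_setequal(out2$index$record_id, lib$records$record_id[bf_retained])
  # monotone: retained set at k is a subset of retained at k+1
  for (k in 0:4) {
    rk <- in_silico_pcr(lib, trnl_primers(k)[["g-h"]])$index$record_id
    rk1 <- in_silico_pcr(lib, trnl_primers(k + 1)[["g-h"]])$index$record_id
    expect_true(all(rk %in% rk1))
  }
})

test_that("in-silico PCR is idempotent on reconstructed amplicons", {
  tr <- generate_truth("bylot-like", seed = 3)
  lib <- generate_reference_library(tr)
  pr <- trnl_primers()[["g-h"]]
  idx1 <- in_silico_pcr(lib, pr)$index
  rebuilt <- ref_library(data.frame(
    record_id = idx1$record_id, family = idx1$family, genus = idx1$genus,
    species = idx1$species,
    sequence = paste0(pr$forward, idx1$amplicon, revcomp(pr$reverse))))
  idx2 <- in_silico_pcr(rebuilt, pr)$index
  expect_equal(idx2$amplicon, idx1$amplicon)
  expect_equal(idx2$record_id, idx1$record_id)
})

test_that("amplicon index exports one row per lineage", {
  tr <- generate_truth("bylot-like", seed = 3)
  lib <- in_silico_pcr(generate_reference_library(tr), trnl_primers()[["g-h"]])
  tab <- amplicon_index_table(lib)
  expect_true(all(c("amplicon", "family", "genus", "species") %in% names(tab)))
  expect_equal(nrow(tab), nrow(unique(tab)))
  f <- withr::local_tempfile(fileext = ".tsv")
  amplicon_index_table(lib, f)
  expect_equal(nrow(read.delim(f)), nrow(tab))
})

test_that("diagnostic site pairs: degenerate cases", {
  # one diagnostic dinucleotide only -> no pair
  expect_equal(nrow(find_diagnostic_site_pairs("AATTGGCC", "AACCGGCC",
                                               c(0, 10))), 0)
  # identical sequence sets -> nothing
  expect_equal(nrow(find_diagnostic_site_pairs(c("ACGTACGT", "ACGTACGT"),
                                               c("ACGTACGT"), c(0, 10))), 0)
  # unequal alignment lengths are fatal
  expect_error(find_diagnostic_site_pairs("ACGT", "ACGTA", c(0, 10)),
               "unequal")
  # within-species polymorphism makes a site ineligible
  a <- c("AATTGGCC", "AATAGGCC")   # column 4 polymorphic in species A
  b <- c("AACCGGCC", "AACCGGCC")
  pairs <- find_diagnostic_site_pairs(a, b, c(0, 10))
  expect_equal(nrow(pairs), 0)
})

test_that("two planted diagnostic dinucleotides 61 nt apart are recovered", {
  set.seed(99)
  base <- sample(c("A", "C", "G", "T"), 150, replace = TRUE)
  a <- base; b <- base
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  p1 <- 20; p2 <- p1 + 2 + 61    # 61 bases strictly between the two sites
  for (p in c(p1, p1 + 1, p2, p2 + 1)) b[p] <- flip[[a[p]]]
  res <- find_diagnostic_site_pairs(paste(a, collapse = ""),
                                    paste(b, collapse = ""), c(50, 70))
  expect_equal(nrow(res), 1)
  expect_equal(res$separation, 61)
  expect_equal(res$pos1, p1 - 1)
  expect_equal(res$pos2, p2 - 1)
})

test_that("diagnostic-site search matches the exhaustive column-pair scan", {
  set.seed(7)
  for (rep in 1:5) {
    L <- sample(60:200, 1)
    a1 <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    b1 <- strsplit(a1, "")[[1]]
    nmut <- sample(3:10, 1)
    pos <- sample(L, nmut)
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    for (p in pos) b1[p] <- flip[[b1[p]]]
    b1 <- paste(b1, collapse = "")
    rng <- c(0, L)
    got <- find_diagnostic_site_pairs(a1, b1, rng)
    want <- bf_site_pairs(a1, b1, rng)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$pos1, unname(want[, "pos1"]))
      expect_equal(got$pos2, unname(want[, "pos2"]))
      expect_equal(got$separation, unname(want[, "sep"]))
    }
  }
})

test_that("primer pairs validate their alphabet and budget", {
  expect_error(primer_pair("x", "", "ACGT"), "empty")
  expect_error(primer_pair("x", "ACGT", "ACXT"), "IUPAC")
  expect_error(primer_pair("x", "ACGT", "ACGT", max_mismatch = -1))
  pr <- primer_pair("x", "acgryn", "tgca")
  expect_equal(pr$forward, "ACGRYN")
})
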