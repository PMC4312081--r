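#' Family universe of the High-Arctic study system
#'
#' The plant families of the Bylot-Island-like scenario with their
#' broad-group tags: `group` separates vascular plants (ferns included)
#' from bryophytes, which are measured with different field techniques and
#' analysed separately for selection; `clade` carries the dicot / monocot /
#' moss split used for broad-group diet comparisons (all bryophytes,
#' including the liverwort families, are pooled as "moss", and the
#' horsetails ride with the dicot-free "monocot"-excluded vascular rest —
#' they are tagged `pteridophyte` and counted among vascular plants).
#'
#' @return data frame with columns family, group, clade.
#' @export
bylot_families <- function() {
  data.frame(
    family = c("Salicaceae", "Rosaceae", "Fabaceae", "Polygonaceae",
               "Saxifragaceae", "Caryophyllaceae", "Ericaceae",
               "Poaceae", "Juncaceae", "Cyperaceae", "Equisetaceae",
               "Polytrichaceae", "Aulacomniaceae", "Dicranaceae",
               "Bryaceae", "Grimmiaceae", "Timmiaceae", "Amblystegiaceae",
               "Hylocomiaceae", "Scapaniaceae", "Ditrichaceae",
               "Ptilidiaceae"),
    group = c(rep("vascular", 11), rep("bryophyte", 11)),
    clade = c(rep("dicot", 7), rep("monocot", 3), "pteridophyte",
              rep("moss", 11)),
    stringsAsFactors = FALSE)
}

#' Generate the ground truth of a synthetic diet study
#'
#' Fixes every parameter of the generative model: species mean diets over
#' the family universe, the Dirichlet concentration governing
#' among-individual diet heterogeneity, per-marker amplification bias,
#' mean sequencing depths, and the availability truth (mean proportions,
#' within-group composition concentration, and total-biomass scale).
#'
#' Presets: `"bylot-like"` mimics the headline structure of the study
#' system (Salicaceae-dominated diets; brown lemming with 26% mosses,
#' collared with ~1%; Ericaceae 58% of vascular biomass but uneaten);
#' `"uniform"` gives both species identical uniform diets (truth overlap
#' 1); `"no-overlap"` gives disjoint diets (truth overlap 0).
#'
#' @param preset scenario name.
#' @param seed integer seed stored in the truth and used by the
#'   downstream generators.
#' @return object of class `synthetic_truth`.
#' @export
generate_truth <- function(preset = c("bylot-like", "no-overlap", "uniform"),
                           seed = 1L) {
  preset <- match.arg(preset)
  fam <- bylot_families()
  K <- nrow(fam)
  zero <- setNames(numeric(K), fam$family)
  mk <- function(x) {
    stopifnot(all(names(x) %in% names(zero)))
    d <- zero; d[names(x)] <- x; d / sum(d)
  }
  diets <- switch(preset,
    "bylot-like" = rbind(
      Dicrostonyx = mk(c(Salicaceae = 0.80, Poaceae = 0.12, Juncaceae = 0.02,
                         Rosaceae = 0.01, Caryophyllaceae = 0.01,
                         Polygonaceae = 0.02, Saxifragaceae = 0.01,
                         Polytrichaceae = 0.01)),
      Lemmus = mk(c(Salicaceae = 0.55, Polygonaceae = 0.04,
                    Saxifragaceae = 0.03, Rosaceae = 0.02, Fabaceae = 0.01,
                    Poaceae = 0.07, Juncaceae = 0.02, Polytrichaceae = 0.15,
                    Aulacomniaceae = 0.06, Dicranaceae = 0.03,
                    Bryaceae = 0.02))),
    "uniform" = rbind(Dicrostonyx = zero + 1 / K, Lemmus = zero + 1 / K),
    "no-overlap" = rbind(
      Dicrostonyx = mk(setNames(rep(1, sum(fam$group == "vascular")),
                                fam$family[fam$group == "vascular"])),
      Lemmus = mk(setNames(rep(1, sum(fam$group == "bryophyte")),
                           fam$family[fam$group == "bryophyte"]))))
  avail_v <- mk(c(Ericaceae = 0.580, Salicaceae = 0.300, Juncaceae = 0.047,
                  Poaceae = 0.023, Rosaceae = 0.018, Caryophyllaceae = 0.010,
                  Cyperaceae = 0.008, Fabaceae = 0.006, Equisetaceae = 0.003,
                  Polygonaceae = 0.003, Saxifragaceae = 0.002))
  avail_b <- mk(c(Polytrichaceae = 0.267, Scapaniaceae = 0.228,
                  Amblystegiaceae = 0.195, Hylocomiaceae = 0.193,
                  Ptilidiaceae = 0.043, Aulacomniaceae = 0.027,
                  Ditrichaceae = 0.032, Dicranaceae = 0.015))
  # Bryaceae, Grimmiaceae and Timmiaceae are deliberately absent from the
  # availability truth although consumed: selection is not calculable for
  # them (class NC), as happens for taxa never hit by the sampling plots.
  structure(list(
    preset = preset,
    families = fam,
    groups = setNames(fam$group, fam$family),
    clades = setNames(fam$clade, fam$family),
    species_mean_diets = diets,
    concentration = 15,
    marker_bias = list(
      "g-h" = c(vascular = 1, bryophyte = 0.02),
      "c-h" = c(vascular = 1, bryophyte = 1)),
    reads_per_sample = c("g-h" = 608, "c-h" = 299),
    depth_size = 8,               # negative-binomial size (uneven depths)
    availability_truth = list(
      vascular = expand_to(avail_v[avail_v > 0], fam$family),
      bryophyte = expand_to(avail_b[avail_b > 0], fam$family),
      concentration = 25,         # within-group quadrat composition
      total_gm2 = c(vascular = 250, bryophyte = 150),
      total_sdlog = 0.5),
    seed = as.integer(seed)), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth (preset '", x$preset, "', seed ", x$seed, "):\n",
      sep = "")
  cat("  ", nrow(x$families), " families; concentration ", x$concentration,
      "; depths ", paste(names(x$reads_per_sample), x$reads_per_sample,
                         sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

.rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic P6-loop reference library
#'
#' Builds one reference record per synthetic species, each carrying both
#' primer systems in their natural nesting (c site ... g site ... insert
#' ... h site), so that in-silico PCR with the g-h pair yields the insert
#' and with the c-h pair the longer spacer+insert amplicon. Inserts are
#' random and species-specific, so amplicons are collision-free with
#' overwhelming probability.
#'
#' @param truth a [generate_truth()] result.
#' @param genera_per_family,species_per_genus library richness knobs.
#' @param insert_len length-2 range of the g-h insert (bp).
#' @param mutate_frac fraction of records receiving `mutate_n` random
#'   substitutions inside their forward (g) primer site — used to exercise
#'   the mismatch tolerance of in-silico PCR.
#' @param mutate_n substitutions applied to mutated records.
#' @param seed RNG seed (defaults to the truth's).
#' @return a `ref_library` whose `truth_counts` attribute records the
#'   generated rank bookkeeping (families, genera, species, records).
#' @export
generate_reference_library <- function(truth, genera_per_family = 2L,
                                       species_per_genus = 2L,
                                       insert_len = c(40L, 70L),
                                       mutate_frac = 0, mutate_n = 3L,
                                       seed = NULL) {
  set.seed(seed %||% truth$seed)
  pr <- trnl_primers()
  g_site <- pr[["g-h"]]$forward
  c_site <- pr[["c-h"]]$forward
  h_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pr[["g-h"]]$reverse)))
  fam <- truth$families
  recs <- list(); rid <- 0L
  for (i in seq_len(nrow(fam))) {
    division <- switch(fam$clade[i], moss = "Bryophyta",
                       pteridophyte = "Pteridophyta", "Spermatophyta")
    for (g in seq_len(genera_per_family)) {
      genus <- paste0(sub("aceae$", "", fam$family[i]), "us", g)
      for (s in seq_len(species_per_genus)) {
        rid <- rid + 1L
        insert <- .rand_seq(1, sample(insert_len[1]:insert_len[2], 1))
        spacer <- .rand_seq(1, 20L)
        seqq <- paste0(.rand_seq(1, 10L), c_site, spacer, g_site, insert,
                       h_rc, .rand_seq(1, 10L))
        recs[[rid]] <- data.frame(
          record_id = sprintf("syn%04d", rid), division = division,
          family = fam$family[i], genus = genus,
          species = paste(genus, sprintf("sp%d", s)),
          sequence = seqq, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  n_mut <- 0L
  if (mutate_frac > 0) {
    mut <- runif(nrow(records)) < mutate_frac
    n_mut <- sum(mut)
    for (i in which(mut)) {
      seqq <- strsplit(records$sequence[i], "")[[1]]
      start <- 10L + nchar(c_site) + 20L   # g-site offset
      pos <- start + sample.int(nchar(g_site), mutate_n)
      for (p in pos) seqq[p] <- sample(setdiff(c("A", "C", "G", "T"), seqq[p]), 1)
      records$sequence[i] <- paste(seqq, collapse = "")
    }
    records$g_site_mutated <- mut
  }
  lib <- ref_library(records)
  attr(lib, "truth_counts") <- list(
    families = nrow(fam), genera = nrow(fam) * genera_per_family,
    species = nrow(records), records = nrow(records), mutated = n_mut)
  lib
}

# Emit sequence variants for r reads of one species' amplicon, splitting
# off erroneous copies when error_rate > 0.
.emit_variants <- function(amplicon, r, error_rate) {
  L <- nchar(amplicon)
  if (error_rate <= 0)
    return(data.frame(sequence = amplicon, reads = r))
  p_any <- 1 - (1 - error_rate)^L
  k_err <- rbinom(1, r, p_any)
  out <- list()
  if (r - k_err > 0) out[[1]] <- data.frame(sequence = amplicon,
                                            reads = r - k_err)
  if (k_err > 0) {
    n_var <- min(k_err, 3L)
    split_r <- as.vector(rmultinom(1, k_err, rep(1, n_var)))
    for (v in seq_len(n_var)) {
      if (split_r[v] == 0) next
      n_mut <- 1L + rbinom(1, L - 1L, error_rate)
      seqq <- strsplit(amplicon, "")[[1]]
      pos <- sample.int(L, min(n_mut, L))
      for (p in pos) seqq[p] <- sample(setdiff(c("A", "C", "G", "T"), seqq[p]), 1)
      out[[length(out) + 1]] <- data.frame(sequence = paste(seqq, collapse = ""),
                                           reads = split_r[v])
    }
  }
  do.call(rbind, out)
}

#' Simulate per-sample, per-marker sequence counts
#'
#' Each sample's diet is drawn from a Dirichlet distribution centred on
#' its species' mean diet (concentration controls among-individual
#' heterogeneity); each marker then draws multinomial reads over families
#' with probabilities proportional to diet x marker bias, at a
#' negative-binomial depth around the marker's mean. When a reference
#' library is supplied, reads are also materialized as sequence variants
#' drawn from the library's amplicons (uniformly over the species of the
#' source family) with optional per-base error.
#'
#' @param truth a [generate_truth()] result.
#' @param n_per_species named integer vector of sample counts per species.
#' @param lib optional `ref_library` from [generate_reference_library()].
#' @param error_rate per-base substitution probability on emitted variants.
#' @param misid_rate probability that the recorded field identification
#'   contradicts the true species.
#' @param seed RNG seed (defaults to the truth's).
#' @return list with `family_counts` (long: sample_id, marker, taxon,
#'   reads), `variants` (long variant table or `NULL`), `metadata`
#'   (sample_id, species, field_id, habitat, measured_length), and
#'   `sample_diets` (true per-sample diet matrix).
#' @export
generate_sample_counts <- function(truth,
                                   n_per_species = c(Dicrostonyx = 22L,
                                                     Lemmus = 54L),
                                   lib = NULL, error_rate = 0,
                                   misid_rate = 0, seed = NULL) {
  set.seed(seed %||% truth$seed)
  fams <- truth$families$family
  groups <- truth$groups
  amp_index <- NULL
  if (!is.null(lib)) {
    pr <- trnl_primers()
    amp_index <- lapply(pr, function(p) in_silico_pcr(lib, p)$index)
    names(amp_index) <- names(pr)
  }
  centers <- c(Dicrostonyx = 128, Lemmus = 146)
  counts <- list(); variants <- list(); meta <- list(); diets <- list()
  for (sp in names(n_per_species)) {
    mean_diet <- truth$species_mean_diets[sp, ]
    for (i in seq_len(n_per_species[[sp]])) {
      sid <- sprintf("%s%03d", substr(sp, 1, 1), i)
      diet <- drop(rdirichlet(1, truth$concentration * mean_diet))
      names(diet) <- fams
      diets[[sid]] <- diet
      for (mk in names(truth$reads_per_sample)) {
        bias <- truth$marker_bias[[mk]][groups[fams]]
        if (all(bias <= 0))
          stop("no family with positive bias for marker ", mk)
        pr_read <- diet * bias
        if (sum(pr_read) <= 0) next   # this diet is invisible to the marker
        depth <- rnbinom(1, size = truth$depth_size,
                         mu = truth$reads_per_sample[[mk]])
        if (mk == "c-h" && depth == 0) depth <- 1L  # split must be defined
        if (depth == 0) next
        cnt <- drop(rmultinom(1, depth, pr_read / sum(pr_read)))
        nz <- which(cnt > 0)
        counts[[length(counts) + 1]] <- data.frame(
          sample_id = sid, marker = mk, taxon = fams[nz],
          reads = cnt[nz], stringsAsFactors = FALSE)
        if (!is.null(amp_index)) {
          idx <- amp_index[[mk]]
          for (j in nz) {
            sp_rows <- which(idx$family == fams[j])
            if (!length(sp_rows)) next
            alloc <- drop(rmultinom(1, cnt[j], rep(1, length(sp_rows))))
            for (k in which(alloc > 0)) {
              vv <- .emit_variants(idx$amplicon[sp_rows[k]], alloc[k],
                                   error_rate)
              vv$sample_id <- sid; vv$marker <- mk
              vv$true_family <- fams[j]
              vv$true_species <- idx$species[sp_rows[k]]
              variants[[length(variants) + 1]] <- vv
            }
          }
        }
      }
      field <- if (misid_rate > 0 && runif(1) < misid_rate)
        setdiff(names(n_per_species), sp)[1] else sp
      meta[[sid]] <- data.frame(
        sample_id = sid, species = sp, field_id = field,
        habitat = sample(c("mesic", "gully", "wetland"), 1,
                         prob = c(0.35, 0.5, 0.15)),
        measured_length = round(rnorm(1, centers[[sp]], 1.5)),
        stringsAsFactors = FALSE)
    }
  }
  fc <- do.call(rbind, counts); rownames(fc) <- NULL
  vt <- if (length(variants)) {
    v <- do.call(rbind, variants); rownames(v) <- NULL
    v[, c("sample_id", "marker", "sequence", "reads", "true_family",
          "true_species")]
  } else NULL
  list(family_counts = fc, variants = vt,
       metadata = do.call(rbind, meta),
       sample_diets = do.call(rbind, diets),
       truth = truth)
}

#' Simulate availability quadrats
#'
#' Each quadrat's within-group composition is drawn from a Dirichlet
#' distribution centred on the availability truth (so quadrat proportions
#' are unbiased for the truth), and its total group biomass from a
#' lognormal around the group's biomass scale; per-family biomass in g/m2
#' is their product. Families absent from the availability truth stay at
#' exactly zero, mimicking taxa never found in the sampling plots.
#'
#' @param truth a [generate_truth()] result.
#' @param n_quadrats total quadrats (split evenly between mesic and gully
#'   habitats).
#' @param dispersion lognormal sdlog of total quadrat biomass; 0 gives
#'   identical totals.
#' @param concentration Dirichlet concentration of quadrat composition;
#'   `Inf` gives every quadrat the truth composition exactly.
#' @param seed RNG seed (defaults to the truth's).
#' @return data frame: plot_id, habitat, one biomass column per family
#'   (vascular and bryophyte families on their own biomass scales).
#' @export
generate_availability_quadrats <- function(truth, n_quadrats = 16L,
                                           dispersion = NULL,
                                           concentration = NULL,
                                           seed = NULL) {
  set.seed(seed %||% truth$seed)
  at <- truth$availability_truth
  dispersion <- dispersion %||% at$total_sdlog
  concentration <- concentration %||% at$concentration
  fams <- truth$families$family
  habitat <- rep(c("mesic", "gully"), length.out = n_quadrats)
  out <- matrix(0, n_quadrats, length(fams), dimnames = list(NULL, fams))
  for (grp in c("vascular", "bryophyte")) {
    pi_g <- at[[grp]][fams[truth$groups[fams] == grp]]
    comp <- if (is.finite(concentration))
      rdirichlet(n_quadrats, concentration * pi_g)
    else matrix(rep(pi_g, each = n_quadrats), n_quadrats)
    tot <- at$total_gm2[[grp]] *
      rlnorm(n_quadrats, -dispersion^2 / 2, dispersion)
    out[, names(pi_g)] <- comp * tot
  }
  data.frame(plot_id = sprintf("%s%02d", ifelse(habitat == "mesic", "M", "R"),
                               seq_len(n_quadrats)),
             habitat = habitat, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}
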