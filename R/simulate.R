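# Synthetic-data generators with known ground truth for every pipeline
# stage. Each generator takes an explicit seed and is fully
# deterministic given seed + parameters; no generator touches global
# options beyond the seeded RNG it sets itself.

.rand_seq <- function(n, alphabet = c("A", "C", "G", "T"), gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  names(p) <- alphabet[c(1, 2, 3, 4)]
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# a base that neither Watson-Crick- nor GU-pairs the given mature base
.nonpairing <- c(A = "C", C = "A", G = "A", U = "C")

#' Generate a planted hairpin precursor
#'
#' Builds a precursor of total length mature + 100 (the mature+2x50
#' flank pattern): 5' pad, the mature, a loop, the reverse complement
#' of the mature with \code{mutations_in_star} star bases replaced by
#' non-pairing bases, and a 3' pad. By construction the mature sits in
#' the 5' arm with exactly the planted number of unpairable star
#' positions.
#'
#' @param mature mature miRNA record (RNA) or list with \code{sequence}.
#' @param loop_len loop length (>= 3, default 8).
#' @param mutations_in_star number of star positions mutated to
#'   non-pairing bases.
#' @param seed integer seed.
#' @param gc GC fraction of the random pads.
#' @return a precursor candidate list as from [extract_precursor()].
#' @export
gen_hairpin_precursor <- function(mature, loop_len = 8, mutations_in_star = 0,
                                  seed = 1, gc = 0.5) {
  stopifnot(loop_len >= 3)
  set.seed(seed)
  mat <- chartr("T", "U", toupper(mature$sequence))
  L <- nchar(mat)
  pad_total <- 100L - loop_len - L
  if (pad_total < 0) stop("mature + loop too long for the mature+100 pattern")
  pad5 <- pad_total %/% 2L
  pad3 <- pad_total - pad5
  star <- strsplit(revcomp(mat, "rna"), "")[[1]]
  if (mutations_in_star > 0) {
    mpos <- sample(2:(L - 1), mutations_in_star)   # mature positions
    mch <- strsplit(mat, "")[[1]]
    for (i in mpos) star[L - i + 1L] <- .nonpairing[[mch[i]]]
  }
  seqn <- paste0(.rand_seq(pad5, c("A", "C", "G", "U"), gc), mat,
                 .rand_seq(loop_len, c("A", "C", "G", "U"), gc),
                 paste(star, collapse = ""),
                 .rand_seq(pad3, c("A", "C", "G", "U"), gc))
  list(id = paste0("planted_", mature$id), sequence = seqn,
       mature_start = pad5 + 1L, mature_end = pad5 + L,
       source_hit = NULL, rejected = FALSE)
}

#' Shuffle a sequence (mononucleotide permutation)
#'
#' Used to build pseudo-hairpin negatives: a shuffled precursor keeps
#' base composition but loses the planted stem.
#'
#' @param s sequence string.
#' @param seed integer seed.
#' @return shuffled string.
#' @export
shuffle_sequence <- function(s, seed = 1) {
  set.seed(seed)
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

#' Generate a synthetic EST corpus with planted miRNA homologs
#'
#' Background units are i.i.d. uniform-base DNA of 300-800 nt. Planted
#' units embed a (possibly mutated) copy of a reference mature miRNA
#' whose 50-nt downstream context carries a loop plus the reverse
#' complement of the planted copy, so the extracted precursor folds
#' into a hairpin. Mutations are placed at mature positions 2..L-7 so
#' the final 7-mer stays exact (a seed word always survives). A stated
#' fraction of units receives a poly-A tail.
#'
#' @param n_background number of units.
#' @param n_planted number of planted homolog cassettes
#'   (<= n_background).
#' @param mismatch_spectrum integer vector of per-planting mismatch
#'   counts, recycled (default 0).
#' @param seed integer seed.
#' @param n_mirnas size of the reference mature set.
#' @param mature_len mature length (default 21).
#' @param polyA_fraction fraction of units given a 15-nt poly-A tail.
#' @return list with \code{units} (records), \code{mirnas} (reference
#'   records, RNA) and \code{truth} (planted homolog table, loop
#'   coordinates).
#' @export
gen_est_corpus <- function(n_background = 200, n_planted = 10,
                           mismatch_spectrum = 0, seed = 1,
                           n_mirnas = 20, mature_len = 21,
                           polyA_fraction = 0.3) {
  stopifnot(n_planted <= n_background)
  set.seed(seed)
  mirnas <- lapply(seq_len(n_mirnas), function(i) {
    list(id = sprintf("mir%03d", i), description = "",
         sequence = .rand_seq(mature_len, c("A", "C", "G", "U")),
         alphabet = "rna")
  })
  units <- lapply(seq_len(n_background), function(i) {
    list(id = sprintf("est%04d", i), description = "",
         sequence = .rand_seq(sample(300:800, 1)), alphabet = "dna")
  })
  planted_idx <- sample(n_background, n_planted)
  spectrum <- rep_len(mismatch_spectrum, n_planted)
  loop_len <- 8L
  truth <- list()
  for (p in seq_len(n_planted)) {
    ui <- planted_idx[p]
    mi <- sample(n_mirnas, 1)
    mat <- chartr("U", "T", mirnas[[mi]]$sequence)
    L <- nchar(mat)
    k <- spectrum[p]
    copy <- strsplit(mat, "")[[1]]
    if (k > 0) {
      pos <- sample(2:(L - 7L), k)
      for (i in pos) {
        copy[i] <- sample(setdiff(c("A", "C", "G", "T"), copy[i]), 1)
      }
    }
    copy <- paste(copy, collapse = "")
    cassette <- paste0(copy, .rand_seq(loop_len), revcomp(copy))
    s <- units[[ui]]$sequence
    n <- nchar(s)
    off <- sample(seq(61L, n - nchar(cassette) - 60L), 1)
    units[[ui]]$sequence <- paste0(substr(s, 1, off - 1L), cassette,
                                   substr(s, off + nchar(cassette), n))
    truth[[p]] <- data.frame(mirna_id = mirnas[[mi]]$id,
                             unit_id = units[[ui]]$id,
                             offset = off, n_mismatch = k,
                             strand = "+", stringsAsFactors = FALSE)
  }
  tailed <- runif(n_background) < polyA_fraction
  for (i in which(tailed)) {
    units[[i]]$sequence <- paste0(units[[i]]$sequence, strrep("A", 15))
  }
  list(units = units, mirnas = mirnas,
       truth = list(planted_homologs = do.call(rbind, truth),
                    polyA_tailed = vapply(units, `[[`, "", "id")[tailed]))
}

#' Generate qPCR Ct and RA-PCR tables with planted truth
#'
#' Emulates a 2-genotype x 4-stage x 3-replicate validation design.
#' Reference genes are constant up to noise; each target gene's Ct is
#' the calibrator Ct minus log2 of its planted fold change plus noise.
#' RA-PCR mid-region Ct is inflated by -log2(1 - reduction/100) for
#' cleaved transcripts.
#'
#' @param genes character vector of target gene ids.
#' @param genotypes,stages design labels.
#' @param fold_spec data.frame (\code{sample}, \code{gene_id},
#'   \code{fold}) or NULL to draw log2 folds uniformly in [-3, 3]
#'   (calibrator sample forced to fold 1).
#' @param noise_sd_ct replicate Ct noise SD.
#' @param cleaved_fraction fraction of transcripts planted as cleaved.
#' @param n_rep replicates per cell.
#' @param seed integer seed.
#' @return list with \code{ct} (sample, genotype, stage, gene_id, role,
#'   replicate, ct), \code{rapcr} (transcript_id, genotype, stage,
#'   region, replicate, ct), \code{calibrator} and \code{truth}
#'   (planted folds, cleaved flags, planted reductions).
#' @export
gen_expression_tables <- function(genes = sprintf("gene%03d", 1:5),
                                  genotypes = c("NRC7", "NRC37"),
                                  stages = c("35DAF", "45DAF", "55DAF", "65DAF"),
                                  fold_spec = NULL, noise_sd_ct = 0.1,
                                  cleaved_fraction = 0.7, n_rep = 3, seed = 1) {
  stopifnot(noise_sd_ct >= 0)
  set.seed(seed)
  design <- expand.grid(genotype = genotypes, stage = stages,
                        stringsAsFactors = FALSE)
  design$sample <- paste(design$genotype, design$stage, sep = ":")
  calibrator <- design$sample[1]
  refs <- c("ref5S", "refMIR172", "refMIR1520")
  if (is.null(fold_spec)) {
    fold_spec <- expand.grid(sample = design$sample, gene_id = genes,
                             stringsAsFactors = FALSE)
    fold_spec$fold <- 2^runif(nrow(fold_spec), -3, 3)
    fold_spec$fold[fold_spec$sample == calibrator] <- 1
  }
  rows <- list()
  for (si in seq_len(nrow(design))) {
    s <- design$sample[si]
    for (g in refs) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, genotype = design$genotype[si], stage = design$stage[si],
        gene_id = g, role = "reference", replicate = seq_len(n_rep),
        ct = 20 + rnorm(n_rep, 0, noise_sd_ct), stringsAsFactors = FALSE)
    }
    for (g in genes) {
      fold <- fold_spec$fold[fold_spec$sample == s & fold_spec$gene_id == g]
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, genotype = design$genotype[si], stage = design$stage[si],
        gene_id = g, role = "target_of_interest", replicate = seq_len(n_rep),
        ct = 25 - log2(fold) + rnorm(n_rep, 0, noise_sd_ct),
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  # RA-PCR: per transcript x sample, three regions
  cleaved <- setNames(runif(length(genes)) < cleaved_fraction, genes)
  red_truth <- list()
  ra <- list()
  for (g in genes) {
    for (si in seq_len(nrow(design))) {
      red <- if (cleaved[[g]]) runif(1, 55, 95) else 0
      base <- 24
      shift_mid <- -log2(1 - red / 100)
      ra[[length(ra) + 1]] <- data.frame(
        transcript_id = g, genotype = design$genotype[si],
        stage = design$stage[si],
        region = rep(c("5p", "mid", "3p"), each = n_rep),
        replicate = rep(seq_len(n_rep), 3),
        ct = c(base + runif(1, -1, 1) + rnorm(n_rep, 0, noise_sd_ct),
               base + shift_mid + rnorm(n_rep, 0, noise_sd_ct),
               base + rnorm(n_rep, 0, noise_sd_ct)),
        stringsAsFactors = FALSE)
      red_truth[[length(red_truth) + 1]] <- data.frame(
        transcript_id = g, sample = design$sample[si], reduction = red,
        stringsAsFactors = FALSE)
    }
  }
  list(ct = ct, rapcr = do.call(rbind, ra), calibrator = calibrator,
       truth = list(planted_fold_changes = fold_spec,
                    planted_cleaved = cleaved,
                    planted_reductions = do.call(rbind, red_truth)))
}

#' Summarise RA-PCR Ct rows into per-sample region profiles
#'
#' Converts replicate Ct values into relative quantities (2^-dCt
#' against the 3' region) and the reduction statistic, one profile per
#' transcript x genotype x stage.
#'
#' @param rapcr RA-PCR table as from [gen_expression_tables()] (or
#'   [read_table()] with the same columns).
#' @return list of profiles from [rapcr_reduction()].
#' @export
rapcr_profiles <- function(rapcr) {
  keys <- unique(rapcr[c("transcript_id", "genotype", "stage")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- merge(rapcr, keys[i, ])
    mct <- tapply(sub$ct, sub$region, mean)
    q <- 2^(-(mct - mct[["3p"]]))
    out[[i]] <- rapcr_reduction(q[["5p"]], q[["mid"]], q[["3p"]],
                                transcript_id = keys$transcript_id[i],
                                stage = keys$stage[i],
                                genotype = keys$genotype[i])
  }
  out
}

#' Generate a gene-to-term annotation map with a planted enriched term
#'
#' Background genes draw 1-3 terms uniformly; the planted term is
#' carried by background genes at \code{base_rate} and by study genes
#' at \code{min(1, odds * base_rate)}.
#'
#' @param population number of genes.
#' @param terms number of distinct terms.
#' @param study_size study set size.
#' @param odds enrichment odds of the planted term in the study set
#'   (> 1 plants signal; 1 gives a null map).
#' @param base_rate background carriage rate of the planted term.
#' @param seed integer seed.
#' @return list with \code{annotation} (gene, term), \code{study},
#'   \code{truth} (planted term id).
#' @export
gen_annotation <- function(population = 1000, terms = 50, study_size = 20,
                           odds = 10, base_rate = 0.05, seed = 1) {
  stopifnot(odds >= 1)
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(population))
  term_ids <- sprintf("T%03d", seq_len(terms))
  planted <- term_ids[1]
  rows <- lapply(genes, function(g) {
    data.frame(gene = g,
               term = sample(term_ids[-1], sample(1:3, 1)),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  study <- sample(genes, study_size)
  p_carry <- ifelse(genes %in% study, min(1, odds * base_rate), base_rate)
  carriers <- genes[runif(population) < p_carry]
  if (length(carriers)) {
    ann <- rbind(ann, data.frame(gene = carriers, term = planted,
                                 stringsAsFactors = FALSE))
  }
  list(annotation = ann, study = study,
       truth = list(planted_term = planted, odds = odds))
}

#' Generate HPLC standards and sample areas with planted truth
#'
#' Standard areas follow the planted line (slope, intercept) at
#' 5/10/20/40/50 ppm plus noise; sample areas are obtained by
#' inverting the quantification arithmetic from the planted ug/g
#' concentrations.
#'
#' @param curve_truth named list per analyte of c(slope, intercept).
#' @param concentrations_truth data.frame (genotype, stage, analyte,
#'   ug_g); NULL for a built-in two-genotype, four-stage profile whose
#'   65DAF totals are 606.36 and 1382.51 ug/g.
#' @param noise_sd_area area noise SD.
#' @param n_rep sample replicates.
#' @param seed integer seed.
#' @param sample_mass_g,extract_volume_ml,dilution extraction
#'   constants (125 mg flour, 6 ml extract by default).
#' @return list with \code{standards}, \code{samples}, \code{truth}.
#' @export
gen_hplc <- function(curve_truth = list(daidzein = c(slope = 10, intercept = 0),
                                        glycitein = c(slope = 12, intercept = 5),
                                        genistein = c(slope = 9, intercept = 2)),
                     concentrations_truth = NULL, noise_sd_area = 0,
                     n_rep = 3, seed = 1, sample_mass_g = 0.125,
                     extract_volume_ml = 6, dilution = 1) {
  set.seed(seed)
  if (is.null(concentrations_truth)) {
    concentrations_truth <- .default_isoflavone_truth()
  }
  ppm_levels <- c(5, 10, 20, 40, 50)
  standards <- do.call(rbind, lapply(names(curve_truth), function(a) {
    data.frame(analyte = a, ppm = ppm_levels,
               area = curve_truth[[a]][["slope"]] * ppm_levels +
                 curve_truth[[a]][["intercept"]] +
                 rnorm(length(ppm_levels), 0, noise_sd_area),
               stringsAsFactors = FALSE)
  }))
  samples <- do.call(rbind, lapply(seq_len(nrow(concentrations_truth)), function(i) {
    r <- concentrations_truth[i, ]
    ppm <- r$ug_g * sample_mass_g / (extract_volume_ml * dilution)
    ct <- curve_truth[[r$analyte]]
    data.frame(genotype = r$genotype, stage = r$stage, analyte = r$analyte,
               replicate = seq_len(n_rep),
               area = ct[["slope"]] * ppm + ct[["intercept"]] +
                 rnorm(n_rep, 0, noise_sd_area),
               stringsAsFactors = FALSE)
  }))
  list(standards = standards, samples = samples,
       truth = list(curve = curve_truth,
                    concentrations = concentrations_truth))
}

# rising totals across 35-65 DAF; 65DAF totals match the two genotypes'
# reported maxima, with a synthetic split across the three aglycones
.default_isoflavone_truth <- function() {
  grid <- expand.grid(genotype = c("NRC7", "NRC37"),
                      stage = c("35DAF", "45DAF", "55DAF", "65DAF"),
                      stringsAsFactors = FALSE)
  totals <- c(NRC7 = 606.36, NRC37 = 1382.51)
  frac <- c("35DAF" = 0.35, "45DAF" = 0.55, "55DAF" = 0.8, "65DAF" = 1.0)
  split3 <- c(daidzein = 0.45, glycitein = 0.15, genistein = 0.40)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tot <- totals[[grid$genotype[i]]] * frac[[grid$stage[i]]]
    data.frame(genotype = grid$genotype[i], stage = grid$stage[i],
               analyte = names(split3), ug_g = unname(tot * split3),
               stringsAsFactors = FALSE)
  }))
}

#' Serialize a ground-truth object to JSON
#'
#' @param truth list as returned in a generator's \code{truth} slot.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
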