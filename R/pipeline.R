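#' Build a labelled training set for the hairpin classifier
#'
#' Positives are planted hairpin precursors around random matures;
#' negatives are mononucleotide shuffles of the same precursors (same
#' composition, no stem), both folded with the chosen engine and
#' encoded as triplet features.
#'
#' @param n_pos,n_neg class sizes.
#' @param mature_len mature length for the planted positives.
#' @param seed integer seed.
#' @param engine folding engine, see [fold_hairpin()].
#' @return list with \code{pos} and \code{neg} lists of feature
#'   vectors.
#' @export
make_training_set <- function(n_pos = 60, n_neg = 60, mature_len = 21,
                              seed = 1, engine = "builtin") {
  set.seed(seed)
  seeds <- sample.int(1e6, n_pos + n_neg)
  pos <- vector("list", n_pos)
  for (i in seq_len(n_pos)) {
    set.seed(seeds[i])
    mat <- list(id = paste0("tm", i),
                sequence = .rand_seq(mature_len, c("A", "C", "G", "U")))
    p <- gen_hairpin_precursor(mat, seed = seeds[i])
    f <- fold_hairpin(p, engine = engine)
    pos[[i]] <- triplet_features(p, f)
  }
  neg <- vector("list", n_neg)
  for (i in seq_len(n_neg)) {
    set.seed(seeds[n_pos + i])
    mat <- list(id = paste0("tn", i),
                sequence = .rand_seq(mature_len, c("A", "C", "G", "U")))
    p <- gen_hairpin_precursor(mat, seed = seeds[n_pos + i])
    p$sequence <- shuffle_sequence(p$sequence, seed = seeds[n_pos + i])
    f <- fold_hairpin(p, engine = engine)
    neg[[i]] <- triplet_features(p, f)
  }
  list(pos = pos, neg = neg)
}

#' Run the full miRNA discovery chain on assembled units
#'
#' scan -> extract -> fold -> classify -> coding/contaminant exclusion
#' -> curation, returning one row per candidate locus with the stage
#' outcomes and a final \code{accepted} flag.
#'
#' @param units assembled unit list.
#' @param mirnas reference mature records (RNA).
#' @param model trained hairpin classifier from [train_classifier()].
#' @param contaminants optional contaminant records for
#'   [exclude_coding()].
#' @param word,max_mismatch,min_len homology scan parameters.
#' @param flank,min_flank precursor extraction parameters.
#' @param engine folding engine.
#' @param ... curation thresholds passed to [curate()].
#' @return data.frame with hit coordinates, classifier label and
#'   margin, exclusion reason, curation flags and \code{accepted}.
#' @export
run_discovery <- function(units, mirnas, model, contaminants = NULL,
                          word = 7, max_mismatch = 3, min_len = 18,
                          flank = 50, min_flank = 20, engine = "builtin",
                          ...) {
  idx <- build_word_index(units, word = word)
  hits <- scan_homologs(mirnas, idx, units,
                        max_mismatch = max_mismatch, min_len = min_len)
  out <- list()
  for (r in seq_len(nrow(hits))) {
    hit <- hits[r, ]
    p <- extract_precursor(hit, units, flank = flank, min_flank = min_flank)
    if (isTRUE(p$rejected)) next
    f <- fold_hairpin(p, engine = engine)
    feat <- try(triplet_features(p, f), silent = TRUE)
    if (inherits(feat, "try-error")) next
    cls <- classify_hairpin(feat, model)
    ex <- exclude_coding(p, contaminants)
    st <- hairpin_stats(p, f)
    cv <- curate(p, f, st, ...)
    out[[length(out) + 1]] <- cbind(
      hit,
      data.frame(precursor_length = st$precursor_length,
                 gc_percent = st$gc_percent, mfe = st$mfe,
                 amfe = st$amfe, mfei = st$mfei,
                 label = cls$label, margin = cls$margin,
                 excluded = !ex$keep, exclusion_reason = ex$reason,
                 star_mismatches = cv$star_mismatches,
                 curated = cv$passed,
                 accepted = cls$label == "real" && ex$keep && cv$passed,
                 stringsAsFactors = FALSE))
  }
  if (!length(out)) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
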