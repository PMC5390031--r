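#' Triplet structure-sequence features of a folded precursor
#'
#' The classic 32-dimensional encoding for pre-miRNA classification:
#' for every interior position i the paired/unpaired status of
#' (i-1, i, i+1) — brackets of either orientation count as paired —
#' combined with the base at i gives one of 4 x 8 = 32 categories;
#' counts are normalised to frequencies.
#'
#' @param p precursor candidate (RNA sequence).
#' @param f fold result with a \code{structure} dot-bracket string.
#' @return named numeric vector of 32 frequencies summing to 1, names
#'   like \code{"A.(("} = base A with statuses (unpaired, paired,
#'   paired) at (i-1, i, i+1).
#' @export
triplet_features <- function(p, f) {
  s <- chartr("T", "U", toupper(p$sequence))
  st <- f$structure
  n <- nchar(s)
  if (n < 3 || nchar(st) != n) stop("feature error: need structure of length >= 3")
  bases <- strsplit(s, "")[[1]]
  paired <- strsplit(st, "")[[1]] != "."
  sym <- ifelse(paired, "(", ".")
  cats <- as.vector(outer(c("A", "C", "G", "U"),
                          apply(expand.grid(c(".", "("), c(".", "("),
                                            c(".", "(")), 1, paste, collapse = ""),
                          paste0))
  v <- setNames(numeric(32), sort(cats))
  for (i in 2:(n - 1)) {
    key <- paste0(bases[i], sym[i - 1], sym[i], sym[i + 1])
    if (key %in% names(v)) v[key] <- v[key] + 1
  }
  tot <- sum(v)
  if (tot == 0) stop("feature error: no scorable interior positions")
  v / tot
}

#' Train a linear maximum-margin hairpin classifier
#'
#' Fits a linear-kernel support vector machine separating genuine
#' pre-miRNA hairpins from pseudo-hairpins on triplet feature vectors.
#' Stands in for a published pre-trained model whose weights are not
#' redistributable; retraining on generator output preserves the
#' stage's mechanics.
#'
#' @param pos list of triplet feature vectors for real hairpins.
#' @param neg list of feature vectors for pseudo-hairpins.
#' @param seed integer seed (stored with the model for provenance).
#' @param cost SVM cost parameter.
#' @return a classifier object (class \code{hairpin_classifier}) with
#'   the fitted svm, the seed and an md5 digest of the fitted
#'   coefficients.
#' @export
train_classifier <- function(pos, neg, seed = 1, cost = 1) {
  if (length(pos) < 20 || length(neg) < 20) {
    stop("need >= 20 examples per class")
  }
  ratio <- max(length(pos), length(neg)) / min(length(pos), length(neg))
  if (ratio > 10) warning("class imbalance exceeds 10:1")
  x <- rbind(do.call(rbind, pos), do.call(rbind, neg))
  y <- factor(c(rep("real", length(pos)), rep("pseudo", length(neg))),
              levels = c("real", "pseudo"))
  set.seed(seed)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    probability = FALSE)
  tf <- tempfile()
  saveRDS(list(coefs = unname(fit$coefs), rho = fit$rho,
               sv = unname(fit$SV)), tf, version = 2)
  digest <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(list(fit = fit, seed = seed, digest = digest,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "hairpin_classifier")
}

#' Classify a folded precursor as real or pseudo hairpin
#'
#' @param feat triplet feature vector from [triplet_features()].
#' @param model trained classifier from [train_classifier()].
#' @return list with \code{label} ("real"/"pseudo") and \code{margin}
#'   (signed decision value, positive toward "real").
#' @export
classify_hairpin <- function(feat, model) {
  if (!inherits(model, "hairpin_classifier")) {
    stop("state error: model is not a trained hairpin_classifier")
  }
  x <- matrix(feat, nrow = 1)
  colnames(x) <- names(feat)
  pr <- predict(model$fit, x, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values")[1, 1])
  # e1071 orients decision values toward the first factor level ("real")
  list(label = as.character(pr[1]), margin = dv)
}

#' Exclude likely protein-coding or structural-RNA candidates
#'
#' Simplified stand-in for coding/ncRNA screens: a candidate is dropped
#' if any reading frame (all six) contains an open reading frame of at
#' least \code{min_orf} codons (ATG..stop), or if it shares an exact
#' 16-mer with a user-supplied contaminant set (rRNA/tRNA/snRNA).
#'
#' @param p precursor candidate.
#' @param contaminants list of contaminant records, or NULL.
#' @param min_orf minimum ORF length in codons (including the start).
#' @return list with \code{keep} (logical) and \code{reason}
#'   ("orf", "contaminant" or "").
#' @export
exclude_coding <- function(p, contaminants = NULL, min_orf = 60) {
  dna <- chartr("U", "T", toupper(p$sequence))
  frames <- c(dna, substring(dna, 2), substring(dna, 3))
  rc <- revcomp(dna)
  frames <- c(frames, rc, substring(rc, 2), substring(rc, 3))
  for (fr in frames) {
    if (.longest_orf_codons(fr) >= min_orf) {
      return(list(keep = FALSE, reason = "orf"))
    }
  }
  if (!is.null(contaminants) && length(contaminants)) {
    if (screen_contaminants(list(p), contaminants, k = 16)[1]) {
      return(list(keep = FALSE, reason = "contaminant"))
    }
  }
  list(keep = TRUE, reason = "")
}

# longest ATG..stop ORF (in codons, counting ATG, excluding stop) in frame 1
.longest_orf_codons <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0) return(0L)
  codons <- substring(s, 3 * (0:(n - 1)) + 1, 3 * (0:(n - 1)) + 3)
  best <- 0L
  open <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(open) && codons[i] == "ATG") open <- i
    if (!is.na(open) && codons[i] %in% c("TAA", "TAG", "TGA")) {
      best <- max(best, i - open)
      open <- NA_integer_
    }
  }
  best
}

#' Rule-based curation of a candidate pre-miRNA
#'
#' Programmatic form of the manual curation rules commonly applied to
#' plant pre-miRNA candidates: the mature must sit wholly within one
#' arm of the hairpin (no base inside the terminal loop, no
#' self-pairing across the loop), have at most
#' \code{max_star_mismatch} unpaired bases against its star region, no
#' multibranch junction may overlap the mature, AU% must lie within
#' \code{[au_lo, au_hi]} and |MFEI| must be at least
#' \code{min_abs_mfei}.
#'
#' @param p precursor candidate with \code{mature_start}/\code{mature_end}.
#' @param f fold result.
#' @param s hairpin statistics from [hairpin_stats()].
#' @param max_star_mismatch maximum mature/star mismatches (default 6).
#' @param au_lo,au_hi AU% window (default 30-70).
#' @param min_abs_mfei minimum |MFEI| (default 0.5; the accepted
#'   candidates in this lineage reach only ~0.61, below the 0.85 often
#'   quoted elsewhere).
#' @return a curation verdict list: \code{in_one_arm},
#'   \code{star_mismatches}, \code{no_branch_in_mature},
#'   \code{au_in_range}, \code{mfei_ok}, \code{passed}.
#' @export
curate <- function(p, f, s, max_star_mismatch = 6, au_lo = 30, au_hi = 70,
                   min_abs_mfei = 0.5) {
  pt <- pair_table(f$structure)
  ch <- strsplit(f$structure, "")[[1]]
  m <- p$mature_start:p$mature_end
  # terminal (hairpin) loops: maximal unpaired runs whose flanks pair
  # with each other
  loop_pos <- integer(0)
  n <- length(ch)
  runs <- rle(is.na(pt))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    a <- starts[k]; b <- ends[k]
    if (a > 1 && b < n && !is.na(pt[a - 1]) && pt[a - 1] == b + 1L) {
      loop_pos <- c(loop_pos, a:b)
    }
  }
  self_pair <- any(!is.na(pt[m]) & pt[m] %in% m)
  in_one_arm <- !any(m %in% loop_pos) && !self_pair
  star_mismatches <- sum(is.na(pt[m]))
  # multibranch junction inside the mature: a helix closes (')') and a
  # new one opens ('(') downstream of it within the mature span
  no_branch <- !any(outer(which(ch[m] == ")"), which(ch[m] == "("), `<`))
  au_in_range <- s$au_percent >= au_lo && s$au_percent <= au_hi
  mfei_ok <- abs(s$mfei) >= min_abs_mfei
  passed <- in_one_arm && star_mismatches <= max_star_mismatch &&
    no_branch && au_in_range && mfei_ok
  list(in_one_arm = in_one_arm,
       star_mismatches = star_mismatches,
       no_branch_in_mature = no_branch,
       au_in_range = au_in_range,
       mfei_ok = mfei_ok,
       passed = passed)
}
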