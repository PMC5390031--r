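#' Per-sample normalization factor from reference genes
#'
#' Geometric-mean multi-reference scheme: for each reference gene the
#' relative quantity of a sample is 2^(-dCt) with dCt taken against
#' that gene's across-sample mean Ct; the sample's factor is the
#' geometric mean over reference genes. Replicates are summarised by
#' mean Ct first.
#'
#' @param ct data.frame with columns \code{sample}, \code{gene_id},
#'   \code{ct} (one row per replicate) for reference genes only.
#' @return named numeric vector of factors, one per sample.
#' @export
normalization_factor <- function(ct) {
  stopifnot(all(c("sample", "gene_id", "ct") %in% names(ct)))
  mean_ct <- aggregate(ct ~ sample + gene_id, data = ct, FUN = mean)
  samples <- unique(mean_ct$sample)
  genes <- unique(mean_ct$gene_id)
  for (g in genes) {
    have <- mean_ct$sample[mean_ct$gene_id == g]
    miss <- setdiff(samples, have)
    if (length(miss)) {
      stop("reference gene '", g, "' missing in sample(s): ",
           paste(miss, collapse = ", "))
    }
  }
  rq <- sapply(samples, function(s) {
    vals <- vapply(genes, function(g) {
      x <- mean_ct$ct[mean_ct$sample == s & mean_ct$gene_id == g]
      xbar <- mean(mean_ct$ct[mean_ct$gene_id == g])
      2^(-(x - xbar))
    }, numeric(1))
    exp(mean(log(vals)))
  })
  setNames(rq, samples)
}

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, dCt = mean target Ct minus the composite reference
#' Ct (the negative log2 of the sample's normalization factor); ddCt is
#' taken against the calibrator sample and the fold change is 2^-ddCt.
#' The replicate SD of dCt is propagated to a log2-scale standard
#' error.
#'
#' @param target data.frame with columns \code{sample}, \code{ct}
#'   (replicate rows) for the gene of interest.
#' @param refs data.frame as in [normalization_factor()] for the
#'   reference panel (same samples).
#' @param calibrator sample label used as the ddCt baseline.
#' @return data.frame with \code{sample}, \code{fold},
#'   \code{log2_fold}, \code{se_log2} (NA with a single replicate).
#' @export
fold_change_ddct <- function(target, refs, calibrator) {
  stopifnot(all(c("sample", "ct") %in% names(target)))
  nf <- normalization_factor(refs)
  samples <- unique(target$sample)
  if (!calibrator %in% samples) stop("calibrator sample not found: ", calibrator)
  ref_ct <- -log2(nf)  # composite reference Ct (centred)
  dct <- vapply(samples, function(s) {
    mean(target$ct[target$sample == s]) - ref_ct[[s]]
  }, numeric(1))
  sdd <- vapply(samples, function(s) {
    reps <- target$ct[target$sample == s] - ref_ct[[s]]
    if (length(reps) > 1) sd(reps) / sqrt(length(reps)) else NA_real_
  }, numeric(1))
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = samples, fold = 2^(-ddct), log2_fold = -ddct,
             se_log2 = unname(sdd), stringsAsFactors = FALSE)
}

#' RA-PCR profile and mid-region reduction for one transcript/sample
#'
#' Regional amplification PCR compares the relative abundance of three
#' amplicons on one transcript: 5' of, spanning, and 3' of a putative
#' miRNA cleavage site. Cleavage depletes the 5' and site-spanning
#' regions relative to the 3' region, so the reduction statistic is
#' (1 - qmid/q3) * 100, taking the 3' region as the reference
#' denominator. Invariant to common rescaling of the three quantities.
#'
#' @param q5,qmid,q3 relative quantities (> 0) of the 5', middle
#'   (target-site) and 3' regions.
#' @param transcript_id,stage,genotype optional labels carried through.
#' @return profile list with the quantities and \code{reduction_pct}
#'   (negative when qmid exceeds q3).
#' @examples
#' rapcr_reduction(1, 0.2, 1)$reduction_pct
#' @export
rapcr_reduction <- function(q5, qmid, q3, transcript_id = NA, stage = NA,
                            genotype = NA) {
  if (any(c(q5, qmid, q3) <= 0)) stop("domain error: quantities must be > 0")
  list(transcript_id = transcript_id, stage = stage, genotype = genotype,
       q5 = q5, qmid = qmid, q3 = q3,
       reduction_pct = (1 - qmid / q3) * 100)
}

#' Call miRNA-directed cleavage from RA-PCR profiles
#'
#' A stage is called cleaved when its mid-region reduction exceeds
#' \code{min_reduction}; the transcript overall is called cleaved only
#' when every stage is.
#'
#' @param profiles list of profiles from [rapcr_reduction()] for one
#'   transcript (one per stage).
#' @param min_reduction percent reduction threshold (default 0).
#' @return list with \code{per_stage} (named logical) and
#'   \code{overall} ("cleaved"/"not_cleaved").
#' @export
call_cleavage <- function(profiles, min_reduction = 0) {
  if (!length(profiles)) stop("need at least one stage")
  red <- vapply(profiles, `[[`, numeric(1), "reduction_pct")
  stages <- vapply(profiles, function(p) as.character(p$stage), "")
  per <- red > min_reduction
  names(per) <- stages
  list(per_stage = per,
       overall = if (all(per)) "cleaved" else "not_cleaved")
}

#' Correlation between miRNA and target fold changes across stages
#'
#' @param mirna_folds,target_folds numeric vectors over the same >= 3
#'   stages.
#' @param method "pearson" or "spearman".
#' @param sign_threshold magnitude below which no sign call is made
#'   (default 0.5).
#' @return list with \code{coefficient} (NA for constant series) and
#'   \code{sign} ("negative", "positive" or "none").
#' @export
mirna_target_correlation <- function(mirna_folds, target_folds,
                                     method = c("spearman", "pearson"),
                                     sign_threshold = 0.5) {
  method <- match.arg(method)
  if (length(mirna_folds) < 3 || length(mirna_folds) != length(target_folds)) {
    stop("need >= 3 paired stages")
  }
  if (sd(mirna_folds) == 0 || sd(target_folds) == 0) {
    return(list(coefficient = NA_real_, sign = "none"))
  }
  r <- cor(mirna_folds, target_folds, method = method)
  s <- if (r < -sign_threshold) "negative"
       else if (r > sign_threshold) "positive" else "none"
  list(coefficient = r, sign = s)
}

#' @importFrom stats aggregate
NULL
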