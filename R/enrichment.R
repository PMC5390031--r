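#' Upper-tail hypergeometric p-value, computed in log space
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n genes from a
#' population of N of which K carry the term, the probability of
#' observing k or more carriers. Terms are summed in log space
#' (log-sum-exp over \code{lchoose} terms) for numerical stability.
#'
#' @param k observed study hits.
#' @param n study size.
#' @param K population hits.
#' @param N population size.
#' @return the upper-tail probability.
#' @examples
#' hypergeom_tail(2, 5, 5, 20)
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || n > N || K > N || k > n) {
    stop("domain error: need 0 <= k <= n <= N and K <= N")
  }
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  x <- k:hi
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment within one family: sort p-values ascending,
#' adj_(i) = min_{j>=i} ( p_(j) * m / j ), capped at 1, returned in the
#' input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted values (FDR) in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("domain error: p-values must be in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of a study gene set
#'
#' Hypergeometric test per annotation term with at least one study hit,
#' followed by Benjamini-Hochberg FDR across all tested terms. The
#' population is the set of annotated genes.
#'
#' @param study character vector of study gene ids (subset of the
#'   annotated population).
#' @param annotation data.frame with columns \code{gene} and
#'   \code{term} (repeated rows for multi-term genes), e.g. from
#'   [read_table()].
#' @param alpha FDR threshold for flagging (default 0.05).
#' @return data.frame with \code{term_id}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p_value}, \code{fdr}, \code{flagged},
#'   sorted by p-value.
#' @export
enrich <- function(study, annotation, alpha = 0.05) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  population <- unique(annotation$gene)
  study <- unique(study)
  if (!length(study)) {
    warning("empty study set")
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), flagged = logical(0)))
  }
  if (!all(study %in% population)) {
    stop("study genes missing from the annotated population: ",
         paste(head(setdiff(study, population), 3), collapse = ", "))
  }
  N <- length(population)
  n <- length(study)
  by_term <- split(unique(annotation[c("gene", "term")])$gene,
                   unique(annotation[c("gene", "term")])$term)
  k <- vapply(by_term, function(g) sum(study %in% g), integer(1))
  K <- lengths(by_term)
  tested <- k >= 1L
  res <- data.frame(term_id = names(by_term)[tested],
                    k = unname(k[tested]), n = n,
                    K = unname(K[tested]), N = N,
                    stringsAsFactors = FALSE)
  res$p_value <- mapply(hypergeom_tail, res$k, n, res$K, N)
  res$fdr <- bh_adjust(res$p_value)
  res$flagged <- res$fdr <= alpha
  res[order(res$p_value), , drop = FALSE]
}
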