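.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

.col_penalty <- function(qb, tb) {
  # qb: miRNA base, tb: target base (both RNA, uppercase)
  if (!is.na(.RNA_COMP[qb]) && .RNA_COMP[[qb]] == tb) return(c(0, 0))   # WC
  if ((qb == "G" && tb == "U") || (qb == "U" && tb == "G")) return(c(0.5, 1)) # wobble
  c(1, 2)  # mismatch
}

#' Score one miRNA against one target window (expectation score)
#'
#' Complementarity expectation in the style of plant target-prediction
#' servers: the miRNA is aligned antiparallel against the window;
#' each mismatch costs 1, each G:U wobble 0.5, each gap 2, and all
#' penalties are doubled at miRNA positions 2..\code{seed_end} counted
#' from the miRNA 5' end. The minimal-penalty global alignment with at
#' most \code{max_gaps} gaps is found by dynamic programming.
#' Expectation 0 means the window is the exact reverse complement.
#'
#' @param mirna mature miRNA record (RNA) or a list with
#'   \code{sequence}.
#' @param window target subsequence (5'->3', RNA or DNA), length within
#'   \code{max_gaps} of the miRNA length.
#' @param seed_end last doubled position (default 13).
#' @param max_gaps maximum gaps (default 1).
#' @return list with \code{expectation}, \code{alignment} (3-line
#'   character vector: miRNA 3'->5', match line, target 5'->3') and
#'   \code{columns} (data.frame of per-column miRNA position and type).
#' @export
score_site <- function(mirna, window, seed_end = 13, max_gaps = 1) {
  q <- strsplit(chartr("T", "U", toupper(mirna$sequence)), "")[[1]]
  w <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  m <- length(q)
  n <- length(w)
  if (abs(n - m) > max_gaps) {
    stop("window length must be within ", max_gaps, " of the miRNA length")
  }
  wr <- rev(w)  # align target 3'->5' column-wise against miRNA 5'->3'
  mult <- function(pos) if (pos >= 2 && pos <= seed_end) 2 else 1
  G <- max_gaps
  INF <- Inf
  # D[i+1, j+1, g+1]: min penalty consuming i miRNA and j target bases, g gaps
  D <- array(INF, dim = c(m + 1, n + 1, G + 1))
  D[1, 1, 1] <- 0
  for (i in 0:m) for (j in 0:n) for (g in 0:G) {
    d <- D[i + 1, j + 1, g + 1]
    if (!is.finite(d)) next
    if (i < m && j < n) {
      pen <- .col_penalty(q[i + 1], wr[j + 1])[1] * mult(i + 1)
      D[i + 2, j + 2, g + 1] <- min(D[i + 2, j + 2, g + 1], d + pen)
    }
    if (g < G) {
      if (i < m) {  # gap in target: miRNA base i+1 unpaired
        D[i + 2, j + 1, g + 2] <- min(D[i + 2, j + 1, g + 2],
                                      d + 2 * mult(i + 1))
      }
      if (j < n) {  # gap in miRNA between positions i and i+1
        D[i + 1, j + 2, g + 2] <- min(D[i + 1, j + 2, g + 2],
                                      d + 2 * mult(min(i + 1, m)))
      }
    }
  }
  best_g <- which.min(D[m + 1, n + 1, ])
  expectation <- D[m + 1, n + 1, best_g]
  # traceback
  i <- m; j <- n; g <- best_g - 1
  cols <- list()
  while (i > 0 || j > 0) {
    d <- D[i + 1, j + 1, g + 1]
    stepped <- FALSE
    if (i > 0 && j > 0) {
      pc <- .col_penalty(q[i], wr[j])
      if (isTRUE(all.equal(D[i, j, g + 1] + pc[1] * mult(i), d))) {
        type <- c("match", "wobble", "mismatch")[pc[2] + 1]
        cols[[length(cols) + 1]] <- data.frame(
          mirna_pos = i, type = type, q = q[i], t = wr[j])
        i <- i - 1; j <- j - 1
        stepped <- TRUE
      }
    }
    if (!stepped && g > 0 && i > 0 &&
        isTRUE(all.equal(D[i, j + 1, g] + 2 * mult(i), d))) {
      cols[[length(cols) + 1]] <- data.frame(
        mirna_pos = i, type = "gap", q = q[i], t = "-")
      i <- i - 1; g <- g - 1
      stepped <- TRUE
    }
    if (!stepped && g > 0 && j > 0 &&
        isTRUE(all.equal(D[i + 1, j, g] + 2 * mult(min(i + 1, m)), d))) {
      cols[[length(cols) + 1]] <- data.frame(
        mirna_pos = min(i + 1, m), type = "gap", q = "-", t = wr[j])
      j <- j - 1; g <- g - 1
      stepped <- TRUE
    }
    if (!stepped) stop("traceback failure")  # should not happen
  }
  cols <- do.call(rbind, rev(cols))
  mk <- c(match = "|", wobble = "o", mismatch = " ", gap = " ")
  aln <- c(paste(rev(cols$q), collapse = ""),                 # miRNA 3'->5'
           paste(rev(mk[cols$type]), collapse = ""),
           paste(rev(cols$t), collapse = ""))                 # target 5'->3'
  list(expectation = expectation, alignment = aln, columns = cols)
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every window (miRNA length +/- \code{max_gaps}) of every
#' transcript against every miRNA and reports sites with expectation
#' <= \code{max_expectation}, keeping the best site per overlapping
#' locus, with an inhibition-mode call.
#'
#' @param mirnas list of mature miRNA records.
#' @param transcripts list of transcript records (RNA or DNA).
#' @param max_expectation report cutoff (default 3.0).
#' @param seed_end,max_gaps passed to [score_site()].
#' @return data.frame of target sites: \code{mirna_id},
#'   \code{transcript_id}, \code{t_start}, \code{t_end} (1-based
#'   inclusive, forward strand), \code{expectation}, \code{mode}.
#' @export
scan_targets <- function(mirnas, transcripts, max_expectation = 3.0,
                         seed_end = 13, max_gaps = 1) {
  rows <- list()
  for (mi in mirnas) {
    m <- nchar(mi$sequence)
    for (tr in transcripts) {
      s <- chartr("T", "U", toupper(tr$sequence))
      n <- nchar(s)
      hits <- list()
      for (len in (m - max_gaps):(m + max_gaps)) {
        if (len < 1 || len > n) next
        for (st in 1:(n - len + 1)) {
          sc <- score_site(mi, substr(s, st, st + len - 1),
                           seed_end = seed_end, max_gaps = max_gaps)
          if (sc$expectation <= max_expectation) {
            hits[[length(hits) + 1]] <- data.frame(
              mirna_id = mi$id, transcript_id = tr$id,
              t_start = st, t_end = st + len - 1,
              expectation = sc$expectation,
              mode = call_mode(sc), stringsAsFactors = FALSE)
          }
        }
      }
      if (!length(hits)) next
      h <- do.call(rbind, hits)
      h <- h[order(h$expectation, h$t_start), , drop = FALSE]
      kept <- h[0, ]
      for (r in seq_len(nrow(h))) {
        if (!nrow(kept) ||
            !any(h$t_start[r] <= kept$t_end & h$t_end[r] >= kept$t_start)) {
          kept <- rbind(kept, h[r, ])
        }
      }
      rows[[length(rows) + 1]] <- kept
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      t_start = integer(0), t_end = integer(0),
                      expectation = numeric(0), mode = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call the inhibition mode of a scored target site
#'
#' Central-complementarity convention for plant miRNAs: a mismatch or
#' gap at miRNA positions 10-11 (the slicing site) blocks cleavage, so
#' the site is called translational repression; otherwise cleavage.
#' Wobbles do not block cleavage.
#'
#' @param site scored site from [score_site()] (needs \code{columns}).
#' @return "cleavage" or "translation".
#' @export
call_mode <- function(site) {
  bad <- site$columns$type %in% c("mismatch", "gap") &
    site$columns$mirna_pos %in% c(10, 11)
  if (any(bad)) "translation" else "cleavage"
}
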