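#' Trim poly-A/T tails from an EST
#'
#' Removes a terminal run of A's at the 3' end and/or T's at the 5' end
#' (single-pass cDNA reads carry poly-A tails, or poly-T when read from
#' the other strand). A run of length k may contain up to
#' \code{floor(k / 10)} interrupting bases. Trimming is applied
#' repeatedly until stable, so it is idempotent.
#'
#' @param r a sequence record (DNA) from [read_fasta()].
#' @param min_run minimum run length that triggers trimming.
#' @return a cleaned-EST list with \code{id}, \code{sequence},
#'   \code{trimmed_5p}, \code{trimmed_3p}, \code{masked_fraction},
#'   \code{dropped} (TRUE when trimming consumed the whole read).
#' @examples
#' r <- list(id = "e1", sequence = "ACGTAAAAAAAA", alphabet = "dna")
#' trim_polyAT(r, min_run = 6)$trimmed_3p
#' @export
trim_polyAT <- function(r, min_run = 10) {
  s <- r$sequence
  t5 <- 0L
  t3 <- 0L
  repeat {
    k3 <- .tail_run(s, "A", from3p = TRUE, min_run = min_run)
    if (k3 > 0L) {
      s <- substr(s, 1L, nchar(s) - k3)
      t3 <- t3 + k3
      if (nchar(s) == 0L) break
      next
    }
    k5 <- .tail_run(s, "T", from3p = FALSE, min_run = min_run)
    if (k5 > 0L) {
      s <- substr(s, k5 + 1L, nchar(s))
      t5 <- t5 + k5
      if (nchar(s) == 0L) break
      next
    }
    break
  }
  list(id = r$id, sequence = s, trimmed_5p = t5, trimmed_3p = t3,
       masked_fraction = 0, dropped = nchar(s) == 0L)
}

# longest terminal run of `base` (with <=1 interruption per 10 bases)
# meeting min_run; 0 if none qualifies
.tail_run <- function(s, base, from3p, min_run) {
  ch <- strsplit(s, "")[[1]]
  if (from3p) ch <- rev(ch)
  is_base <- ch == base
  if (!length(is_base) || !is_base[1]) return(0L)
  miss <- cumsum(!is_base)
  k <- seq_along(ch)
  ok <- is_base & miss <= k %/% 10L
  best <- if (any(ok)) max(which(ok)) else 0L
  if (best >= min_run) best else 0L
}

#' Mask low-complexity regions (DUST-style)
#'
#' Scores each window by the DUST statistic: with \eqn{c_t} the count of
#' triplet t in the window and k the number of triplets (window - 2),
#' score = \eqn{\sum_t c_t (c_t - 1) / 2 / (k - 1)}. Windows scoring
#' strictly above \code{threshold} are soft-masked (lowercased); masked
#' bases are excluded from seed matching downstream but remain available
#' to alignment extensions.
#'
#' @param r cleaned-EST list (or any list with \code{sequence}).
#' @param window window width in bases (>= 4).
#' @param threshold DUST score above which a window is masked.
#' @return the input with \code{sequence} soft-masked and
#'   \code{masked_fraction} updated.
#' @export
mask_low_complexity <- function(r, window = 64, threshold = 2) {
  if (window < 4) stop("parameter error: window must be >= 4")
  s <- toupper(r$sequence)
  n <- nchar(s)
  mask <- logical(n)
  if (n >= window) {
    ch <- strsplit(s, "")[[1]]
    tri <- paste0(ch[1:(n - 2)], ch[2:(n - 1)], ch[3:n])
    for (start in 1:(n - window + 1)) {
      tw <- tri[start:(start + window - 3)]
      cnt <- table(tw)
      score <- sum(cnt * (cnt - 1) / 2) / (length(tw) - 1)
      if (score > threshold) mask[start:(start + window - 1)] <- TRUE
    }
  }
  ch <- strsplit(s, "")[[1]]
  ch[mask] <- tolower(ch[mask])
  r$sequence <- paste(ch, collapse = "")
  r$masked_fraction <- mean(mask)
  r
}

#' Collapse exact-duplicate sequences
#'
#' Keeps the first record of each distinct sequence, preserving input
#' order (mirrors redundancy removal in a multi-species mature-miRNA
#' reference set before homology search).
#'
#' @param rs list of sequence records.
#' @return de-duplicated list.
#' @export
deduplicate <- function(rs) {
  if (length(rs) == 0L) return(rs)
  seqs <- vapply(rs, `[[`, "", "sequence")
  rs[!duplicated(toupper(seqs))]
}

#' Greedy overlap assembly of cleaned ESTs
#'
#' A simplified overlap-layout assembler: repeatedly merges the pair
#' with the longest suffix-prefix overlap of length >= \code{min_overlap}
#' and identity >= \code{min_identity}, until no qualifying overlap
#' remains. Unmerged inputs become singlets. Forward strand only.
#'
#' @param rs list of cleaned ESTs (or sequence records).
#' @param min_overlap minimum overlap length (>= 16).
#' @param min_identity minimum fractional identity in the overlap (>= 0.9).
#' @return list of assembled units, each with \code{id}, \code{sequence},
#'   \code{kind} ("contig" or "singlet") and \code{member_ids}.
#' @export
assemble_greedy <- function(rs, min_overlap = 30, min_identity = 0.95) {
  stopifnot(min_overlap >= 16, min_identity >= 0.9)
  units <- lapply(rs, function(r) {
    list(id = r$id, sequence = toupper(r$sequence), member_ids = r$id)
  })
  repeat {
    n <- length(units)
    if (n < 2L) break
    best <- NULL
    best_len <- min_overlap - 1L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      ov <- .best_overlap(units[[i]]$sequence, units[[j]]$sequence,
                          min_overlap, min_identity)
      if (ov > best_len) {
        best_len <- ov
        best <- c(i, j)
      }
    }
    if (is.null(best)) break
    a <- units[[best[1]]]
    b <- units[[best[2]]]
    merged <- list(
      id = a$id,
      sequence = paste0(a$sequence,
                        substr(b$sequence, best_len + 1L, nchar(b$sequence))),
      member_ids = c(a$member_ids, b$member_ids)
    )
    units <- c(units[-best], list(merged))
  }
  ctg <- 0L
  lapply(units, function(u) {
    kind <- if (length(u$member_ids) >= 2L) "contig" else "singlet"
    id <- if (kind == "contig") {
      ctg <<- ctg + 1L
      paste0("contig", ctg)
    } else u$id
    list(id = id, sequence = u$sequence, kind = kind,
         member_ids = u$member_ids)
  })
}

# longest suffix(a)-prefix(b) overlap meeting thresholds, else 0
.best_overlap <- function(a, b, min_overlap, min_identity) {
  la <- nchar(a)
  lb <- nchar(b)
  if (min(la, lb) < min_overlap) return(0L)
  for (k in seq(min(la, lb), min_overlap, by = -1L)) {
    sa <- strsplit(substr(a, la - k + 1L, la), "")[[1]]
    sb <- strsplit(substr(b, 1L, k), "")[[1]]
    if (mean(sa == sb) >= min_identity) return(k)
  }
  0L
}

#' Screen units against a contaminant set by exact k-mer match
#'
#' Simplified vector/contaminant screen: a unit sharing any exact k-mer
#' with the contaminant set is flagged.
#'
#' @param units list of assembled units or records.
#' @param contaminants list of contaminant sequence records, or NULL to
#'   skip screening.
#' @param k k-mer length.
#' @return logical vector, TRUE where the unit is contaminated.
#' @export
screen_contaminants <- function(units, contaminants, k = 16) {
  if (is.null(contaminants) || length(contaminants) == 0L) {
    return(rep(FALSE, length(units)))
  }
  kmers <- unlist(lapply(contaminants, function(cc) {
    .kmers(chartr("U", "T", toupper(cc$sequence)), k)
  }))
  vapply(units, function(u) {
    any(.kmers(chartr("U", "T", toupper(u$sequence)), k) %in% kmers)
  }, logical(1))
}

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}
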