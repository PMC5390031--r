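#' Reverse complement of a DNA/RNA string
#'
#' @param s sequence string; case preserved.
#' @param alphabet "dna" or "rna".
#' @return reverse-complemented string.
#' @export
revcomp <- function(s, alphabet = "dna") {
  map <- if (alphabet == "rna") c("ACGUacgu", "UGCAugca") else c("ACGTacgt", "TGCAtgca")
  paste(rev(strsplit(chartr(map[1], map[2], s), "")[[1]]), collapse = "")
}

#' Build a seed word index over assembled units
#'
#' Indexes every fully unmasked word of length \code{word} on both
#' strands of every unit, T-normalised. Soft-masked (lowercase) bases
#' are excluded from seeding; extensions may still cross them.
#'
#' @param units list of assembled units (\code{id}, \code{sequence}).
#' @param word word length (>= 4); 7 mirrors the BLAST word size used
#'   for mature-miRNA homology searches.
#' @return an index object (environment keyed by word, holding matrices
#'   of unit index / strand / start-on-strand), with attributes
#'   \code{word} and \code{units}.
#' @export
build_word_index <- function(units, word = 7) {
  if (word < 4) stop("word must be >= 4")
  chunks <- list()
  for (ui in seq_along(units)) {
    for (strand in c(1L, -1L)) {
      s <- units[[ui]]$sequence
      if (strand < 0) s <- revcomp(s)
      n <- nchar(s)
      if (n < word) next
      starts <- 1:(n - word + 1)
      words <- substring(s, starts, starts + word - 1L)
      keep <- grepl("^[ACGT]+$", chartr("U", "T", words))  # unmasked only
      if (!any(keep)) next
      chunks[[length(chunks) + 1L]] <- data.frame(
        word = chartr("U", "T", toupper(words[keep])),
        unit = ui, strand = strand, start = starts[keep],
        stringsAsFactors = FALSE)
    }
  }
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (length(chunks)) {
    big <- do.call(rbind, chunks)
    entries <- lapply(split(seq_len(nrow(big)), big$word), function(rows) {
      cbind(unit = big$unit[rows], strand = big$strand[rows],
            start = big$start[rows])
    })
    list2env(entries, envir = idx)
  }
  attr(idx, "word") <- as.integer(word)
  attr(idx, "n_units") <- length(units)
  idx
}

#' Seeded homology scan of mature miRNAs against assembled units
#'
#' For every exact seed-word match, the full mature sequence is extended
#' ungapped over the unit; a hit is reported when the whole mature
#' aligns with at most \code{max_mismatch} mismatches, no gaps, and
#' aligned length >= \code{min_len}. Reverse-strand hits are reported in
#' forward coordinates of the unit with strand "-". Duplicate hits at
#' the same locus/strand are collapsed.
#'
#' @param mirnas list of mature miRNA records (RNA).
#' @param index word index from [build_word_index()].
#' @param units the same unit list the index was built from.
#' @param max_mismatch maximum mismatches over the mature length.
#' @param min_len minimum aligned length; matures shorter than this are
#'   skipped with a warning.
#' @return data.frame of hits: \code{mirna_id}, \code{unit_id},
#'   \code{unit_start}, \code{unit_end} (1-based inclusive, forward
#'   coordinates), \code{strand}, \code{aligned_length},
#'   \code{mismatches}, \code{gaps} (always 0).
#' @export
scan_homologs <- function(mirnas, index, units, max_mismatch = 3, min_len = 18) {
  word <- attr(index, "word")
  out <- list()
  for (m in mirnas) {
    q <- chartr("U", "T", toupper(m$sequence))
    L <- nchar(q)
    if (L < min_len) {
      warning("mature '", m$id, "' shorter than min_len; skipped")
      next
    }
    qc <- strsplit(q, "")[[1]]
    seen <- character(0)
    seed_starts <- 1:(L - word + 1)
    for (p in seed_starts) {
      entries <- index[[substr(q, p, p + word - 1L)]]
      if (is.null(entries)) next
      for (e in seq_len(nrow(entries))) {
        ui <- entries[e, 1]
        strand <- if (entries[e, 2] > 0) "+" else "-"
        s <- units[[ui]]$sequence
        if (strand == "-") s <- revcomp(s)
        off <- entries[e, 3] - p + 1L
        if (off < 1L || off + L - 1L > nchar(s)) next
        winc <- strsplit(chartr("U", "T",
                         toupper(substr(s, off, off + L - 1L))), "")[[1]]
        mm <- sum(winc != qc)
        if (mm > max_mismatch) next
        n <- nchar(units[[ui]]$sequence)
        if (strand == "+") {
          st <- off
          en <- off + L - 1L
        } else {
          st <- n - (off + L - 1L) + 1L
          en <- n - off + 1L
        }
        key <- paste(m$id, ui, st, strand, sep = "/")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = m$id, unit_id = units[[ui]]$id,
          unit_start = st, unit_end = en, strand = strand,
          aligned_length = L, mismatches = mm, gaps = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), unit_id = character(0),
                      unit_start = integer(0), unit_end = integer(0),
                      strand = character(0), aligned_length = integer(0),
                      mismatches = integer(0), gaps = integer(0)))
  }
  do.call(rbind, out)
}
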