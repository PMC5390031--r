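#' Extract a precursor candidate around a homology hit
#'
#' Takes \code{flank} nucleotides upstream and downstream of the mature
#' locus on the hit strand (truncated at unit boundaries) and returns
#' the candidate as RNA. Absent truncation the precursor length is
#' mature length + 2*flank, the mature+100 pattern of ~20-21 nt matures
#' giving 120-121 nt precursors.
#'
#' @param hit one row of the hit table from [scan_homologs()] (as a
#'   list or single-row data.frame).
#' @param units unit list the hit refers to.
#' @param flank flanking length on each side (default 50).
#' @param min_flank minimum surviving flank; candidates truncated below
#'   this are rejected.
#' @return a precursor candidate list (\code{id}, \code{sequence} (RNA),
#'   \code{mature_start}, \code{mature_end}, \code{source_hit}) or
#'   \code{NULL} with attribute-free rejection signalled by a list with
#'   \code{rejected = TRUE} and a \code{reason}.
#' @export
extract_precursor <- function(hit, units, flank = 50, min_flank = 20) {
  stopifnot(flank >= 0)
  hit <- as.list(hit)
  uidx <- which(vapply(units, `[[`, "", "id") == hit$unit_id)[1]
  if (is.na(uidx)) stop("unknown unit id: ", hit$unit_id)
  s <- toupper(units[[uidx]]$sequence)
  n <- nchar(s)
  if (hit$strand == "-") {
    s <- revcomp(s)
    st <- n - hit$unit_end + 1L
    en <- n - hit$unit_start + 1L
  } else {
    st <- hit$unit_start
    en <- hit$unit_end
  }
  up <- min(flank, st - 1L)
  down <- min(flank, n - en)
  if (up < min_flank || down < min_flank) {
    return(list(rejected = TRUE,
                reason = sprintf("flank truncated to %d/%d (< %d)",
                                 up, down, min_flank)))
  }
  pre <- chartr("T", "U", substr(s, st - up, en + down))
  list(id = paste0(hit$mirna_id, "@", hit$unit_id, ":", hit$unit_start),
       sequence = pre,
       mature_start = up + 1L,
       mature_end = up + (en - st + 1L),
       source_hit = hit,
       rejected = FALSE)
}

#' Fold a precursor candidate into a hairpin structure
#'
#' The folding engine is pluggable. The built-in engine is a simplified
#' nearest-neighbour model (stacking energies only, minimum loop 3, no
#' dangling ends) solved exactly by dynamic programming; it needs no
#' external software. The external engine shells out to ViennaRNA's
#' \code{RNAfold} (37 C, default parameters) when it is on the PATH.
#' Both return a non-crossing structure; the same input always gives
#' the same output for a fixed engine.
#'
#' @param p precursor candidate (or any list with an RNA \code{sequence}).
#' @param engine "builtin" or "external".
#' @param min_len minimum sequence length; relax for small test cases.
#' @return list with \code{structure} (dot-bracket) and \code{mfe}
#'   (kcal/mol, <= 0).
#' @examples
#' fold_hairpin(list(sequence = "GGGGAAAACCCC"), min_len = 1)
#' @export
fold_hairpin <- function(p, engine = c("builtin", "external"), min_len = 40) {
  engine <- match.arg(engine)
  s <- chartr("T", "U", toupper(p$sequence))
  if (nchar(s) < min_len) {
    stop("precursor shorter than ", min_len, " nt")
  }
  if (engine == "builtin") {
    res <- .fold_builtin_cpp(s)
    return(list(structure = res$structure, mfe = res$mfe))
  }
  rnafold <- Sys.which("RNAfold")
  if (!nzchar(rnafold)) stop("RNAfold not found on PATH")
  out <- system2(rnafold, c("--noPS"), input = s, stdout = TRUE)
  line <- out[2]
  struct <- sub("\\s.*$", "", line)
  mfe <- as.numeric(gsub("[()\\s]", "", sub("^\\S+\\s+", "", line), perl = TRUE))
  list(structure = struct, mfe = mfe)
}

#' Hairpin statistics: GC%, AU%, MFE, AMFE, MFEI
#'
#' The discriminative statistics of a candidate pre-miRNA:
#' GC% = 100 (G+C)/length, AU% = 100 - GC%, AMFE = MFE/length * 100
#' (kcal/mol per 100 nt) and MFEI = AMFE / GC% (with GC% as the
#' percentage number), the minimal folding free energy index that
#' separates miRNA hairpins from other RNAs. Values are returned at
#' full precision; use [round_display()] for 2-decimal display.
#'
#' @param p precursor candidate (RNA sequence).
#' @param f fold result from [fold_hairpin()], or a list with
#'   \code{mfe}.
#' @return list with \code{precursor_length}, \code{gc_percent},
#'   \code{au_percent}, \code{mfe}, \code{amfe}, \code{mfei}.
#' @examples
#' p <- list(sequence = paste(rep("GCAU", 25), collapse = ""))
#' hairpin_stats(p, list(mfe = -30))
#' @export
hairpin_stats <- function(p, f) {
  s <- chartr("T", "U", toupper(p$sequence))
  n <- nchar(s)
  gc <- 100 * (lengths(regmatches(s, gregexpr("[GC]", s)))) / n
  if (gc == 0) stop("MFEI undefined: GC content is zero")
  amfe <- f$mfe / n * 100
  list(precursor_length = n,
       gc_percent = gc,
       au_percent = 100 - gc,
       mfe = f$mfe,
       amfe = amfe,
       mfei = amfe / gc)
}

#' Round for display, half away from zero
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded values.
#' @export
round_display <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
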