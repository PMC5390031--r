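#' Read a FASTA file into sequence records
#'
#' Parses a FASTA file into a list of sequence records, normalising case
#' and the U/T alphabet. miRBase-style mature miRNA files use the RNA
#' alphabet (U); EST and transcript files use DNA (T). The declared
#' alphabet is enforced for the whole file: with \code{alphabet = "rna"}
#' any T is converted to U, with \code{"dna"} any U to T, and with
#' \code{"auto"} the file is called RNA if it contains U and no T, DNA
#' otherwise.
#'
#' @param path path to a FASTA file.
#' @param alphabet one of \code{"rna"}, \code{"dna"}, \code{"auto"}.
#' @return a list of records, each a list with elements \code{id},
#'   \code{description}, \code{sequence} (uppercase) and
#'   \code{alphabet}; records are in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), fa)
#' read_fasta(fa, "rna")[[1]]$sequence
#' @export
read_fasta <- function(path, alphabet = c("auto", "rna", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "auto") {
    alphabet <- if (any(grepl("U", seqs, fixed = TRUE)) &&
                    !any(grepl("T", seqs, fixed = TRUE))) "rna" else "dna"
  }
  seqs <- if (alphabet == "rna") chartr("T", "U", seqs) else chartr("U", "T", seqs)
  legal <- if (alphabet == "rna") "^[ACGUN]+$" else "^[ACGTN]+$"
  bad <- which(!grepl(legal, seqs))
  if (length(bad)) {
    stop("illegal characters in record '", ids[bad[1]], "' of ", path)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in record '", ids[which(nchar(seqs) == 0L)[1]], "'")
  }
  mapply(function(i, d, s) {
    list(id = i, description = d, sequence = s, alphabet = alphabet)
  }, ids, desc, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' Sequences are wrapped at 60 columns; \code{read_fasta} round-trips
#' ids and sequences exactly.
#'
#' @param records list of records as returned by [read_fasta()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(length(records) > 0)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description %||% "")) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a dot-bracket secondary-structure string
#'
#' Checks that a structure string over \code{(}, \code{)}, \code{.} is
#' balanced and purely nested (dot-bracket notation cannot express
#' crossing pairs, so balance is the binding constraint). Reports the
#' index of the first violation.
#'
#' @param s structure string.
#' @return a list with \code{structure}, \code{length} and \code{pairs}
#'   (two-column matrix of 1-based paired positions).
#' @examples
#' validate_dotbracket("((..))")$pairs
#' @export
validate_dotbracket <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
    stop("structure error: empty or non-scalar structure string")
  }
  ch <- strsplit(s, "")[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad)) stop("structure error: illegal character at position ", bad[1])
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0L) {
        stop("structure error: unmatched ')' at position ", i)
      }
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  if (length(open)) {
    stop("structure error: unmatched '(' at position ", open[length(open)])
  }
  list(structure = s, length = length(ch), pairs = pairs)
}

#' Pairing partner table from a dot-bracket string
#'
#' @param s validated dot-bracket string.
#' @return integer vector \code{p} with \code{p[i]} the partner of
#'   position i, or \code{NA} if unpaired.
#' @export
pair_table <- function(s) {
  db <- validate_dotbracket(s)
  p <- rep(NA_integer_, db$length)
  if (nrow(db$pairs)) {
    p[db$pairs[, 1]] <- db$pairs[, 2]
    p[db$pairs[, 2]] <- db$pairs[, 1]
  }
  p
}

#' Read a typed TSV table against a column schema
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema named character vector mapping column names to types
#'   (\code{"numeric"} or \code{"character"}).
#' @return a data.frame with the schema's columns, typed; extra columns
#'   are preserved as character.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v))
      if (length(bad)) {
        stop("schema error: unparseable numeric cell in column '", col,
             "', row ", bad[1])
      }
      df[[col]] <- v
    }
  }
  df
}
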