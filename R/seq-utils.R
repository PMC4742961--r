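#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; only `A`, `C`, `G`, `T` and `N` are
#' accepted. Parse failures report the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "crisprcensus_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(setNames(character(0), character(0)))
  }
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(setNames(character(0), character(0)))
  }
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    abort(
      paste0("malformed FASTA: expected '>' header at line ", first),
      class = "crisprcensus_parse_error"
    )
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad) > 0) {
    # locate the first illegal character's line for the error message
    hdr <- which(startsWith(lines, ">"))
    rec_line <- hdr[bad[1]]
    body <- lines[seq(rec_line + 1, length(lines))]
    stop_at <- which(startsWith(body, ">"))
    if (length(stop_at) > 0) body <- body[seq_len(stop_at[1] - 1)]
    off <- which(grepl("[^ACGTNacgtn]", body))[1]
    abort(
      paste0(
        "illegal character in sequence '", names(set)[bad[1]],
        "' at line ", rec_line + off
      ),
      class = "crisprcensus_parse_error"
    )
  }
  # ids: first whitespace-delimited token of the header
  ids <- sub("\\s.*$", "", names(set))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  if (length(seqs) == 0 || is.null(names(seqs))) {
    abort("write_fasta() needs a non-empty named vector", class = "crisprcensus_io_error")
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' `N` complements to `N`.
#'
#' @param seq Nucleotide string (ACGTN).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Six-frame translation
#'
#' Translates the three forward frames of `seq` and the three frames of its
#' reverse complement under the standard genetic code. Stops are `*`,
#' ambiguous codons (any `N`) are `X`, and trailing partial codons are
#' dropped.
#'
#' @param seq Nucleotide string, length >= 3.
#' @return Character vector of six protein strings, named
#'   `F1,F2,F3,R1,R2,R3`.
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3) {
    abort("sequence shorter than one codon", class = "crisprcensus_input_error")
  }
  fwd <- Biostrings::DNAString(toupper(seq))
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3
    if (n == 0) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1, width = n),
      if.fuzzy.codon = "X"
    ))
  }
  c(
    F1 = one(fwd, 0), F2 = one(fwd, 1), F3 = one(fwd, 2),
    R1 = one(rev, 0), R2 = one(rev, 1), R3 = one(rev, 2)
  )
}
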