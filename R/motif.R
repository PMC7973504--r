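# Ungapped sliding-window mismatch scan of short transcription-factor
# binding motifs over promoter windows. Coordinates are 0-based, half-open,
# relative to the scanned window start.

#' The three EVI1 DNA-binding motifs
#'
#' The N-terminal zinc-finger domain binding sequence, the C-terminal
#' domain binding sequence, and the overall consensus binding sequence.
#'
#' @return named character vector:
#'   `n_terminal` = `GACAAGATA`, `c_terminal` = `GAAGATGAG`,
#'   `consensus` = `TGACAAGATAA`.
#' @export
eviMotifs <- function() {
  c(n_terminal = "GACAAGATA", c_terminal = "GAAGATGAG",
    consensus = "TGACAAGATAA")
}

#' Ungapped mismatch scan of motifs over a sequence window
#'
#' Counts exact base matches of each motif at every offset of the window
#' (and, optionally, of the reverse strand: the reverse-complemented motif
#' scanned against the given sequence, positions still reported on the
#' forward coordinates). `N` in the sequence never matches. Hits per motif
#' are ranked by match count (descending) with ties broken by ascending
#' position, `+` strand first; the top `topK` per motif are returned.
#'
#' @param sequence a [Biostrings::DNAString] or character (alphabet ACGTN),
#'   at least as long as the shortest motif; motifs longer than the
#'   sequence are skipped.
#' @param motifs named character vector of uppercase ACGT motifs (default
#'   [eviMotifs()]).
#' @param bothStrands also scan the reverse strand (default FALSE: promoter
#'   orientation is assumed given).
#' @param topK hits returned per motif.
#' @return a data.frame of hits: `motifName`, `position` (0-based offset),
#'   `strand`, `matches`, `motifLength`, `fraction`.
#' @examples
#' scanMotifs("TGACAAGATAA", topK = 1)
#' @export
scanMotifs <- function(sequence, motifs = eviMotifs(),
                       bothStrands = FALSE, topK = 5) {
  subject <- Biostrings::DNAString(as.character(sequence))
  L <- length(subject)
  stopifnot(length(motifs) >= 1L, !is.null(names(motifs)))
  if (L < min(nchar(motifs)))
    stop("sequence (", L, " bp) is shorter than every motif")
  hits <- lapply(names(motifs), function(nm) {
    pat <- motifs[[nm]]
    w <- nchar(pat)
    if (w > L) return(NULL)
    starts <- seq_len(L - w + 1L)
    strands <- if (bothStrands) c("+", "-") else "+"
    per <- lapply(strands, function(st) {
      p <- Biostrings::DNAString(pat)
      if (st == "-") p <- Biostrings::reverseComplement(p)
      nedit <- Biostrings::neditStartingAt(p, subject, starting.at = starts,
                                           with.indels = FALSE)
      data.frame(motifName = nm, position = starts - 1L, strand = st,
                 matches = w - nedit, motifLength = w,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, per)
    d <- d[order(-d$matches, d$position, d$strand), , drop = FALSE]
    utils::head(d, topK)
  })
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out$fraction <- out$matches / out$motifLength
  out
}

#' Extract the promoter-proximal upstream window from a FASTA record
#'
#' Records are stored 5'-to-3' as upstream regions, so the window closest
#' to the transcription start is the *final* `window` bases; shorter
#' records are returned whole with a warning.
#'
#' @param record a [Biostrings::DNAString], a single-element
#'   [Biostrings::DNAStringSet], or a character string.
#' @param window window size in bp (default 5000).
#' @return a [Biostrings::DNAString] of at most `window` bases.
#' @export
upstreamWindow <- function(record, window = 5000) {
  if (is(record, "DNAStringSet")) {
    stopifnot(length(record) == 1L)
    record <- record[[1L]]
  }
  x <- Biostrings::DNAString(as.character(record))
  L <- length(x)
  if (L <= window) {
    if (L < window)
      warning("record is ", L, " bp, shorter than the requested ",
              window, " bp window; returning it whole")
    return(x)
  }
  Biostrings::subseq(x, start = L - window + 1L, end = L)
}
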