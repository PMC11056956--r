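# In-silico PCR utilities for RT-qPCR primer assays.  Primer tables are
# sometimes typeset with the forward and reverse sequences run together
# into one string; given the target transcript the unique split point
# can be recovered (prefix matches the sense strand, reverse-complement
# of the suffix matches downstream).  Matching is exact; transcripts
# are supplied as FASTA, never fetched.

as_dna <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  s <- toupper(as.character(x))
  if (!grepl("^[ACGT]+$", s)) stop_adq("sequence must be over {A, C, G, T}")
  Biostrings::DNAString(s)
}

match_starts <- function(pattern, subject) {
  Biostrings::start(Biostrings::matchPattern(pattern, subject))
}

#' Split a concatenated forward+reverse primer string
#'
#' Scans every split point of `s`; a split is valid when the prefix
#' matches the transcript sense strand at a unique position and the
#' reverse-complement of the suffix matches uniquely downstream of it.
#' Exactly one valid split must exist.
#'
#' @param s concatenated primer string (forward then reverse, 5'-3').
#' @param transcript transcript sequence (character or `DNAString`).
#' @param min_len minimum primer length considered (default 15).
#' @return list `forward`, `reverse` (character).
#' @export
split_concatenated_primers <- function(s, transcript, min_len = 15) {
  s <- toupper(as.character(s))
  if (!grepl("^[ACGT]+$", s)) stop_adq("primer string must be over {A, C, G, T}")
  tx <- as_dna(transcript)
  lo <- max(1, min_len); hi <- nchar(s) - max(1, min_len)
  if (hi < lo) stop_adq("primer string too short to split at length >= ", min_len)
  hits <- list()
  for (k in lo:hi) {
    fwd <- substr(s, 1, k)
    rev <- substr(s, k + 1, nchar(s))
    fpos <- match_starts(fwd, tx)
    if (length(fpos) != 1) next
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
    rpos <- match_starts(rc, tx)
    rpos <- rpos[rpos > fpos]
    if (length(rpos) != 1) next
    hits[[length(hits) + 1]] <- list(k = k, forward = fwd, reverse = rev)
  }
  if (length(hits) == 0)
    stop_adq("no valid split point: primers do not match this transcript")
  if (length(hits) > 1)
    stop_adq("ambiguous primer split; candidate split points: ",
             paste(vapply(hits, `[[`, numeric(1), "k"), collapse = ", "))
  hits[[1]][c("forward", "reverse")]
}

#' In-silico PCR product size
#'
#' Both primers must bind exactly and uniquely, the forward on the sense
#' strand upstream of the reverse primer's (reverse-complement) site.
#' The product length runs from the forward primer's 5' start to the
#' reverse primer's 5' start on the opposite strand, inclusive of both
#' primers.
#'
#' @param forward,reverse primer sequences (5'-3').
#' @param transcript transcript sequence (character or `DNAString`).
#' @return integer product length in bp.
#' @export
insilico_pcr <- function(forward, reverse, transcript) {
  tx <- as_dna(transcript)
  fwd <- as_dna(forward); rev <- as_dna(reverse)
  fpos <- match_starts(fwd, tx)
  if (length(fpos) == 0) stop_adq("forward primer has no binding site")
  if (length(fpos) > 1) stop_adq("forward primer binds at multiple sites")
  rc <- Biostrings::reverseComplement(rev)
  rpos <- match_starts(rc, tx)
  if (length(rpos) == 0) stop_adq("reverse primer has no binding site")
  if (length(rpos) > 1) stop_adq("reverse primer binds at multiple sites")
  prod_end <- rpos + length(rc) - 1L
  if (rpos <= fpos) stop_adq("reverse site is not downstream of the forward site")
  as.integer(prod_end - fpos + 1L)
}

#' Resolve a table of primer assays against transcript sequences
#'
#' @param assays data frame with `gene`, `accession`, and either
#'   `primers` (concatenated) or `forward` + `reverse` columns, and
#'   optionally `expected_bp`.
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcript sequences keyed by accession.
#' @return data frame `gene`, `accession`, `forward`, `reverse`,
#'   `product_bp`, `matches_expected` (`NA` when no expectation given);
#'   unresolvable assays carry `NA` sizes and the error in `note`.
#' @export
resolve_primer_assays <- function(assays, transcripts) {
  out <- lapply(seq_len(nrow(assays)), function(i) {
    a <- assays[i, ]
    res <- data.frame(gene = a$gene, accession = a$accession,
                      forward = NA_character_, reverse = NA_character_,
                      product_bp = NA_integer_, matches_expected = NA,
                      note = NA_character_)
    if (!a$accession %in% names(transcripts)) {
      res$note <- "transcript not supplied"
      return(res)
    }
    tx <- transcripts[[a$accession]]
    ans <- tryCatch({
      pr <- if (!is.null(a$forward) && !is.na(a$forward))
        list(forward = a$forward, reverse = a$reverse)
      else split_concatenated_primers(a$primers, tx)
      bp <- insilico_pcr(pr$forward, pr$reverse, tx)
      res$forward <- pr$forward; res$reverse <- pr$reverse
      res$product_bp <- bp
      if (!is.null(a$expected_bp) && !is.na(a$expected_bp))
        res$matches_expected <- bp == a$expected_bp
      res
    }, error = function(e) { res$note <- conditionMessage(e); res })
    ans
  })
  do.call(rbind, out)
}

#' Read a FASTA file into a named vector of sequences
#'
#' @param path FASTA file.
#' @return named character vector (names = first word of each header).
#' @export
read_fasta_seqs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  stats::setNames(as.character(set), names(set))
}
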