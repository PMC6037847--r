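#' Alignment scoring scheme
#'
#' Affine-gap scoring used by \code{\link{align_pair}} and
#' \code{\link{search_library}}. A gap run of length L costs
#' \code{gap_open + (L - 1) * gap_extend}. The defaults (+1/-1, -2/-1) are
#' a deliberately simple, documented convention; identity-based
#' authentication depends on the identity ratio far more than on the exact
#' scores.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open score of the first position of a gap run
#'   (\code{<= gap_extend}).
#' @param gap_extend score of each further gap position (< 0).
#' @return an object of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -1) {
  if (!(match > 0 && mismatch < 0)) {
    stop("need match > 0 > mismatch", call. = FALSE)
  }
  if (!(gap_open <= gap_extend && gap_extend < 0)) {
    stop("need gap_open <= gap_extend < 0", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal pairwise alignment of two nucleotide sequences
#'
#' Dynamic-programming alignment under affine gap penalties, global
#' (Needleman-Wunsch with penalized end gaps) or local (Smith-Waterman).
#' Traceback is deterministic: diagonal is preferred, then the vertical
#' gap, then the horizontal gap, so identical inputs always yield the
#' identical alignment. Symbols are compared literally; IUPAC-compatible
#' but non-identical symbols count as mismatches.
#'
#' @param seq_a,seq_b non-empty nucleotide strings.
#' @param mode \code{"global"} or \code{"local"}.
#' @param scoring a \code{\link{scoring_scheme}}.
#' @return object of class \code{alignment}: \code{aligned_a},
#'   \code{aligned_b} (equal-length gapped strings), \code{score},
#'   \code{mode}, \code{scoring}.
#' @examples
#' align_pair("ACGT", "ACGA")
#' align_pair("TTTACGTTTT", "ACGT", mode = "local")
#' @export
align_pair <- function(seq_a, seq_b, mode = c("global", "local"),
                       scoring = scoring_scheme()) {
  mode <- match.arg(mode)
  seq_a <- assert_sequence(seq_a, "seq_a")
  seq_b <- assert_sequence(seq_b, "seq_b")
  stopifnot(inherits(scoring, "scoring_scheme"))
  res <- cpp_align(seq_a, seq_b, mode == "local", scoring$match,
                   scoring$mismatch, scoring$gap_open, scoring$gap_extend)
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, mode = mode, scoring = scoring),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s, score %g, %d columns\n",
              x$mode, x$score, nchar(x$aligned_a)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' BLAST-style identity: 100 x identical columns / total alignment
#' columns, gap columns included in the denominator. IUPAC-compatible but
#' non-identical symbols (e.g. N over A) count as non-identical.
#'
#' @param alignment an \code{\link{align_pair}} result.
#' @return percent identity in [0, 100], full precision (callers that
#'   report identities round to 1 decimal place, half up).
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "alignment"))
  n <- nchar(alignment$aligned_a)
  if (n == 0L) stop("zero-length alignment; identity undefined", call. = FALSE)
  a <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  100 * sum(a == b & a != "-") / n
}

#' Search a query sequence against the reference library
#'
#' Alignment-based stand-in for a BLAST search of a remote database:
#' aligns the query against every same-marker SRM reference and ranks
#' references by percent identity (reported to 1 decimal place, half-up,
#' matching the precision conventionally reported by identity searches).
#' Global alignment is used when the two lengths are compatible
#' (shorter/longer >= \code{length_ratio}); otherwise local alignment, so
#' that a bare core can still be matched against a much longer reference.
#'
#' All references tied with the \code{top_n}-th identity are returned;
#' within a tie, hits are ordered by species name, then record id.
#'
#' @param query a \code{\link{barcode_record}} or a nucleotide string.
#' @param library a \code{barcode_library}.
#' @param marker marker to search (default: the query record's marker).
#' @param top_n number of top identities to keep (default 5).
#' @param scoring a \code{\link{scoring_scheme}}.
#' @param length_ratio global/local switch (default 0.5).
#' @param kmer_screen if \code{TRUE}, references sharing no \code{k}-mer
#'   with the query are skipped before alignment (speed knob; default off,
#'   libraries are small).
#' @param k word size for the screen.
#' @return data frame of class \code{hit_table}: \code{query_id},
#'   \code{rank}, \code{record_id}, \code{species}, \code{drug},
#'   \code{identity}, \code{mode}, \code{score}, \code{n_ident},
#'   \code{n_cols}.
#' @export
search_library <- function(query, library, marker = NULL, top_n = 5,
                           scoring = scoring_scheme(), length_ratio = 0.5,
                           kmer_screen = FALSE, k = 8) {
  stopifnot(inherits(library, "barcode_library"))
  if (inherits(query, "barcode_record")) {
    qid <- query$record_id
    qseq <- query$sequence
    if (is.null(marker)) marker <- query$marker
  } else {
    qid <- "query"
    qseq <- assert_sequence(query, "query")
  }
  if (is.null(marker)) stop("marker must be given for a bare query string",
                            call. = FALSE)
  marker <- assert_marker(marker)
  if (nchar(qseq) == 0L) stop("query sequence is empty", call. = FALSE)

  refs <- library$records
  refs <- refs[refs$role == "SRM" & refs$marker == marker, , drop = FALSE]
  if (!nrow(refs)) {
    stop("library has no ", marker, " references to search", call. = FALSE)
  }

  if (isTRUE(kmer_screen) && nchar(qseq) >= k) {
    qk <- unique(substring(qseq, seq_len(nchar(qseq) - k + 1L),
                           seq_len(nchar(qseq) - k + 1L) + k - 1L))
    keep <- vapply(refs$sequence, function(rs) {
      if (nchar(rs) < k) return(TRUE)
      rk <- substring(rs, seq_len(nchar(rs) - k + 1L),
                      seq_len(nchar(rs) - k + 1L) + k - 1L)
      any(rk %in% qk)
    }, logical(1), USE.NAMES = FALSE)
    if (any(keep)) refs <- refs[keep, , drop = FALSE]
  }

  rl <- nchar(refs$sequence)
  ql <- nchar(qseq)
  local_mode <- pmin(ql, rl) / pmax(ql, rl) < length_ratio
  st <- cpp_search_stats(qseq, refs$sequence, local_mode, scoring$match,
                         scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend)
  identity <- ifelse(st$n_cols > 0, round_half_up(100 * st$n_ident / st$n_cols, 1), 0)

  hits <- data.frame(
    query_id = qid, rank = NA_integer_,
    record_id = refs$record_id, species = refs$species, drug = refs$drug,
    identity = identity, mode = ifelse(local_mode, "local", "global"),
    score = st$score, n_ident = st$n_ident, n_cols = st$n_cols,
    stringsAsFactors = FALSE)
  ord <- order(-hits$identity, hits$species, hits$record_id)
  hits <- hits[ord, , drop = FALSE]
  if (nrow(hits) > top_n) {
    cutoff <- hits$identity[top_n]
    hits <- hits[hits$identity >= cutoff, , drop = FALSE]
  }
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  class(hits) <- c("hit_table", "data.frame")
  hits
}
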