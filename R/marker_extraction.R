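#' Primer set for in-silico marker extraction
#'
#' A pair of PCR primers used as flank anchors to cut the barcode core out
#' of a longer amplicon or consensus sequence. Both primers are given
#' 5'->3' as they would be ordered; the reverse primer therefore matches
#' the reverse complement of the template downstream of the core.
#'
#' @param marker \code{"ITS2"} or \code{"psbA-trnH"}.
#' @param forward,reverse primer sequences, 5'->3'.
#' @param max_mismatch_fraction maximum fraction of mismatching positions
#'   tolerated when anchoring a primer (default 0.10; must be < 0.5).
#' @return an object of class \code{primer_set}.
#' @seealso \code{\link{default_primers}} for the standard universal
#'   primers used for these two markers.
#' @export
primer_set <- function(marker, forward, reverse, max_mismatch_fraction = 0.10) {
  marker <- assert_marker(marker)
  forward <- assert_sequence(forward, "forward primer")
  reverse <- assert_sequence(reverse, "reverse primer")
  if (!is.numeric(max_mismatch_fraction) || max_mismatch_fraction < 0 ||
      max_mismatch_fraction >= 0.5) {
    stop("max_mismatch_fraction must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(marker = marker, forward = forward, reverse = reverse,
                 max_mismatch_fraction = max_mismatch_fraction),
            class = "primer_set")
}

#' Default universal primer sets
#'
#' The universal primer pairs routinely used to amplify the two barcode
#' regions in medicinal-plant work: ITS2F/ITS3R for nuclear ribosomal ITS2
#' and PA/TH for the chloroplast psbA-trnH intergenic spacer.
#'
#' @param max_mismatch_fraction mismatch budget per anchor (default 0.10).
#' @return named list of two \code{\link{primer_set}} objects
#'   (\code{ITS2}, \code{psbA-trnH}).
#' @export
default_primers <- function(max_mismatch_fraction = 0.10) {
  list(
    "ITS2" = primer_set("ITS2",
                        forward = "ATGCGATACTTGGTGTGAAT",     # ITS2F
                        reverse = "GACGCTTCTCCAGACTACAAT",    # ITS3R
                        max_mismatch_fraction = max_mismatch_fraction),
    "psbA-trnH" = primer_set("psbA-trnH",
                             forward = "GTTATGCATGAACGTAATGCTC",   # PA
                             reverse = "CGCGCATGGTGGATTCACAATCC",  # TH
                             max_mismatch_fraction = max_mismatch_fraction)
  )
}

# Expected bare-core length ranges per marker, used by permissive
# pass-through when no anchors are found.
marker_length_range <- function(marker) {
  switch(marker, "ITS2" = c(190L, 280L), "psbA-trnH" = c(262L, 520L))
}

# compat[x, y] is TRUE when IUPAC codes x and y denote at least one common
# base ("ambiguity codes match any base they denote"). Built on first use,
# then cached.
iupac_compat_env <- new.env(parent = emptyenv())
iupac_compat_matrix <- function() {
  if (is.null(iupac_compat_env$m)) {
    m <- matrix(FALSE, length(IUPAC_LETTERS), length(IUPAC_LETTERS),
                dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
    for (x in IUPAC_LETTERS) for (y in IUPAC_LETTERS) {
      m[x, y] <- length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0L
    }
    iupac_compat_env$m <- m
  }
  iupac_compat_env$m
}

#' Find the best ungapped placement of a primer motif in a sequence
#'
#' Scans every ungapped placement of \code{motif} along \code{sequence},
#' counting mismatches with IUPAC-aware matching (an ambiguity code matches
#' any base it denotes, on either side). Returns the leftmost placement
#' with the minimal mismatch count among placements whose mismatch fraction
#' does not exceed the budget; absence is a valid result, not an error.
#'
#' @param sequence nucleotide string to search in.
#' @param motif nucleotide motif (shorter than \code{sequence}).
#' @param max_mismatch_fraction mismatch budget as a fraction of motif
#'   length.
#' @return \code{NULL} if no acceptable placement exists, else a list with
#'   \code{start}, \code{end} (0-based half-open interval on
#'   \code{sequence}) and \code{mismatches}.
#' @examples
#' find_anchor("TTACGTTT", "ACGT", 0)       # span [2, 6), 0 mismatches
#' find_anchor("GGGGGG", "ACGT", 0.25)      # NULL
#' @export
find_anchor <- function(sequence, motif, max_mismatch_fraction = 0.10) {
  sequence <- assert_sequence(sequence)
  motif <- assert_sequence(motif, "motif")
  n <- nchar(sequence); m <- nchar(motif)
  if (m >= n) {
    if (m > n) return(NULL)
  }
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  mo <- strsplit(motif, "", fixed = TRUE)[[1]]
  compat <- iupac_compat_matrix()
  n_place <- n - m + 1L
  mm <- integer(n_place)
  for (k in seq_len(m)) {
    mm <- mm + !compat[mo[k], s[k:(k + n_place - 1L)]]
  }
  mm <- unname(mm)
  ok <- which(mm / m <= max_mismatch_fraction)
  if (!length(ok)) return(NULL)
  best <- ok[which.min(mm[ok])]   # minimal mismatches, leftmost on ties
  list(start = best - 1L, end = best - 1L + m, mismatches = mm[best])
}

extract_on_strand <- function(sequence, ps) {
  fwd <- find_anchor(sequence, ps$forward, ps$max_mismatch_fraction)
  # The reverse primer reads 5'->3' on the opposite strand, so it appears
  # verbatim in the reverse complement of the template; searching there and
  # mapping back prefers the placement closest to the 3' end.
  rc <- revcomp(sequence)
  rev_rc <- find_anchor(rc, ps$reverse, ps$max_mismatch_fraction)
  if (is.null(fwd) || is.null(rev_rc)) return(NULL)
  n <- nchar(sequence)
  rev_span <- c(n - rev_rc$end, n - rev_rc$start)
  list(fwd = fwd, rev = list(start = rev_span[1], end = rev_span[2],
                             mismatches = rev_rc$mismatches))
}

#' Extract a barcode core from an amplicon using primer anchors
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the input; if either is absent, retries on the reverse
#' complement of the input (reporting \code{strand = "reverse"}). The core
#' is the sequence strictly between the two anchors; primer sites are
#' excluded by convention.
#'
#' In strict mode (default) a sequence with no usable anchors raises an
#' error of class \code{seedbarcode_extraction_failure}, signalling that
#' the sample should be treated as unsequenced downstream. In permissive
#' mode an anchor-free input whose length falls inside the marker's
#' expected core range is passed through unchanged, flagged with
#' \code{status = "passthrough"}.
#'
#' @param sequence nucleotide string (amplicon or consensus).
#' @param ps a \code{\link{primer_set}}.
#' @param strict logical; see Details.
#' @return list of class \code{extraction_result}: \code{core},
#'   \code{fwd_span}, \code{rev_span} (0-based half-open, on the reported
#'   strand), \code{strand} (\code{"forward"}/\code{"reverse"}),
#'   \code{fwd_mismatches}, \code{rev_mismatches}, \code{status}
#'   (\code{"extracted"} or \code{"passthrough"}).
#' @export
extract_marker <- function(sequence, ps, strict = TRUE) {
  stopifnot(inherits(ps, "primer_set"))
  sequence <- assert_sequence(sequence)

  for (strand in c("forward", "reverse")) {
    seq_s <- if (strand == "forward") sequence else revcomp(sequence)
    hit <- extract_on_strand(seq_s, ps)
    if (!is.null(hit)) {
      if (hit$fwd$end > hit$rev$start) {
        stop("primer anchors found in inverted order (forward at [",
             hit$fwd$start, ",", hit$fwd$end, "), reverse at [",
             hit$rev$start, ",", hit$rev$end, "))", call. = FALSE)
      }
      core <- substr(seq_s, hit$fwd$end + 1L, hit$rev$start)
      return(structure(
        list(core = core,
             fwd_span = c(hit$fwd$start, hit$fwd$end),
             rev_span = c(hit$rev$start, hit$rev$end),
             strand = strand,
             fwd_mismatches = hit$fwd$mismatches,
             rev_mismatches = hit$rev$mismatches,
             status = "extracted"),
        class = "extraction_result"))
    }
  }

  if (!strict) {
    rng <- marker_length_range(ps$marker)
    if (nchar(sequence) >= rng[1] && nchar(sequence) <= rng[2]) {
      return(structure(
        list(core = sequence, fwd_span = NULL, rev_span = NULL,
             strand = "forward", fwd_mismatches = NA_integer_,
             rev_mismatches = NA_integer_, status = "passthrough"),
        class = "extraction_result"))
    }
  }
  stop(structure(
    class = c("seedbarcode_extraction_failure", "error", "condition"),
    list(message = paste0("no ", ps$marker,
                          " primer anchors found on either strand"),
         call = NULL)))
}

#' Extract barcode cores for a batch of sequences
#'
#' Applies \code{\link{extract_marker}} to each sequence, trying primer
#' sets in the given order; the first marker whose anchors are found wins.
#'
#' @param sequences named character vector (names are sample ids).
#' @param primer_sets list of \code{\link{primer_set}} objects in priority
#'   order (default \code{\link{default_primers}()}).
#' @param strict passed to \code{\link{extract_marker}}.
#' @return data frame: \code{sample_id}, \code{marker}, \code{strand},
#'   \code{fwd_start}, \code{fwd_end}, \code{rev_start}, \code{rev_end},
#'   \code{fwd_mismatches}, \code{rev_mismatches}, \code{status}
#'   (\code{extracted}/\code{passthrough}/\code{failed}), \code{core}.
#' @export
extract_batch <- function(sequences, primer_sets = default_primers(),
                          strict = TRUE) {
  stopifnot(length(sequences) == 0 || !is.null(names(sequences)))
  rows <- lapply(seq_along(sequences), function(i) {
    id <- names(sequences)[i]
    for (ps in primer_sets) {
      res <- tryCatch(extract_marker(sequences[[i]], ps, strict = strict),
                      seedbarcode_extraction_failure = function(e) NULL)
      if (!is.null(res)) {
        return(data.frame(
          sample_id = id, marker = ps$marker, strand = res$strand,
          fwd_start = if (is.null(res$fwd_span)) NA_integer_ else res$fwd_span[1],
          fwd_end = if (is.null(res$fwd_span)) NA_integer_ else res$fwd_span[2],
          rev_start = if (is.null(res$rev_span)) NA_integer_ else res$rev_span[1],
          rev_end = if (is.null(res$rev_span)) NA_integer_ else res$rev_span[2],
          fwd_mismatches = res$fwd_mismatches,
          rev_mismatches = res$rev_mismatches,
          status = res$status, core = res$core,
          stringsAsFactors = FALSE))
      }
    }
    data.frame(sample_id = id, marker = NA_character_, strand = NA_character_,
               fwd_start = NA_integer_, fwd_end = NA_integer_,
               rev_start = NA_integer_, rev_end = NA_integer_,
               fwd_mismatches = NA_integer_, rev_mismatches = NA_integer_,
               status = "failed", core = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
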