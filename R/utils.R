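# Internal helpers shared across modules.

# IUPAC nucleotide codes and the base sets they denote.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

#' @noRd
is_nucleotide_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[ACGTRYSWKMBDHVN]*$", x)
}

#' @noRd
assert_sequence <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (!allow_empty && nchar(x) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  if (!grepl("^[ACGTRYSWKMBDHVN]*$", x)) {
    stop(what, " contains non-IUPAC characters", call. = FALSE)
  }
  x
}

# Round half away from zero (survey percentages are reported as e.g.
# 77.25%, identities to 1 d.p.); base round() is half-to-even.
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented to the code denoting the
#' complementary base set (e.g. R -> Y, N -> N).
#'
#' @param x single nucleotide string (IUPAC alphabet).
#' @return the reverse complement, upper case.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  x <- assert_sequence(x, allow_empty = TRUE)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Species-name normalization for matching: collapse whitespace, strip
# author citations, keep genus + epithet and any var./subsp./f. epithet,
# compare case-insensitively. "Prunus armeniaca L. var. ansu Maxim." and
# "prunus armeniaca var. ansu" normalize identically.
#' @noRd
normalize_species <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    s <- gsub("\\([^)]*\\)", " ", s)          # parenthesised authors
    s <- gsub("\\s+", " ", trimws(s))
    if (s == "") return("")
    words <- strsplit(s, " ", fixed = TRUE)[[1]]
    out <- words[seq_len(min(2L, length(words)))]
    rank <- match(c("var.", "subsp.", "ssp.", "f."), words)
    rank <- rank[!is.na(rank)]
    if (length(rank)) {
      i <- rank[1]
      if (i < length(words)) out <- c(out, words[i], words[i + 1L])
    }
    tolower(paste(out, collapse = " "))
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
valid_markers <- function() c("ITS2", "psbA-trnH")

#' @noRd
assert_marker <- function(marker) {
  if (!is.character(marker) || length(marker) != 1L ||
      !(marker %in% valid_markers())) {
    stop("marker must be one of: ", paste(valid_markers(), collapse = ", "),
         call. = FALSE)
  }
  marker
}

# Atomic text write: write to a temp file in the same directory, then rename.
#' @noRd
atomic_write <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}
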