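# The authentication decision procedure: per-sample five-way verdict from
# identity search against the reference library, and survey aggregation.

VERDICT_CATEGORIES <- c("authentic", "mislabeled", "completely_undetermined",
                        "partially_undetermined", "amplification_failure")

#' Decision configuration for sample authentication
#'
#' @param identity_threshold minimum percent identity of the top match for
#'   a species-level identification (default 98; comparison is inclusive,
#'   \code{>=}, on the identity rounded to 1 decimal place).
#' @param tie_margin hits within this many identity points of the best hit
#'   are treated as tied top species (default 0: ties only at exactly
#'   equal rounded identity).
#' @param marker_priority markers tried in order; the first marker with
#'   references in the library is used, later ones are fallbacks (default
#'   ITS2 core marker, psbA-trnH supplementary).
#' @param subthreshold_as_unknown if \code{TRUE}, a best hit below the
#'   threshold yields \code{completely_undetermined} instead of the
#'   default \code{mislabeled} (the default follows the practice of
#'   treating sub-threshold products as mislabeled).
#' @param adulterant_match_in_multiorigin how to file a confident match to
#'   a non-accepted species when the declared drug is multi-origin:
#'   \code{"mislabeled"} (default, the strict cascade reading) or
#'   \code{"partially_undetermined"} (the lenient reading that emphasises
#'   genuine/false discriminability within the drug group).
#' @return object of class \code{decision_config}.
#' @export
decision_config <- function(identity_threshold = 98,
                            tie_margin = 0,
                            marker_priority = c("ITS2", "psbA-trnH"),
                            subthreshold_as_unknown = FALSE,
                            adulterant_match_in_multiorigin = c("mislabeled", "partially_undetermined")) {
  if (!(identity_threshold > 0 && identity_threshold <= 100)) {
    stop("identity_threshold must be in (0, 100]", call. = FALSE)
  }
  if (tie_margin < 0) stop("tie_margin must be >= 0", call. = FALSE)
  marker_priority <- vapply(marker_priority, assert_marker, character(1),
                            USE.NAMES = FALSE)
  structure(list(
    identity_threshold = identity_threshold,
    tie_margin = tie_margin,
    marker_priority = marker_priority,
    subthreshold_as_unknown = isTRUE(subthreshold_as_unknown),
    adulterant_match_in_multiorigin = match.arg(adulterant_match_in_multiorigin)
  ), class = "decision_config")
}

#' Classify one market sample against the reference library
#'
#' Implements the authentication decision cascade:
#' \enumerate{
#'   \item no usable sequence -> \code{amplification_failure};
#'   \item search the library marker by marker in priority order; the top
#'     species set is every species within \code{tie_margin} of the best
#'     identity;
#'   \item best identity below the threshold -> \code{mislabeled}
#'     (sub-threshold rule; configurable);
#'   \item top set inside the declared drug's accepted species: a single
#'     species -> \code{authentic}; several accepted species that cannot
#'     be resolved among themselves -> \code{partially_undetermined};
#'   \item top set mixing accepted and non-accepted species at the same
#'     identity -> \code{completely_undetermined};
#'   \item top set entirely outside the accepted species ->
#'     \code{mislabeled}.
#' }
#'
#' @param sample a \code{\link{barcode_record}} query, a bare nucleotide
#'   string, or \code{NA}/\code{NULL} for a failed amplification.
#' @param declared_drug drug name on the product label; must exist in the
#'   library's monographs.
#' @param library a \code{barcode_library}.
#' @param config a \code{\link{decision_config}}.
#' @param sample_id identifier for the verdict (defaults to the record id).
#' @return object of class \code{sample_verdict}: \code{sample_id},
#'   \code{declared_drug}, \code{category}, \code{top_species} (character
#'   vector), \code{top_identity}, \code{marker_used}, \code{evidence}.
#' @export
classify_sample <- function(sample, declared_drug, library,
                            config = decision_config(),
                            sample_id = NULL) {
  stopifnot(inherits(library, "barcode_library"), inherits(config, "decision_config"))
  mono <- library$monographs
  row <- match(declared_drug, mono$drug_name)
  if (is.na(row)) {
    stop("declared drug '", declared_drug, "' not found in the checklist",
         call. = FALSE)
  }
  accepted <- mono$accepted_species[[row]]
  accepted_norm <- normalize_species(accepted)
  multi_origin <- mono$multi_origin[row]

  if (is.null(sample_id)) {
    sample_id <- if (inherits(sample, "barcode_record")) sample$record_id else "sample"
  }

  no_seq <- is.null(sample) ||
    (is.atomic(sample) && length(sample) == 1L && is.na(sample)) ||
    (inherits(sample, "barcode_record") && nchar(sample$sequence) == 0L) ||
    (is.character(sample) && !inherits(sample, "barcode_record") && nchar(sample) == 0L)
  if (no_seq) {
    return(new_verdict(sample_id, declared_drug, "amplification_failure",
                       character(0), NA_real_, NA_character_,
                       "no usable sequence obtained"))
  }

  markers_present <- unique(library$records$marker[library$records$role == "SRM"])
  tried <- character(0)
  hits <- NULL
  marker_used <- NA_character_
  for (m in config$marker_priority) {
    if (!(m %in% markers_present)) {
      tried <- c(tried, paste0(m, ": no references"))
      next
    }
    h <- tryCatch(search_library(sample, library, marker = m),
                  error = function(e) NULL)
    if (!is.null(h) && nrow(h)) {
      hits <- h
      marker_used <- m
      break
    }
    tried <- c(tried, paste0(m, ": search failed"))
  }
  if (is.null(hits)) {
    stop("no marker in the priority list has searchable references (",
         paste(tried, collapse = "; "), ")", call. = FALSE)
  }

  best <- hits$identity[1]
  top <- hits[hits$identity >= best - config$tie_margin, , drop = FALSE]
  top_species <- sort(unique(top$species))
  top_norm <- normalize_species(top_species)
  in_accepted <- top_norm %in% accepted_norm

  evidence <- sprintf(
    "marker %s%s; best identity %.1f to %s",
    marker_used,
    if (length(tried)) paste0(" (fallback after ", paste(tried, collapse = "; "), ")") else "",
    best, paste(top_species, collapse = " / "))

  if (best < config$identity_threshold) {
    cat_out <- if (config$subthreshold_as_unknown) "completely_undetermined" else "mislabeled"
    return(new_verdict(sample_id, declared_drug, cat_out, top_species, best,
                       marker_used,
                       paste0(evidence, sprintf("; below %.1f%% threshold",
                                                config$identity_threshold))))
  }

  if (all(in_accepted)) {
    if (length(top_species) == 1L || !multi_origin) {
      category <- "authentic"
    } else {
      category <- "partially_undetermined"
      evidence <- paste0(evidence, "; tie across accepted species of a multi-origin drug")
    }
  } else if (any(in_accepted)) {
    category <- "completely_undetermined"
    evidence <- paste0(evidence, "; tie mixes accepted and non-accepted species")
  } else {
    category <- "mislabeled"
    if (multi_origin &&
        config$adulterant_match_in_multiorigin == "partially_undetermined") {
      category <- "partially_undetermined"
      evidence <- paste0(evidence,
                         "; confident match to non-accepted species filed as partially undetermined (config)")
    } else {
      evidence <- paste0(evidence, "; top match not an accepted species")
    }
  }
  new_verdict(sample_id, declared_drug, category, top_species, best,
              marker_used, evidence)
}

new_verdict <- function(sample_id, declared_drug, category, top_species,
                        top_identity, marker_used, evidence) {
  stopifnot(category %in% VERDICT_CATEGORIES)
  structure(list(sample_id = sample_id, declared_drug = declared_drug,
                 category = category, top_species = top_species,
                 top_identity = top_identity, marker_used = marker_used,
                 evidence = evidence),
            class = "sample_verdict")
}

#' @export
print.sample_verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s (declared %s): %s", x$sample_id,
              x$declared_drug, x$category))
  if (length(x$top_species)) {
    cat(sprintf(" [%s @ %.1f%%]", paste(x$top_species, collapse = "; "),
                x$top_identity))
  }
  cat("\n")
  invisible(x)
}

#' Aggregate sample verdicts into a survey summary
#'
#' Counts and percentages per category; percentages are
#' \code{100 * count / n} rounded half-up to 2 decimal places. The
#' headline four-way split merges the two undetermined categories.
#'
#' @param verdicts list of \code{sample_verdict} objects, or a character
#'   vector of category names.
#' @return object of class \code{survey_summary} with \code{n_total},
#'   \code{counts}, \code{percentages} (five-way) and \code{headline}
#'   (four-way counts and percentages).
#' @examples
#' v <- rep(c("authentic", "mislabeled", "completely_undetermined",
#'            "amplification_failure"), c(309, 30, 41, 20))
#' summarize_survey(v)
#' @export
summarize_survey <- function(verdicts) {
  if (is.list(verdicts)) {
    cats <- vapply(verdicts, function(v) {
      stopifnot(inherits(v, "sample_verdict"))
      v$category
    }, character(1))
  } else {
    cats <- as.character(verdicts)
  }
  if (!length(cats)) stop("no verdicts to summarize", call. = FALSE)
  bad <- setdiff(unique(cats), VERDICT_CATEGORIES)
  if (length(bad)) {
    stop("unknown verdict categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(cats)
  counts <- vapply(VERDICT_CATEGORIES, function(cc) sum(cats == cc), integer(1))
  pct <- round_half_up(100 * counts / n, 2)

  headline_counts <- c(
    authentic = counts[["authentic"]],
    mislabeled = counts[["mislabeled"]],
    undetermined = counts[["completely_undetermined"]] +
      counts[["partially_undetermined"]],
    amplification_failure = counts[["amplification_failure"]]
  )
  headline_pct <- round_half_up(100 * headline_counts / n, 2)

  structure(list(n_total = n, counts = counts, percentages = pct,
                 headline = list(counts = headline_counts,
                                 percentages = headline_pct)),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("<survey_summary> n =", x$n_total, "\n")
  for (cc in names(x$headline$counts)) {
    cat(sprintf("  %-22s %4d  (%.2f%%)\n", cc, x$headline$counts[[cc]],
                x$headline$percentages[[cc]]))
  }
  und <- x$counts[c("completely_undetermined", "partially_undetermined")]
  if (sum(und) > 0) {
    cat(sprintf("  (undetermined: %d completely, %d partially)\n",
                und[[1]], und[[2]]))
  }
  invisible(x)
}

#' Run the full survey authentication pipeline
#'
#' For every manifest row: samples flagged \code{no_amplification} are
#' filed as amplification failures without touching the sequence data;
#' sequenced samples have their barcode core extracted with the configured
#' primer sets (extraction failure also files the sample as an
#' amplification failure) and are then classified against the library.
#' Output is ordered by sample id.
#'
#' @param manifest data frame with columns \code{sample_id},
#'   \code{declared_drug}, \code{source_code}, \code{status}
#'   (\code{sequenced}/\code{no_amplification}), or the path of such a
#'   TSV.
#' @param sequences named character vector of amplicon sequences (names
#'   are sample ids), or the path of a FASTA whose headers are sample ids.
#' @param library a \code{barcode_library}.
#' @param config a \code{\link{decision_config}}.
#' @param primer_sets primer sets for core extraction, in marker priority
#'   order (default \code{\link{default_primers}()}).
#' @param strict_extraction strict (default) vs permissive pass-through
#'   for anchor-free sequences, see \code{\link{extract_marker}}.
#' @return list with \code{verdicts} (data frame, one row per sample) and
#'   \code{summary} (a \code{\link{summarize_survey}} result).
#' @export
survey_pipeline <- function(manifest, sequences, library,
                            config = decision_config(),
                            primer_sets = default_primers(),
                            strict_extraction = TRUE) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                                  colClasses = "character", quote = "")
  }
  need <- c("sample_id", "declared_drug", "status")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    ss <- Biostrings::readBStringSet(sequences)
    sequences <- stats::setNames(toupper(as.character(ss)), names(ss))
  }

  sequenced <- manifest$sample_id[manifest$status == "sequenced"]
  orphans_m <- setdiff(sequenced, names(sequences))
  orphans_f <- setdiff(names(sequences), manifest$sample_id)
  if (length(orphans_m) || length(orphans_f)) {
    stop("manifest/FASTA id mismatch; missing sequences: [",
         paste(orphans_m, collapse = ", "), "]; unclaimed sequences: [",
         paste(orphans_f, collapse = ", "), "]", call. = FALSE)
  }

  manifest <- manifest[order(manifest$sample_id), , drop = FALSE]
  verdicts <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    drug <- manifest$declared_drug[i]
    if (manifest$status[i] != "sequenced") {
      verdicts[[i]] <- classify_sample(NULL, drug, library, config,
                                       sample_id = sid)
      next
    }
    amplicon <- sequences[[sid]]
    core <- NULL
    marker <- NULL
    for (ps in primer_sets) {
      res <- tryCatch(extract_marker(amplicon, ps, strict = strict_extraction),
                      seedbarcode_extraction_failure = function(e) NULL)
      if (!is.null(res)) {
        core <- res$core
        marker <- ps$marker
        break
      }
    }
    if (is.null(core) || !nzchar(core)) {
      v <- classify_sample(NULL, drug, library, config, sample_id = sid)
      v$evidence <- "marker extraction failed: no primer anchors found"
      verdicts[[i]] <- v
      next
    }
    cfg <- config
    # extraction fixes the marker; search that marker first
    cfg$marker_priority <- unique(c(marker, config$marker_priority))
    verdicts[[i]] <- classify_sample(
      barcode_record(sid, NA_character_, marker, core, role = "query"),
      drug, library, cfg, sample_id = sid)
  }

  vdf <- do.call(rbind, lapply(verdicts, function(v) {
    data.frame(sample_id = v$sample_id, declared_drug = v$declared_drug,
               category = v$category,
               top_species = paste(v$top_species, collapse = ";"),
               top_identity = v$top_identity,
               marker_used = v$marker_used, evidence = v$evidence,
               stringsAsFactors = FALSE)
  }))
  list(verdicts = vdf, summary = summarize_survey(vdf$category))
}

#' Write survey pipeline outputs
#'
#' @param result a \code{\link{survey_pipeline}} result.
#' @param verdict_path TSV output path for per-sample verdicts.
#' @param summary_path JSON output path for the survey summary (five-way
#'   and headline four-way splits).
#' @return invisibly, the two paths.
#' @export
write_survey_results <- function(result, verdict_path, summary_path) {
  v <- result$verdicts
  lines <- c(paste(names(v), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(vapply(v[i, ], as.character, character(1)), collapse = "\t")
             }, character(1)))
  atomic_write(lines, verdict_path)
  s <- result$summary
  json <- jsonlite::toJSON(list(
    n_total = s$n_total,
    five_way = list(counts = as.list(s$counts),
                    percentages = as.list(s$percentages)),
    headline = list(counts = as.list(s$headline$counts),
                    percentages = as.list(s$headline$percentages))
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  atomic_write(as.character(json), summary_path)
  invisible(c(verdict_path, summary_path))
}
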