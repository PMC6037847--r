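# Synthetic reference libraries and market surveys with known ground
# truth, so the full authentication pipeline is testable without any
# sequence downloads.

marker_sim_defaults <- function(marker) {
  switch(marker,
         "ITS2" = list(length_mean = 220, length_sd = 20,
                       length_range = c(190L, 280L), gc_target = 61),
         "psbA-trnH" = list(length_mean = 328, length_sd = 45,
                            length_range = c(262L, 520L), gc_target = 24))
}

#' Specification of a simulated reference library
#'
#' Defaults emulate the scale and sequence statistics of a pharmacopoeia
#' seed-drug reference collection: 51 drugs drawn from 64 species (40
#' single-origin drugs, 9 with two accepted species, 2 with three), 3
#' voucher records per species (192 SRM records), ITS2-like length and GC
#' moments (mean 220 bp in 190-280, mean 61% GC), one known adulterant
#' species per drug, three "indistinguishable" multi-origin drugs whose
#' accepted congeners carry identical barcodes, and one "confusable" drug
#' whose adulterant is sequence-identical to its accepted species.
#'
#' @param marker \code{"ITS2"} or \code{"psbA-trnH"}; sets length/GC
#'   defaults.
#' @param n_drugs number of drugs.
#' @param species_per_drug integer vector (length \code{n_drugs}) of
#'   accepted-species counts; default derives the 40/9/2 pattern
#'   proportionally.
#' @param n_adulterants_per_drug adulterant species per drug (default 1).
#' @param n_records_per_species SRM records per accepted species (default
#'   3; adulterant species get one record each).
#' @param length_mean,length_sd,length_range per-species core length is
#'   drawn from a normal truncated to \code{length_range} (bp).
#' @param gc_target root-sequence GC percent (exact composition).
#' @param inter_species_divergence,intra_species_divergence expected
#'   substitutions/site separating species (and drug clades) and records
#'   within a species. Intra must be well below inter; the defaults (0.08
#'   vs 0.002) put conspecific identity near 99.6\% and congeneric
#'   identity near 85\%, far on either side of the 98\% rule.
#' @param ti_tv_ratio expected transition:transversion count ratio kappa
#'   (default 2, a typical nuclear ribosomal value).
#' @param n_indistinguishable number of multi-origin drugs whose accepted
#'   species are generated with zero divergence (identical barcodes);
#'   default 3, capped at the number of multi-origin drugs.
#' @param n_confusable number of drugs whose adulterant is generated with
#'   zero divergence from the accepted species; default 1, capped at the
#'   number of single-origin drugs.
#' @param n_toxic number of drugs flagged toxic in the checklist.
#' @return object of class \code{library_sim_spec}.
#' @export
library_sim_spec <- function(marker = "ITS2",
                             n_drugs = 51,
                             species_per_drug = NULL,
                             n_adulterants_per_drug = 1,
                             n_records_per_species = 3,
                             length_mean = NULL, length_sd = NULL,
                             length_range = NULL, gc_target = NULL,
                             inter_species_divergence = 0.08,
                             intra_species_divergence = 0.002,
                             ti_tv_ratio = 2,
                             n_indistinguishable = NULL,
                             n_confusable = NULL,
                             n_toxic = 9) {
  marker <- assert_marker(marker)
  md <- marker_sim_defaults(marker)
  if (is.null(length_mean)) length_mean <- md$length_mean
  if (is.null(length_sd)) length_sd <- md$length_sd
  if (is.null(length_range)) length_range <- md$length_range
  if (is.null(gc_target)) gc_target <- md$gc_target
  if (is.null(species_per_drug)) {
    n2 <- max(1L, round(n_drugs * 9 / 51))
    n3 <- max(1L, round(n_drugs * 2 / 51))
    n1 <- n_drugs - n2 - n3
    if (n1 < 0) stop("n_drugs too small for the default species pattern",
                     call. = FALSE)
    species_per_drug <- c(rep(1L, n1), rep(2L, n2), rep(3L, n3))
  }
  if (length(species_per_drug) != n_drugs) {
    stop("species_per_drug must have length n_drugs", call. = FALSE)
  }
  if (is.null(n_indistinguishable)) {
    n_indistinguishable <- min(3L, sum(species_per_drug > 1L))
  }
  if (is.null(n_confusable)) {
    n_confusable <- min(1L, sum(species_per_drug == 1L))
  }
  if (!(intra_species_divergence < inter_species_divergence)) {
    stop("intra-species divergence must be < inter-species divergence",
         call. = FALSE)
  }
  if (!(gc_target > 0 && gc_target < 100)) {
    stop("gc_target must be in (0, 100)", call. = FALSE)
  }
  if (ti_tv_ratio <= 0) stop("ti_tv_ratio must be > 0", call. = FALSE)
  if (n_indistinguishable > sum(species_per_drug > 1L)) {
    stop("not enough multi-origin drugs for n_indistinguishable",
         call. = FALSE)
  }
  if (n_confusable > 0 && n_adulterants_per_drug < 1) {
    stop("confusable drugs need at least one adulterant per drug",
         call. = FALSE)
  }
  if (n_confusable > sum(species_per_drug == 1L)) {
    stop("not enough single-origin drugs for n_confusable", call. = FALSE)
  }
  structure(list(
    marker = marker, n_drugs = n_drugs, species_per_drug = species_per_drug,
    n_adulterants_per_drug = n_adulterants_per_drug,
    n_records_per_species = n_records_per_species,
    length_mean = length_mean, length_sd = length_sd,
    length_range = as.integer(length_range), gc_target = gc_target,
    inter_species_divergence = inter_species_divergence,
    intra_species_divergence = intra_species_divergence,
    ti_tv_ratio = ti_tv_ratio,
    n_indistinguishable = n_indistinguishable,
    n_confusable = n_confusable, n_toxic = n_toxic
  ), class = "library_sim_spec")
}

# Substitution probability matrix over branch length t (expected
# substitutions/site) for a transition/transversion process with
# stationary frequencies pi4 (HKY). kappa is calibrated as the expected
# transition:transversion COUNT ratio at uniform composition, i.e. the
# transition rate multiplier is 2*kappa. Computed by symmetrized eigen
# decomposition of the 4x4 rate matrix.
sub_prob_matrix <- function(t, kappa, pi4) {
  bases <- c("A", "C", "G", "T")
  stopifnot(length(pi4) == 4, all(pi4 > 0))
  pi4 <- pi4 / sum(pi4)
  names(pi4) <- bases
  is_ti <- matrix(FALSE, 4, 4, dimnames = list(bases, bases))
  is_ti["A", "G"] <- is_ti["G", "A"] <- TRUE
  is_ti["C", "T"] <- is_ti["T", "C"] <- TRUE
  Q <- matrix(rep(pi4, each = 4), 4, 4, dimnames = list(bases, bases))
  Q[is_ti] <- Q[is_ti] * 2 * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi4 * diag(Q))   # mean substitution rate; rescale to 1
  Q <- Q / mu
  d_half <- sqrt(pi4)
  S <- outer(d_half, 1 / d_half) * Q   # similar symmetric matrix
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  P <- outer(1 / d_half, d_half) *
    (eig$vectors %*% diag(exp(eig$values * t)) %*% t(eig$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve a sequence under a composition-preserving K2P-style process
#'
#' Each unambiguous site substitutes independently under a
#' transition/transversion rate process whose stationary frequencies are
#' the ancestor's own base composition, so composition is preserved (an
#' AT-rich spacer stays AT-rich). At uniform composition the process
#' reduces exactly to Kimura's two-parameter model, and the expected K2P
#' distance between ancestor and descendant approximates
#' \code{branch_length}. After sampling, a handful of compensating
#' transitions restores the ancestor's exact G+C count, emulating the
#' compositional constraint real spacers evolve under; the compensation
#' amounts to a few percent of the substitutions and leaves the
#' transition:transversion and distance calibrations intact. Gap and
#' ambiguity characters are left untouched. Draws come from R's global
#' RNG; wrap calls in \code{set.seed} for reproducibility (the
#' \code{simulate_*} drivers do).
#'
#' @param ancestor nucleotide string.
#' @param branch_length expected substitutions per site (>= 0).
#' @param kappa expected transition:transversion count ratio (default 2).
#' @return the descendant sequence (same length).
#' @export
evolve_sequence <- function(ancestor, branch_length, kappa = 2) {
  if (branch_length < 0) stop("branch_length must be >= 0", call. = FALSE)
  if (branch_length == 0) return(ancestor)
  chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  gc_before <- sum(chars %in% c("G", "C"))
  counts <- vapply(bases, function(b) sum(chars == b), numeric(1))
  pi4 <- (counts + 0.5) / sum(counts + 2)   # pseudocount guards zeros
  P <- sub_prob_matrix(branch_length, kappa, pi4)
  for (b in bases) {
    idx <- which(chars == b)
    if (!length(idx)) next
    chars[idx] <- sample(bases, length(idx), replace = TRUE, prob = P[b, ])
  }
  # restore the exact G+C count with compensating transitions
  delta <- sum(chars %in% c("G", "C")) - gc_before
  if (delta > 0) {
    pool <- which(chars %in% c("G", "C"))
    flip <- if (length(pool) > delta) sample(pool, delta) else pool
    chars[flip] <- c(G = "A", C = "T")[chars[flip]]
  } else if (delta < 0) {
    pool <- which(chars %in% c("A", "T"))
    flip <- if (length(pool) > -delta) sample(pool, -delta) else pool
    chars[flip] <- c(A = "G", T = "C")[chars[flip]]
  }
  paste(chars, collapse = "")
}

# Block-wise evolution for deep internal branches of the simulator: the
# sequence is evolved in windows so the exact-GC compensation acts
# locally, keeping every prefix of the descendant near the ancestral
# composition (per-species cores are prefixes of drug-ancestor
# sequences). Not exported: the local compensation inflates the realized
# transition count noticeably, which is harmless for clade structure but
# would distort the calibration contracts of evolve_sequence.
evolve_blockwise <- function(ancestor, branch_length, kappa, block = 60L) {
  n <- nchar(ancestor)
  if (branch_length == 0 || n <= block) {
    return(evolve_sequence(ancestor, branch_length, kappa))
  }
  starts <- seq(1L, n, by = block)
  paste(vapply(starts, function(s) {
    evolve_sequence(substr(ancestor, s, min(s + block - 1L, n)),
                    branch_length, kappa)
  }, character(1)), collapse = "")
}

# Root sequence with the target GC placed by error diffusion over short
# blocks: every prefix carries the target composition to within one base,
# so per-species 3' truncation cannot shift composition.
random_root <- function(length, gc_target, block = 25L) {
  chars <- character(length)
  placed <- 0L
  starts <- seq(1L, length, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, length)
    want <- round(e * gc_target / 100) - placed
    want <- max(0L, min(e - s + 1L, want))
    idx <- s:e
    gc_pos <- if (want > 0) sample(idx, want) else integer(0)
    at_pos <- setdiff(idx, gc_pos)
    chars[gc_pos] <- sample(c("G", "C"), length(gc_pos), replace = TRUE)
    chars[at_pos] <- sample(c("A", "T"), length(at_pos), replace = TRUE)
    placed <- placed + want
  }
  paste(chars, collapse = "")
}

trunc_norm_int <- function(n, mean, sd, range) {
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      x <- round(stats::rnorm(1, mean, sd))
      if (x >= range[1] && x <= range[2]) break
    }
    out[i] <- x
  }
  out
}

#' Simulate a barcode reference library with known ground truth
#'
#' Species are generated on a star of drug clades: every drug ancestor
#' sits \code{inter_species_divergence} from the root, accepted species
#' and the adulterant species of a drug sit another
#' \code{inter_species_divergence} below their drug ancestor, and voucher
#' records scatter around their species sequence at
#' \code{intra_species_divergence}. "Indistinguishable" multi-origin drugs
#' and the adulterants of "confusable" drugs are generated at zero
#' divergence (identical barcodes, the situation that produces exact
#' identity ties downstream). Per-species core lengths come from the
#' truncated normal; a species' records share its length (indistinguishable
#' and confusable drug groups share one length so their ties stay exact).
#'
#' @param spec a \code{\link{library_sim_spec}}.
#' @param seed integer seed; all randomness derives from it.
#' @return object of class \code{simulated_library}: \code{library} (a
#'   \code{barcode_library}), \code{truth} (list with \code{drugs} and
#'   \code{species} tables carrying the planted structure and core
#'   sequences), \code{tree} (the generating \code{phylo} tree over record
#'   ids), \code{spec}, \code{seed}.
#' @export
simulate_library <- function(spec, seed) {
  stopifnot(inherits(spec, "library_sim_spec"))
  with_seed(seed, simulate_library_impl(spec, seed))
}

simulate_library_impl <- function(spec, seed) {
  L <- spec$length_range[2]
  kappa <- spec$ti_tv_ratio
  inter <- spec$inter_species_divergence
  intra <- spec$intra_species_divergence
  root <- random_root(L, spec$gc_target)

  n_drugs <- spec$n_drugs
  multi <- which(spec$species_per_drug > 1L)
  single <- which(spec$species_per_drug == 1L)
  indis <- utils::tail(multi, spec$n_indistinguishable)
  conf <- utils::head(single, spec$n_confusable)

  drug_names <- sprintf("Drug%02d", seq_len(n_drugs))
  genus <- sprintf("Genus%02d", seq_len(n_drugs))
  epithets <- c("alpha", "beta", "gamma", "delta", "epsilon")

  drugs <- data.frame(
    drug_name = drug_names, genus = genus,
    n_species = spec$species_per_drug,
    type = ifelse(seq_len(n_drugs) %in% indis, "indistinguishable",
                  ifelse(seq_len(n_drugs) %in% conf, "confusable",
                         "resolvable")),
    toxic = seq_len(n_drugs) <= spec$n_toxic,
    stringsAsFactors = FALSE)

  sp_rows <- list()
  rec_rows <- list()
  drug_frags <- character(n_drugs)

  for (d in seq_len(n_drugs)) {
    # block-wise evolution keeps every prefix of the drug ancestor at the
    # root composition (species cores are prefixes of it)
    anc <- evolve_blockwise(root, inter, kappa)
    dtype <- drugs$type[d]
    group_len <- if (dtype %in% c("indistinguishable", "confusable")) {
      trunc_norm_int(1, spec$length_mean, spec$length_sd, spec$length_range)
    } else NA_integer_
    sp_frags <- character(0)

    emit_species <- function(sp_name, divergence, record_div, n_records,
                             is_adulterant) {
      len <- if (is.na(group_len)) {
        trunc_norm_int(1, spec$length_mean, spec$length_sd, spec$length_range)
      } else group_len
      # truncate first, then evolve: species and record sequences keep the
      # exact composition of their own core ancestor
      core_anc <- substr(anc, 1L, len)
      core <- if (divergence > 0) {
        evolve_sequence(core_anc, divergence, kappa)
      } else core_anc
      recs <- lapply(seq_len(n_records), function(r) {
        seq_r <- if (record_div > 0) {
          evolve_sequence(core, record_div, kappa)
        } else core
        id <- sprintf("SRM-%s-%d", gsub(" ", "_", sp_name), r)
        data.frame(record_id = id, species = sp_name, marker = spec$marker,
                   drug = if (is_adulterant) NA_character_ else drug_names[d],
                   sequence = seq_r, role = "SRM", stringsAsFactors = FALSE)
      })
      frag <- paste0("(", paste0(vapply(recs, function(x) x$record_id, character(1)),
                                 ":", format(record_div, scientific = FALSE),
                                 collapse = ","), "):",
                     format(divergence, scientific = FALSE))
      list(
        sp = data.frame(species = sp_name, drug = drug_names[d],
                        is_adulterant = is_adulterant, core = core,
                        drug_type = dtype, stringsAsFactors = FALSE),
        recs = do.call(rbind, recs), frag = frag)
    }

    for (k in seq_len(spec$species_per_drug[d])) {
      sp_name <- paste(genus[d], epithets[k])
      # confusable drugs: accepted species and adulterant coincide at the
      # drug ancestor, so confident hits tie across the accepted and the
      # non-accepted name
      div <- if (dtype %in% c("indistinguishable", "confusable")) 0 else inter
      rdiv <- if (dtype %in% c("indistinguishable", "confusable")) 0 else intra
      res <- emit_species(sp_name, div, rdiv, spec$n_records_per_species, FALSE)
      sp_rows[[length(sp_rows) + 1L]] <- res$sp
      rec_rows[[length(rec_rows) + 1L]] <- res$recs
      sp_frags <- c(sp_frags, res$frag)
    }
    for (k in seq_len(spec$n_adulterants_per_drug)) {
      sp_name <- paste(genus[d], if (spec$n_adulterants_per_drug == 1L)
        "spurium" else paste0("spurium", k))
      div <- if (dtype == "confusable") 0 else inter
      res <- emit_species(sp_name, div, 0, 1L, TRUE)
      sp_rows[[length(sp_rows) + 1L]] <- res$sp
      rec_rows[[length(rec_rows) + 1L]] <- res$recs
      sp_frags <- c(sp_frags, res$frag)
    }
    drug_frags[d] <- paste0("(", paste(sp_frags, collapse = ","), "):",
                            format(inter, scientific = FALSE))
  }

  species <- do.call(rbind, sp_rows)
  records <- do.call(rbind, rec_rows)
  rownames(species) <- rownames(records) <- NULL

  mono <- data.frame(drug_name = drug_names, stringsAsFactors = FALSE)
  mono$accepted_species <- lapply(seq_len(n_drugs), function(d) {
    species$species[species$drug == drug_names[d] & !species$is_adulterant]
  })
  mono$known_adulterants <- lapply(seq_len(n_drugs), function(d) {
    species$species[species$drug == drug_names[d] & species$is_adulterant]
  })
  mono$toxic <- drugs$toxic

  lib <- barcode_library(records, mono)
  tree <- ape::read.tree(
    text = paste0("(", paste(drug_frags, collapse = ","), ");"))

  structure(list(library = lib,
                 truth = list(drugs = drugs, species = species),
                 tree = tree, spec = spec, seed = seed),
            class = "simulated_library")
}

#' @export
print.simulated_library <- function(x, ...) {
  cat("<simulated_library> seed", x$seed, "\n")
  print(x$library)
  cat("  drug types:",
      paste(names(table(x$truth$drugs$type)), table(x$truth$drugs$type),
            collapse = ", ", sep = ":"), "\n")
  invisible(x)
}

#' Specification of a simulated market survey
#'
#' Defaults plant the canonical 400-sample composition: 309 authentic, 30
#' mislabeled, 41 undetermined (34 completely + 7 partially) and 20
#' amplification failures.
#'
#' @param n_authentic,n_mislabeled,n_undetermined,n_failure planted
#'   four-way counts.
#' @param n_completely how many of the undetermined samples are planted as
#'   completely undetermined (default scales the 34:7 split).
#' @param noise per-sample sequencing noise, substitutions/site (default
#'   0.001).
#' @return object of class \code{survey_sim_spec}; \code{n_samples} is the
#'   sum of the four counts.
#' @export
survey_sim_spec <- function(n_authentic = 309, n_mislabeled = 30,
                            n_undetermined = 41, n_failure = 20,
                            n_completely = NULL, noise = 0.001) {
  if (is.null(n_completely)) {
    n_completely <- round(n_undetermined * 34 / 41)
  }
  if (n_completely > n_undetermined) {
    stop("n_completely cannot exceed n_undetermined", call. = FALSE)
  }
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  structure(list(
    n_samples = n_authentic + n_mislabeled + n_undetermined + n_failure,
    n_authentic = n_authentic, n_mislabeled = n_mislabeled,
    n_undetermined = n_undetermined, n_completely = n_completely,
    n_partially = n_undetermined - n_completely,
    n_failure = n_failure, noise = noise
  ), class = "survey_sim_spec")
}

#' Simulate a market survey against a simulated library
#'
#' Authentic samples are noisy copies of an accepted species of a
#' resolvable drug; mislabeled samples are noisy copies of a declared
#' drug's adulterant; partially undetermined samples come from
#' indistinguishable multi-origin drugs; completely undetermined samples
#' from confusable drugs; failures are emitted as
#' \code{status = no_amplification}. Every sequenced sample is emitted as
#' a full amplicon: forward primer + core + reverse-complemented reverse
#' primer, so the pipeline's extraction step is exercised.
#'
#' @param sim a \code{\link{simulate_library}} result.
#' @param spec a \code{\link{survey_sim_spec}}.
#' @param seed integer seed.
#' @return object of class \code{simulated_survey}: \code{manifest} (data
#'   frame: sample_id, declared_drug, source_code, status),
#'   \code{sequences} (named character vector of amplicons), \code{truth}
#'   (data frame: sample_id, planted_category, true_species), \code{spec},
#'   \code{seed}.
#' @export
simulate_survey <- function(sim, spec, seed) {
  stopifnot(inherits(sim, "simulated_library"), inherits(spec, "survey_sim_spec"))
  with_seed(seed, simulate_survey_impl(sim, spec, seed))
}

simulate_survey_impl <- function(sim, spec, seed) {
  truth <- sim$truth
  lib_spec <- sim$spec
  kappa <- lib_spec$ti_tv_ratio
  ps <- default_primers()[[lib_spec$marker]]
  rc_rev <- revcomp(ps$reverse)

  drugs <- truth$drugs
  resolvable <- drugs$drug_name[drugs$type == "resolvable"]
  indis <- drugs$drug_name[drugs$type == "indistinguishable"]
  conf <- drugs$drug_name[drugs$type == "confusable"]
  has_adulterant <- vapply(drugs$drug_name, function(d) {
    any(truth$species$drug == d & truth$species$is_adulterant)
  }, logical(1))
  mislabel_pool <- intersect(resolvable, drugs$drug_name[has_adulterant])

  need <- c(authentic = spec$n_authentic, mislabeled = spec$n_mislabeled,
            completely_undetermined = spec$n_completely,
            partially_undetermined = spec$n_partially,
            amplification_failure = spec$n_failure)
  if (need[["authentic"]] > 0 && !length(resolvable)) {
    stop("cannot plant authentic samples: library has no resolvable drugs",
         call. = FALSE)
  }
  if (need[["mislabeled"]] > 0 && !length(mislabel_pool)) {
    stop("cannot plant mislabeled samples: no resolvable drug has a ",
         "diverged adulterant species", call. = FALSE)
  }
  if (need[["partially_undetermined"]] > 0 && !length(indis)) {
    stop("cannot plant partially undetermined samples: library has no ",
         "indistinguishable multi-origin drug", call. = FALSE)
  }
  if (need[["completely_undetermined"]] > 0 && !length(conf)) {
    stop("cannot plant completely undetermined samples: library has no ",
         "confusable drug", call. = FALSE)
  }

  categories <- sample(rep(names(need), need))
  n <- length(categories)
  ids <- sprintf("S%0*d", nchar(n), seq_len(n))
  sources <- sample(c("ZH", "HH", "YS"), n, replace = TRUE)

  pick_core <- function(drug, adulterant) {
    sp <- truth$species[truth$species$drug == drug &
                          truth$species$is_adulterant == adulterant, ,
                        drop = FALSE]
    i <- if (nrow(sp) == 1L) 1L else sample.int(nrow(sp), 1L)
    list(species = sp$species[i], core = sp$core[i])
  }

  manifest <- data.frame(sample_id = ids, declared_drug = NA_character_,
                         source_code = sources, status = "sequenced",
                         stringsAsFactors = FALSE)
  truth_out <- data.frame(sample_id = ids, planted_category = categories,
                          true_species = NA_character_,
                          stringsAsFactors = FALSE)
  sequences <- character(0)

  for (i in seq_len(n)) {
    cat_i <- categories[i]
    if (cat_i == "amplification_failure") {
      manifest$declared_drug[i] <- sample(drugs$drug_name, 1L)
      manifest$status[i] <- "no_amplification"
      next
    }
    drug <- switch(cat_i,
      authentic = sample(resolvable, 1L),
      mislabeled = sample(mislabel_pool, 1L),
      partially_undetermined = sample(indis, 1L),
      completely_undetermined = sample(conf, 1L))
    src <- pick_core(drug, adulterant = (cat_i == "mislabeled"))
    manifest$declared_drug[i] <- drug
    truth_out$true_species[i] <- src$species
    core <- if (spec$noise > 0) {
      evolve_sequence(src$core, spec$noise, kappa)
    } else src$core
    sequences[[ids[i]]] <- paste0(ps$forward, core, rc_rev)
  }

  structure(list(manifest = manifest, sequences = sequences,
                 truth = truth_out, spec = spec, seed = seed),
            class = "simulated_survey")
}

#' Write a simulated library to disk
#'
#' Emits \code{reference.fasta}, \code{checklist.tsv},
#' \code{true_tree.nwk} and \code{sim_spec.json} into \code{dir}.
#'
#' @param sim a \code{\link{simulate_library}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_library <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "reference.fasta"),
             checklist = file.path(dir, "checklist.tsv"),
             tree = file.path(dir, "true_tree.nwk"),
             spec = file.path(dir, "sim_spec.json"))
  write_barcode_library(sim$library, paths[["fasta"]], paths[["checklist"]])
  write_tree_newick(sim$tree, paths[["tree"]])
  spec_json <- jsonlite::toJSON(c(unclass(sim$spec), list(seed = sim$seed)),
                                auto_unbox = TRUE, digits = NA, pretty = TRUE)
  atomic_write(as.character(spec_json), paths[["spec"]])
  invisible(paths)
}

#' Write a simulated survey to disk
#'
#' Emits \code{manifest.tsv}, \code{survey.fasta} and
#' \code{ground_truth.tsv} into \code{dir}.
#'
#' @param survey a \code{\link{simulate_survey}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "simulated_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             fasta = file.path(dir, "survey.fasta"),
             truth = file.path(dir, "ground_truth.tsv"))
  m <- survey$manifest
  atomic_write(c(paste(names(m), collapse = "\t"),
                 vapply(seq_len(nrow(m)), function(i)
                   paste(as.character(m[i, ]), collapse = "\t"), character(1))),
               paths[["manifest"]])
  atomic_write(as.vector(rbind(paste0(">", names(survey$sequences)),
                               unname(survey$sequences))),
               paths[["fasta"]])
  t <- survey$truth
  atomic_write(c(paste(names(t), collapse = "\t"),
                 vapply(seq_len(nrow(t)), function(i)
                   paste(as.character(t[i, ]), collapse = "\t"), character(1))),
               paths[["truth"]])
  invisible(paths)
}
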