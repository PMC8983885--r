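# Query-anchored homology coverage. Hit-table intervals on the query are
# merged into a coverage profile; overlap with annotated domains then
# classifies the query-genome relationship as full-length homology,
# PH-domain-restricted, coiled-coil/C-terminal-restricted, other-partial,
# or absent.

#' Merged coverage profile of one query against one genome
#'
#' Converts hit intervals on the query (1-based inclusive, as in BLAST
#' tabular output) to 0-based half-open, merges overlapping or adjacent
#' intervals, and records the best (smallest) E-value.
#'
#' @param hits Data.frame of outfmt-6 rows for one query-genome pair
#'   (may be empty); all rows must share `query_id`.
#' @param query_length Query length in residues.
#' @param subject_genome Optional genome/database tag for reports.
#' @return Object of class `coverage_profile`: list with `query_id`,
#'   `subject_genome`, `covered` (matrix of disjoint sorted intervals,
#'   0-based half-open), `best_evalue`, `coverage_fraction`.
#' @export
coverage_profile <- function(hits, query_length,
                             subject_genome = NA_character_) {
  stopifnot(query_length > 0)
  if (nrow(hits) == 0L) {
    return(structure(list(query_id = NA_character_,
                          subject_genome = subject_genome,
                          covered = matrix(integer(0), 0, 2,
                                           dimnames = list(NULL, c("start", "end"))),
                          best_evalue = NA_real_, coverage_fraction = 0),
                     class = "coverage_profile"))
  }
  qid <- unique(hits$query_id)
  if (length(qid) != 1L) stop("hits span multiple query ids")
  if (any(hits$qend > query_length))
    stop("hit interval exceeds query length (", query_length, ")")
  iv <- cbind(start = hits$qstart - 1L, end = hits$qend)  # to half-open
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[i, 1] <= merged[last, 2]) {        # overlapping or adjacent
      merged[last, 2] <- max(merged[last, 2], iv[i, 2])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  covered_len <- sum(merged[, 2] - merged[, 1])
  structure(list(query_id = qid, subject_genome = subject_genome,
                 covered = merged, best_evalue = min(hits$evalue),
                 coverage_fraction = covered_len / query_length),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile", x$query_id, "vs", x$subject_genome, ":",
      sprintf("%.1f%%", 100 * x$coverage_fraction), "covered, best E =",
      format(x$best_evalue), "\n")
  invisible(x)
}

# total length of `covered` falling inside any of `domain_iv` (both 0-based
# half-open interval matrices)
.overlap_length <- function(covered, domain_iv) {
  if (nrow(covered) == 0L || nrow(domain_iv) == 0L) return(0L)
  total <- 0L
  for (i in seq_len(nrow(covered))) for (j in seq_len(nrow(domain_iv))) {
    total <- total + max(0L, min(covered[i, 2], domain_iv[j, 2]) -
                             max(covered[i, 1], domain_iv[j, 1]))
  }
  total
}

#' Classify a query-genome homology relationship
#'
#' `none` when there are no hits or the best E-value exceeds
#' `evalue_max`; `full_length` when the coverage fraction exceeds
#' `cov_min`; otherwise `PH_only` when at least `domain_frac` of the
#' covered length lies inside the PH domain, `CC_or_Cterm_only` when it
#' lies inside the coiled-coil/C-terminal region, else `partial_other`.
#'
#' @param profile A [coverage_profile()].
#' @param domains Data.frame with columns `name` (`PH, WW, CC, PRO,
#'   CTERM, other`), `start`, `end` (0-based half-open query residue
#'   coordinates).
#' @param cov_min Full-length coverage threshold (default 0.60).
#' @param evalue_max Homology E-value ceiling (default 1e-20).
#' @param domain_frac Fraction of covered length that must fall inside a
#'   domain for a domain-restricted label (default 0.80).
#' @return One of `"full_length", "PH_only", "CC_or_Cterm_only",
#'   "partial_other", "none"`.
#' @export
classify_homology <- function(profile, domains, cov_min = 0.60,
                              evalue_max = 1e-20, domain_frac = 0.80) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (nrow(profile$covered) == 0L || is.na(profile$best_evalue) ||
      profile$best_evalue > evalue_max)
    return("none")
  if (profile$coverage_fraction > cov_min) return("full_length")
  covered_len <- sum(profile$covered[, 2] - profile$covered[, 1])
  dom_iv <- function(names) {
    sel <- domains$name %in% names
    cbind(domains$start[sel], domains$end[sel])
  }
  ph <- dom_iv("PH")
  if (nrow(ph) == 0L) stop("missing PH domain annotation for query '",
                           profile$query_id, "'")
  if (.overlap_length(profile$covered, ph) >= domain_frac * covered_len)
    return("PH_only")
  cc <- dom_iv(c("CC", "CTERM"))
  if (nrow(cc) > 0L &&
      .overlap_length(profile$covered, cc) >= domain_frac * covered_len)
    return("CC_or_Cterm_only")
  "partial_other"
}

#' Classify every query-genome pair of a hit table
#'
#' Convenience wrapper: groups hits by query and subject genome, builds
#' the [coverage_profile()], and applies [classify_homology()].
#'
#' @param hits Outfmt-6 data.frame (see [read_hit_table()]); the subject
#'   genome of a hit is taken from `genome_of[subject_id]` when given,
#'   else from `subject_id` itself.
#' @param domains Data.frame `query_id, name, start, end` (0-based
#'   half-open).
#' @param query_lengths Named vector of query lengths.
#' @param genome_of Optional named vector mapping subject ids to genomes.
#' @inheritParams classify_homology
#' @return Data.frame `query_id, subject_genome, label,
#'   coverage_fraction, best_evalue`.
#' @export
classify_hit_table <- function(hits, domains, query_lengths,
                               genome_of = NULL, cov_min = 0.60,
                               evalue_max = 1e-20, domain_frac = 0.80) {
  genome <- if (is.null(genome_of)) hits$subject_id
            else unname(genome_of[hits$subject_id])
  key <- paste(hits$query_id, genome, sep = "\r")
  out <- lapply(unique(key), function(kk) {
    sel <- key == kk
    qid <- hits$query_id[sel][1]
    gen <- genome[sel][1]
    if (!qid %in% names(query_lengths))
      stop("no query length for '", qid, "'")
    prof <- coverage_profile(hits[sel, , drop = FALSE],
                             query_lengths[[qid]], subject_genome = gen)
    dom <- domains[domains$query_id == qid, , drop = FALSE]
    data.frame(query_id = qid, subject_genome = gen,
               label = classify_homology(prof, dom, cov_min, evalue_max,
                                         domain_frac),
               coverage_fraction = prof$coverage_fraction,
               best_evalue = prof$best_evalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write homology classifications as TSV
#'
#' @param classes Data.frame from [classify_hit_table()].
#' @param path Output path (header line starts `#`).
#' @export
write_classification_tsv <- function(classes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("query_id", "subject_genome", "label", "coverage_fraction",
            "best_evalue")
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  write.table(classes[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
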