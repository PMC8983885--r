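# BLAST tabular (outfmt 6) hit tables: 12 tab-separated columns in the
# standard order. Lines starting '#' are comments. Parsed with per-line
# validation so malformed rows are reported by line number.

.outfmt6_cols <- c("query_id", "subject_id", "pct_identity", "length",
                   "mismatch", "gapopen", "qstart", "qend", "sstart",
                   "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' @param path Path to a 12-column tab-separated file; `#`-prefixed lines
#'   are skipped.
#' @return A data.frame with the standard outfmt-6 columns
#'   (`query_id, subject_id, pct_identity, length, mismatch, gapopen,
#'   qstart, qend, sstart, send, evalue, bitscore`), rows in file order.
#'   Alignment coordinates are kept 1-based inclusive as in the format.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), .outfmt6_cols))
    return(.coerce_hit_cols(out, path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop("expected 12 tab-separated columns but found ", nf[i],
         " at line ", lineno[i], " of ", path)
  }
  m <- do.call(rbind, fields)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .outfmt6_cols
  out <- .coerce_hit_cols(out, path, lineno)
  validate_hit_table(out)
  out
}

.coerce_hit_cols <- function(out, path, lineno = integer(0)) {
  num_cols <- c("pct_identity", "evalue", "bitscore")
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")
  for (col in c(num_cols, int_cols)) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v) && nrow(out) > 0L) {
      i <- which(is.na(v))[1]
      where <- if (length(lineno)) paste0(" at line ", lineno[i]) else ""
      stop("unparsable ", col, " value '", out[[col]][i], "'", where,
           " of ", path)
    }
    out[[col]] <- if (col %in% int_cols) as.integer(v) else v
  }
  out
}

validate_hit_table <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$qstart > hits$qend)) stop("hit with qstart > qend")
  if (any(hits$evalue < 0)) stop("hit with negative evalue")
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop("pct_identity outside [0, 100]")
  invisible(hits)
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' @param hits A data.frame as returned by [read_hit_table()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(.outfmt6_cols %in% names(hits)))
  write.table(hits[, .outfmt6_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
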