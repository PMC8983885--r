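# Protein multiple sequence alignments and the projection of intron
# positions into shared column coordinates. Alignments are consumed, not
# produced: aligned FASTA is the carrier, '-' the only gap character
# ('.' is normalized to '-' on input by read_fasta()).

#' Construct a protein alignment
#'
#' @param seqs Named character vector of equal-length gapped protein
#'   sequences, or a [read_fasta()] table.
#' @return An object of class `protein_alignment`: list with `seqs`
#'   (named character vector) and `n_cols`.
#' @export
alignment <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seq_vector(seqs)
  stopifnot(is.character(seqs), length(seqs) > 0L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate row id: '", names(seqs)[duplicated(names(seqs))][1], "'")
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L)
    stop("alignment rows differ in length")
  structure(list(seqs = seqs, n_cols = widths[1]),
            class = "protein_alignment")
}

as_alignment <- function(x) {
  if (inherits(x, "protein_alignment")) x else alignment(x)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", length(x$seqs), "rows x", x$n_cols, "columns\n")
  invisible(x)
}

# character matrix view (rows x columns)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

#' Map an ungapped residue index to its alignment column
#'
#' @param row Gapped sequence string.
#' @param residue_index 0-based index (or vector of indices) into the
#'   ungapped sequence.
#' @return 0-based alignment column(s) holding the residue(s).
#' @export
residue_to_column <- function(row, residue_index) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  if (any(residue_index < 0L) || any(residue_index >= length(nongap)))
    stop("residue_index out of range (ungapped length ", length(nongap), ")")
  as.integer(nongap[residue_index + 1L] - 1L)
}

#' Project intron records into alignment column coordinates
#'
#' Each intron is anchored to the alignment column holding its
#' `protein_anchor` residue in that gene's row.
#'
#' @param aln A [alignment()] (rows keyed by gene id).
#' @param introns Data.frame with columns `gene_id`, `protein_anchor`,
#'   `phase` (as from [extract_introns()]).
#' @return Data.frame with columns `row_id`, `msa_column` (0-based),
#'   `phase`.
#' @export
project_introns <- function(aln, introns) {
  aln <- as_alignment(aln)
  if (nrow(introns) == 0L)
    return(data.frame(row_id = character(0), msa_column = integer(0),
                      phase = integer(0)))
  missing_rows <- setdiff(unique(introns$gene_id), names(aln$seqs))
  if (length(missing_rows))
    stop("intron for a row absent from the alignment: '",
         missing_rows[1], "'")
  cols <- integer(nrow(introns))
  for (id in unique(introns$gene_id)) {
    sel <- introns$gene_id == id
    cols[sel] <- residue_to_column(aln$seqs[[id]],
                                   introns$protein_anchor[sel])
  }
  data.frame(row_id = introns$gene_id, msa_column = cols,
             phase = as.integer(introns$phase))
}

#' Intron position/phase conservation across alignment rows
#'
#' Groups projected introns by alignment column. A column carried by at
#' least two rows with one common phase is a shared site; a column whose
#' carriers disagree in phase is a phase-conflict site; single-carrier
#' columns are singletons.
#'
#' @param map Data.frame from [project_introns()].
#' @return An object of class `intron_conservation`: list with `columns`
#'   (one row per intron-bearing column: `msa_column, n_carriers, phases,
#'   carriers, status`), and the subsets `shared` and `conflicts`.
#' @export
intron_conservation <- function(map) {
  if (nrow(map) == 0L) stop("empty intron map")
  if (anyDuplicated(map[, c("row_id", "msa_column")]))
    stop("a row carries the same column twice")
  cols <- sort(unique(map$msa_column))
  rows <- lapply(cols, function(cl) {
    sub <- map[map$msa_column == cl, , drop = FALSE]
    phases <- sort(unique(sub$phase))
    status <- if (nrow(sub) == 1L) "singleton"
              else if (length(phases) == 1L) "shared" else "conflict"
    data.frame(msa_column = cl, n_carriers = nrow(sub),
               phases = paste(phases, collapse = ","),
               carriers = paste(sort(sub$row_id), collapse = ","),
               status = status, stringsAsFactors = FALSE)
  })
  columns <- do.call(rbind, rows)
  structure(list(columns = columns,
                 shared = columns[columns$status == "shared", , drop = FALSE],
                 conflicts = columns[columns$status == "conflict", , drop = FALSE]),
            class = "intron_conservation")
}

#' @export
print.intron_conservation <- function(x, ...) {
  cat("intron_conservation:", nrow(x$columns), "intron-bearing columns (",
      nrow(x$shared), "shared,", nrow(x$conflicts), "phase conflicts )\n")
  invisible(x)
}

#' Write an intron-conservation report as TSV
#'
#' @param cons An [intron_conservation()] result.
#' @param path Output path (header line starts `#`).
#' @export
write_conservation_tsv <- function(cons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("msa_column", "n_carriers", "phases", "carriers", "status")
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  write.table(cons$columns[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Complete deletion of gapped/missing alignment columns
#'
#' Removes every column in which any row has a gap (`-`) or missing data
#' (`X`, `?`), the treatment applied before distance computation.
#'
#' @param aln A [alignment()].
#' @return The column-filtered `protein_alignment`; attribute `columns`
#'   gives the retained 0-based column indices. Warns (and returns an
#'   empty alignment) when nothing survives.
#' @export
complete_deletion <- function(aln) {
  aln <- as_alignment(aln)
  m <- alignment_matrix(aln)
  bad <- apply(m, 2L, function(col) any(col %in% c("-", "X", "?")))
  keep <- which(!bad)
  if (length(keep) == 0L) {
    warning("complete deletion removed every column")
    out <- structure(list(seqs = setNames(rep("", nrow(m)), rownames(m)),
                          n_cols = 0L), class = "protein_alignment")
  } else {
    seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    out <- alignment(setNames(seqs, rownames(m)))
  }
  attr(out, "columns") <- keep - 1L
  out
}

#' Filter alignment rows by their share of gap characters
#'
#' With `mode = "msa_share"` (default) a row is dropped when its gap
#' characters exceed `threshold` as a fraction of all gap characters in
#' the alignment; `mode = "row_fraction"` instead drops rows whose own
#' gap fraction (gaps / columns) exceeds `threshold`.
#'
#' @param aln A [alignment()].
#' @param threshold Fraction in (0, 1]; default 0.20.
#' @param mode `"msa_share"` or `"row_fraction"`.
#' @return Character vector of retained row ids.
#' @export
gap_fraction_filter <- function(aln, threshold = 0.20,
                                mode = c("msa_share", "row_fraction")) {
  aln <- as_alignment(aln)
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  gaps <- vapply(strsplit(aln$seqs, "", fixed = TRUE),
                 function(ch) sum(ch == "-"), 0L)
  share <- if (mode == "msa_share") {
    total <- sum(gaps)
    if (total == 0L) rep(0, length(gaps)) else gaps / total
  } else {
    gaps / aln$n_cols
  }
  names(aln$seqs)[share <= threshold]
}

#' Per-column information content in bits
#'
#' Sequence-logo information: `log2(20)` minus the Shannon entropy of the
#' residue frequencies in the column (maximum 4.32 bits for a fully
#' conserved column). Gap and missing-data characters (`-`, `X`, `?`) are
#' excluded from the counts. With `small_sample_correction`, the
#' approximate correction `19 / (2 ln(2) n)` is subtracted.
#'
#' @param column Character vector of single residues, or one string.
#' @param small_sample_correction Apply the small-sample correction?
#' @return Information content in bits.
#' @export
column_information_bits <- function(column, small_sample_correction = FALSE) {
  if (length(column) == 1L && nchar(column) > 1L)
    column <- strsplit(column, "", fixed = TRUE)[[1]]
  column <- toupper(column)
  column <- column[!(column %in% c("-", "X", "?", "*"))]
  if (length(column) == 0L) stop("column has no scorable residues")
  if (!all(column %in% AA_ALPHABET))
    stop("non-standard residue in column")
  p <- table(column) / length(column)
  h <- -sum(p * log2(p))
  bits <- log2(20) - h
  if (small_sample_correction)
    bits <- bits - 19 / (2 * log(2) * length(column))
  bits
}

#' Information content for every alignment column
#'
#' @param aln A [alignment()].
#' @param small_sample_correction Passed to [column_information_bits()].
#' @return Numeric vector of per-column bits (`NA` for columns with no
#'   scorable residues).
#' @export
alignment_information <- function(aln, small_sample_correction = FALSE) {
  aln <- as_alignment(aln)
  m <- alignment_matrix(aln)
  apply(m, 2L, function(col) {
    if (all(col %in% c("-", "X", "?", "*"))) return(NA_real_)
    column_information_bits(col, small_sample_correction)
  })
}

#' Write a filtered alignment to aligned FASTA
#'
#' @param aln A [alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  write_fasta(aln$seqs, path)
}
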