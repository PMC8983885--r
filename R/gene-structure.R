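# Gene models and exon-intron architecture. A GeneModel holds the ordered
# coding exons of one protein-coding gene (0-based half-open genomic
# intervals, transcription order), its CDS (including the stop codon) and
# the translated protein. Intron phases follow the modulo-of-exon-lengths
# rule: the phase is the cumulative coding length preceding the intron,
# modulo 3 (0 = intron falls between codons; 1/2 = codon split after the
# first/second codon position).

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Translate a CDS (including its stop codon) to protein
#'
#' @param cds Nucleotide string; length must be a multiple of 3 and the
#'   last codon must be a stop.
#' @return Amino-acid string of length `nchar(cds)/3 - 1`.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  if (substr(aa, nchar(aa), nchar(aa)) != "*")
    stop("CDS does not end in a stop codon")
  substr(aa, 1L, nchar(aa) - 1L)
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param seqid Chromosome/contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`, `end`: coding exon
#'   intervals, 0-based half-open, in transcription order (ascending
#'   genomic coordinates on `"+"`, descending on `"-"`).
#' @param cds_seq CDS nucleotide string including the stop codon; derived
#'   from `genome_seq` when omitted.
#' @param genome_seq Optional sequence of `seqid` from which to extract the
#'   CDS (exon substrings, reverse-complemented on `"-"`).
#' @return An object of class `gene_model` with fields `gene_id`, `seqid`,
#'   `strand`, `exons`, `cds_seq`, `protein_seq`.
#' @export
gene_model <- function(gene_id, seqid, strand, exons, cds_seq = NULL,
                       genome_seq = NULL) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2L)
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  if (any(exons[, 1] >= exons[, 2])) stop("empty or inverted exon interval")
  gene_model_check_order(exons, strand)
  if (is.null(cds_seq)) {
    if (is.null(genome_seq)) stop("need cds_seq or genome_seq")
    parts <- substring(genome_seq, exons[, 1] + 1L, exons[, 2])
    if (strand == "-") parts <- vapply(parts, revcomp, "")
    cds_seq <- paste(parts, collapse = "")
  }
  cds_seq <- toupper(cds_seq)
  if (sum(exons[, 2] - exons[, 1]) != nchar(cds_seq))
    stop("exon lengths do not sum to CDS length")
  model <- structure(list(gene_id = gene_id, seqid = seqid, strand = strand,
                          exons = exons, cds_seq = cds_seq,
                          protein_seq = translate_cds(cds_seq)),
                     class = "gene_model")
  model
}

gene_model_check_order <- function(exons, strand) {
  n <- nrow(exons)
  if (n > 1L) {
    genomic <- exons[order(exons[, 1]), , drop = FALSE]
    if (any(genomic[-n, 2] > genomic[-1, 1])) stop("overlapping exons")
    ok <- if (strand == "+") all(diff(exons[, 1]) > 0)
          else all(diff(exons[, 1]) < 0)
    if (!ok) stop("exons not in transcription order for strand ", strand)
  }
  invisible(TRUE)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "(", x$seqid, x$strand, ")\n")
  cat("  ", nrow(x$exons), "coding exon(s),", nchar(x$cds_seq), "nt CDS,",
      nchar(x$protein_seq), "aa\n")
  invisible(x)
}

#' Intron phase from the coding offset of the splice point
#'
#' The phase is `cds_offset %% 3`: 0 when the intron falls between codons,
#' 1 or 2 when it splits a codon after its first or second position.
#'
#' @param cds_offset Positive integer(s): nucleotides of CDS preceding the
#'   intron.
#' @return Integer phase(s) in `{0, 1, 2}`.
#' @export
compute_intron_phase <- function(cds_offset) {
  if (any(cds_offset <= 0))
    stop("cds_offset must be positive (intron inside the coding region)")
  as.integer(cds_offset %% 3L)
}

#' Extract intron records from a gene model
#'
#' One record per inter-exon gap, in transcription order. The
#' `protein_anchor` is `floor(cds_offset / 3)`: the 0-based index of the
#' residue whose codon contains the splice point (for phase 0, the residue
#' immediately 3' of it).
#'
#' @param model A [gene_model()].
#' @return A data.frame with columns `gene_id, index, cds_offset, phase,
#'   protein_anchor, genomic_start, genomic_end` (empty for single-exon
#'   genes).
#' @export
extract_introns <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  gene_model_check_order(model$exons, model$strand)
  n <- nrow(model$exons)
  if (n < 2L)
    return(data.frame(gene_id = character(0), index = integer(0),
                      cds_offset = integer(0), phase = integer(0),
                      protein_anchor = integer(0), genomic_start = integer(0),
                      genomic_end = integer(0)))
  lens <- model$exons[, 2] - model$exons[, 1]
  offs <- cumsum(lens)[-n]
  if (model$strand == "+") {
    gs <- model$exons[-n, 2]
    ge <- model$exons[-1, 1]
  } else {
    gs <- model$exons[-1, 2]
    ge <- model$exons[-n, 1]
  }
  data.frame(gene_id = model$gene_id, index = seq_len(n - 1L) - 1L,
             cds_offset = as.integer(offs),
             phase = compute_intron_phase(offs),
             protein_anchor = as.integer(offs %/% 3L),
             genomic_start = as.integer(gs), genomic_end = as.integer(ge))
}

#' Gene models from an annotation table plus genome sequences
#'
#' Groups CDS features by transcript and builds one [gene_model()] per
#' transcript.
#'
#' @param ann An [annotation_table()].
#' @param genome Named character vector of chromosome sequences (or a
#'   [read_fasta()] table).
#' @return Named list of [gene_model()] objects keyed by gene id.
#' @export
gene_models_from_gff3 <- function(ann, genome) {
  if (is.data.frame(genome)) genome <- seq_vector(genome)
  cds <- ann[ann$feature_type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(list())
  out <- list()
  for (tx in unique(cds$transcript_id)) {
    rows <- cds[cds$transcript_id == tx, , drop = FALSE]
    strand <- rows$strand[1]
    seqid <- rows$seqid[1]
    if (!seqid %in% names(genome))
      stop("no genome sequence for seqid '", seqid, "'")
    ord <- order(rows$start, decreasing = (strand == "-"))
    exons <- cbind(start = rows$start[ord], end = rows$end[ord])
    gid <- rows$gene_id[1]
    out[[gid]] <- gene_model(gid, seqid, strand, exons,
                             genome_seq = genome[[seqid]])
  }
  out
}

#' Spliced mapping of a CDS onto a genomic sequence
#'
#' Greedy left-to-right exact matching: the current exon is extended while
#' the genomic sequence matches the CDS; at a mismatch, candidate GT...AG
#' introns are searched so that matching resumes and the remaining CDS
#' suffix stays representable. Ties are broken deterministically: the
#' donor giving the longest current exon is preferred, then the shortest
#' intron (smallest acceptor coordinate).
#'
#' @param cds Nucleotide CDS string.
#' @param genomic Nucleotide genomic string (the `"+"`-strand slice
#'   containing the gene).
#' @return Integer matrix of exon intervals (`start`, `end`; 0-based
#'   half-open) whose concatenated substrings equal `cds`.
#' @export
spliced_map <- function(cds, genomic) {
  cds <- toupper(cds); genomic <- toupper(genomic)
  cc <- strsplit(cds, "", fixed = TRUE)[[1]]
  gc <- strsplit(genomic, "", fixed = TRUE)[[1]]
  nc <- length(cc); ng <- length(gc)
  if (nc == 0L) stop("empty CDS")
  failed <- new.env(parent = emptyenv())

  match_run <- function(ci, gi) {
    k <- 0L
    while (ci + k <= nc && gi + k <= ng && cc[ci + k] == gc[gi + k]) k <- k + 1L
    k
  }
  solve <- function(ci, gi) {
    key <- paste0(ci, "_", gi)
    if (!is.null(failed[[key]])) return(NULL)
    m <- match_run(ci, gi)
    if (ci + m - 1L == nc)            # CDS exhausted: final exon
      return(list(c(gi - 1L, gi + m - 1L)))
    if (m > 0L) {
      for (exon_len in seq(m, 1L)) {  # longest current exon first
        p <- gi + exon_len            # 1-based start of candidate intron
        if (p + 1L > ng || gc[p] != "G" || gc[p + 1L] != "T") next
        remaining <- nc - (ci + exon_len - 1L)
        qmax <- ng - remaining        # intron must leave room for the suffix
        q <- p + 3L                   # minimal GT..AG intron is 4 nt
        while (q <= qmax) {
          if (gc[q - 1L] == "A" && gc[q] == "G") {
            rest <- solve(ci + exon_len, q + 1L)
            if (!is.null(rest))
              return(c(list(c(gi - 1L, gi - 1L + exon_len)), rest))
          }
          q <- q + 1L
        }
      }
    }
    failed[[key]] <- TRUE
    NULL
  }
  res <- solve(1L, 1L)
  if (is.null(res)) {
    # allow the first exon to start downstream of position 1
    gi <- 2L
    while (is.null(res) && gi + (nc - 1L) <= ng) {
      if (gc[gi] == cc[1L]) res <- solve(1L, gi)
      gi <- gi + 1L
    }
  }
  if (is.null(res)) stop("unmappable CDS")
  out <- do.call(rbind, res)
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  out
}

#' Write / read an introns table as TSV
#'
#' The header line starts with `#`.
#' @param introns A data.frame from [extract_introns()] (rows from several
#'   genes may be concatenated).
#' @param path File path.
#' @export
write_introns_tsv <- function(introns, path) {
  cols <- c("gene_id", "index", "cds_offset", "phase", "protein_anchor",
            "genomic_start", "genomic_end")
  stopifnot(all(cols %in% names(introns)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  write.table(introns[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_introns_tsv
#' @export
read_introns_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  out <- read.table(path, sep = "\t", skip = 1L, col.names = cols,
                    stringsAsFactors = FALSE)
  out
}
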