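# GFF3 annotations. rtracklayer does the parsing/serialization; this layer
# converts between GFF3's 1-based inclusive coordinates and the package's
# internal 0-based half-open convention, resolves gene/transcript parentage,
# and flags RNA genes (which the synteny rules later exclude).

.rna_types <- c("tRNA", "rRNA", "ncRNA", "snRNA", "snoRNA", "miRNA",
                "lnc_RNA", "lincRNA", "scRNA")

#' Convert GFF3 coordinates to the internal convention
#'
#' GFF3 is 1-based inclusive; internally all intervals are 0-based
#' half-open.
#' @param start,end 1-based inclusive coordinates.
#' @return A list with `start` and `end` in 0-based half-open coordinates.
#' @export
coords_to_internal <- function(start, end) {
  stopifnot(all(start >= 1L), all(start <= end))
  list(start = start - 1L, end = end)
}

#' Convert internal coordinates to GFF3's convention
#'
#' @param start,end 0-based half-open coordinates.
#' @return A list with `start` and `end` 1-based inclusive.
#' @export
coords_to_gff <- function(start, end) {
  stopifnot(all(start >= 0L), all(start < end))
  list(start = start + 1L, end = end)
}

#' Build an annotation table
#'
#' The in-memory representation of genome annotations: one row per feature,
#' coordinates 0-based half-open.
#'
#' @param seqid,feature_type,start,end,strand,gene_id,transcript_id,name,biotype
#'   Per-feature vectors; `feature_type` in
#'   `gene, mRNA, CDS, exon, rna_gene`; `biotype` in
#'   `protein_coding, RNA`.
#' @return A data.frame of class `annotation_table`.
#' @export
annotation_table <- function(seqid, feature_type, start, end, strand,
                             gene_id, transcript_id = NA_character_,
                             name = gene_id, biotype = "protein_coding") {
  out <- data.frame(seqid = seqid, feature_type = feature_type,
                    start = as.integer(start), end = as.integer(end),
                    strand = strand, gene_id = gene_id,
                    transcript_id = transcript_id, name = name,
                    biotype = biotype, stringsAsFactors = FALSE)
  validate_annotation_table(out)
  class(out) <- c("annotation_table", "data.frame")
  out
}

validate_annotation_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (any(x$start < 0L) || any(x$start >= x$end))
    stop("invalid feature interval (need 0 <= start < end)")
  bad_ft <- setdiff(unique(x$feature_type),
                    c("gene", "mRNA", "CDS", "exon", "rna_gene"))
  if (length(bad_ft)) stop("unknown feature_type: ", bad_ft[1])
  needs_strand <- x$feature_type %in% c("gene", "CDS", "rna_gene")
  if (any(needs_strand & !(x$strand %in% c("+", "-"))))
    stop("strand must be '+' or '-' for gene/CDS features")
  invisible(x)
}

#' Read a GFF3 file into an annotation table
#'
#' Requires the `##gff-version 3` directive. Coordinates are converted to
#' the internal 0-based half-open convention. RNA genes (a non-coding
#' `biotype`/`gene_biotype` attribute, or a child transcript of an RNA
#' type) get `feature_type = "rna_gene"` and `biotype = "RNA"`.
#'
#' @param path Path to a GFF3 file.
#' @return An [annotation_table()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^##gff-version\\s+3", first))
    stop("missing '##gff-version 3' directive in ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 (", path, "): ",
                                          conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(mc))
    vapply(mc$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  else rep(NA_character_, length(gr))
  name <- if ("Name" %in% names(mc)) as.character(mc$Name) else rep(NA_character_, length(gr))
  bt_attr <- rep(NA_character_, length(gr))
  for (col in c("biotype", "gene_biotype")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      bt_attr[is.na(bt_attr) & !is.na(v)] <- v[is.na(bt_attr) & !is.na(v)]
    }
  }
  strand <- as.character(BiocGenerics::strand(gr))
  start1 <- BiocGenerics::start(gr)
  end1 <- BiocGenerics::end(gr)

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", .rna_types, "transcript")
  # map transcript id -> gene id for CDS/exon parent resolution
  tx2gene <- setNames(parent[is_tx], id[is_tx])
  gene_id <- ifelse(is_gene, id,
             ifelse(is_tx, parent,
                    unname(tx2gene[parent])))
  transcript_id <- ifelse(is_tx, id,
                   ifelse(type %in% c("CDS", "exon"), parent, NA_character_))
  # RNA-gene flag: explicit biotype, or any child transcript of an RNA type
  rna_gene_ids <- unique(c(id[is_gene & !is.na(bt_attr) &
                                !(bt_attr %in% "protein_coding")],
                           parent[type %in% .rna_types]))
  feature_type <- type
  feature_type[is_tx] <- "mRNA"
  feature_type[is_gene & id %in% rna_gene_ids] <- "rna_gene"
  keep <- feature_type %in% c("gene", "rna_gene", "mRNA", "CDS", "exon")
  biotype <- ifelse(gene_id %in% rna_gene_ids, "RNA", "protein_coding")

  cds <- feature_type == "CDS"
  if (any(cds & !(strand %in% c("+", "-"))))
    stop("CDS feature with undefined strand in ", path)

  out <- data.frame(seqid = as.character(GenomeInfoDb::seqnames(gr)),
                    feature_type = feature_type,
                    start = start1 - 1L, end = end1,
                    strand = strand, gene_id = gene_id,
                    transcript_id = transcript_id, name = name,
                    biotype = biotype, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$name <- ifelse(is.na(out$name), out$gene_id, out$name)
  validate_annotation_table(out)
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write an annotation table to GFF3
#'
#' Coordinates are converted back to 1-based inclusive; the
#' `##gff-version 3` directive is emitted.
#'
#' @param ann An [annotation_table()].
#' @param path Output path.
#' @export
write_gff3 <- function(ann, path) {
  validate_annotation_table(ann)
  type <- ifelse(ann$feature_type == "rna_gene", "gene", ann$feature_type)
  id <- ifelse(ann$feature_type %in% c("gene", "rna_gene"), ann$gene_id,
        ifelse(ann$feature_type == "mRNA", ann$transcript_id, NA_character_))
  parent <- ifelse(ann$feature_type == "mRNA", ann$gene_id,
            ifelse(ann$feature_type %in% c("CDS", "exon"),
                   ann$transcript_id, NA_character_))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seqid,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- id
  S4Vectors::mcols(gr)$Parent <- parent
  S4Vectors::mcols(gr)$Name <- ann$name
  S4Vectors::mcols(gr)$biotype <- ifelse(
    ann$feature_type %in% c("gene", "rna_gene"),
    ifelse(ann$biotype == "RNA", "ncRNA", "protein_coding"), NA_character_)
  # GFF3 CDS phase: bases to skip to the next codon boundary, accumulated
  # over the transcript's CDS segments in transcription order
  phase <- rep(NA_integer_, nrow(ann))
  cds_rows <- which(ann$feature_type == "CDS")
  for (tx in unique(ann$transcript_id[cds_rows])) {
    rows <- cds_rows[ann$transcript_id[cds_rows] %in% tx]
    minus <- ann$strand[rows[1]] == "-"
    rows <- rows[order(ann$start[rows], decreasing = minus)]
    lens <- ann$end[rows] - ann$start[rows]
    before <- cumsum(c(0L, lens))[seq_along(rows)]
    phase[rows] <- (3L - before %% 3L) %% 3L
  }
  S4Vectors::mcols(gr)$phase <- phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
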