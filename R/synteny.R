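# Genomic neighborhoods and conserved synteny blocks. A neighborhood is a
# focal protein-coding gene plus up to k protein-coding flankers per side
# within a distance window (RNA genes are skipped and do not count toward
# k). Neighborhood comparison is by family label: gene symbols normalized
# by stripping a paralog suffix, or an explicit user-provided map.

#' Extract the genomic neighborhood of a focal gene
#'
#' Walks outward from the focal gene's boundaries and collects up to `k`
#' protein-coding genes per side whose nearest boundary lies within
#' `window` bp. RNA genes are skipped and not counted toward `k`; genes
#' overlapping the focal gene are ignored. Distances are between nearest
#' gene boundaries, negative upstream and positive downstream.
#'
#' @param ann An [annotation_table()] (gene rows are used).
#' @param focal_gene_id Identifier of a protein-coding gene in `ann`.
#' @param k Maximum flankers per side (default 4).
#' @param window Maximum boundary-to-boundary distance in bp
#'   (default 500000).
#' @param species Optional species tag carried through to reports.
#' @param family_map Optional named character vector mapping gene symbols
#'   to family labels (see [assign_family()]).
#' @return An object of class `neighborhood`: list with `focal_gene_id`,
#'   `species`, `seqid`, and `flankers` (data.frame `gene_id,
#'   family_label, strand, distance, side`, sorted by |distance| within
#'   side).
#' @export
extract_neighborhood <- function(ann, focal_gene_id, k = 4L,
                                 window = 500000L, species = NA_character_,
                                 family_map = NULL) {
  genes <- ann[ann$feature_type %in% c("gene", "rna_gene"), , drop = FALSE]
  focal <- genes[genes$gene_id == focal_gene_id, , drop = FALSE]
  if (nrow(focal) == 0L) stop("focal gene not found: '", focal_gene_id, "'")
  if (focal$biotype[1] != "protein_coding")
    stop("focal gene '", focal_gene_id, "' is not protein-coding")
  focal <- focal[1, ]
  same <- genes[genes$seqid == focal$seqid &
                genes$gene_id != focal_gene_id, , drop = FALSE]
  up <- same[same$end <= focal$start, , drop = FALSE]
  down <- same[same$start >= focal$end, , drop = FALSE]

  take_side <- function(side_genes, side) {
    if (nrow(side_genes) == 0L)
      return(data.frame(gene_id = character(0), family_label = character(0),
                        strand = character(0), distance = integer(0),
                        side = character(0), stringsAsFactors = FALSE))
    gap <- if (side == "up") focal$start - side_genes$end
           else side_genes$start - focal$end
    ord <- order(gap)
    side_genes <- side_genes[ord, , drop = FALSE]
    gap <- gap[ord]
    keep <- gap <= window
    side_genes <- side_genes[keep, , drop = FALSE]
    gap <- gap[keep]
    coding <- side_genes$biotype == "protein_coding"   # RNA genes skipped
    side_genes <- side_genes[coding, , drop = FALSE]
    gap <- gap[coding]
    n <- min(nrow(side_genes), k)
    side_genes <- head(side_genes, n)
    gap <- head(gap, n)
    data.frame(gene_id = side_genes$gene_id,
               family_label = if (n) assign_family(side_genes$name, family_map)
                              else character(0),
               strand = side_genes$strand,
               distance = as.integer(if (side == "up") -gap else gap),
               side = rep(side, n), stringsAsFactors = FALSE)
  }
  flankers <- rbind(take_side(up, "up"), take_side(down, "down"))
  rownames(flankers) <- NULL
  structure(list(focal_gene_id = focal_gene_id, species = species,
                 seqid = focal$seqid, flankers = flankers),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat("neighborhood of", x$focal_gene_id, "on", x$seqid, ":",
      sum(x$flankers$side == "up"), "upstream /",
      sum(x$flankers$side == "down"), "downstream flankers\n")
  invisible(x)
}

#' Normalize gene symbols to family labels
#'
#' Default rule: uppercase the symbol and strip one paralog suffix -- a
#' single trailing letter when it follows a digit (`PIK3C2A -> PIK3C2`),
#' otherwise the trailing digit run (`SOX13 -> SOX`). Symbols present in
#' `family_map` take the mapped label instead.
#'
#' @param symbols Character vector of gene symbols.
#' @param family_map Optional named character vector (symbol -> family).
#' @return Character vector of family labels.
#' @export
assign_family <- function(symbols, family_map = NULL) {
  if (any(is.na(symbols) | !nzchar(symbols))) stop("empty gene symbol")
  up <- toupper(symbols)
  out <- ifelse(grepl("[0-9][A-Z]$", up), sub("[A-Z]$", "", up),
                sub("[0-9]+$", "", up))
  out[!nzchar(out)] <- up[!nzchar(out)]   # all-digit symbols keep themselves
  if (!is.null(family_map)) {
    mapped <- match(toupper(symbols), toupper(names(family_map)))
    hit <- !is.na(mapped)
    out[hit] <- unname(family_map[mapped[hit]])
  }
  out
}

#' Conserved synteny block between two neighborhoods
#'
#' Families present in both flanker sets (focal genes excluded) form the
#' shared block; the score is the Jaccard index of the two family-label
#' sets (1 when both neighborhoods are empty).
#'
#' @param nbhd_a,nbhd_b [extract_neighborhood()] results built with the
#'   same `k` and `window`.
#' @return An object of class `synteny_block`: list with `locus_a`,
#'   `locus_b`, `shared` (data.frame `family_label, gene_a, gene_b`,
#'   ordered by family label) and `score`.
#' @export
conserved_blocks <- function(nbhd_a, nbhd_b) {
  stopifnot(inherits(nbhd_a, "neighborhood"), inherits(nbhd_b, "neighborhood"))
  fam_a <- unique(nbhd_a$flankers$family_label)
  fam_b <- unique(nbhd_b$flankers$family_label)
  shared_fams <- sort(intersect(fam_a, fam_b))
  union_n <- length(union(fam_a, fam_b))
  score <- if (union_n == 0L) 1 else length(shared_fams) / union_n
  first_gene <- function(nb, fam)
    nb$flankers$gene_id[nb$flankers$family_label == fam][1]
  shared <- data.frame(
    family_label = shared_fams,
    gene_a = vapply(shared_fams, first_gene, "", nb = nbhd_a),
    gene_b = vapply(shared_fams, first_gene, "", nb = nbhd_b),
    stringsAsFactors = FALSE)
  rownames(shared) <- NULL
  structure(list(locus_a = nbhd_a$focal_gene_id,
                 locus_b = nbhd_b$focal_gene_id,
                 shared = shared, score = score),
            class = "synteny_block")
}

#' @export
print.synteny_block <- function(x, ...) {
  cat("synteny_block", x$locus_a, "vs", x$locus_b, ": score",
      format(x$score, digits = 4), "with", nrow(x$shared),
      "shared families\n")
  invisible(x)
}

#' Write neighborhoods / synteny blocks as TSV
#'
#' @param nbhds List of [extract_neighborhood()] results.
#' @param path Output path (header line starts `#`).
#' @export
write_neighborhoods_tsv <- function(nbhds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("focal_gene_id", "species", "seqid", "gene_id", "family_label",
            "strand", "distance", "side")
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  for (nb in nbhds) {
    if (nrow(nb$flankers) == 0L) next
    df <- cbind(focal_gene_id = nb$focal_gene_id, species = nb$species,
                seqid = nb$seqid, nb$flankers)
    write.table(df[, cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_neighborhoods_tsv
#' @param blocks List of [conserved_blocks()] results.
#' @export
write_blocks_tsv <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("locus_a", "locus_b", "score", "shared_families")
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  for (bl in blocks) {
    writeLines(paste(bl$locus_a, bl$locus_b,
                     sprintf("%.10g", bl$score),
                     paste(bl$shared$family_label, collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}
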