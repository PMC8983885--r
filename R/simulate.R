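# Ground-truthed simulator of a gene family descended from one ancestral
# gene through two rounds of duplication (the 1R/2R scenario): per-branch
# amino-acid substitution under the JTT model (optionally with
# discrete-Gamma site rates), intron loss/gain, lineage-specific gene
# loss, and decaying genomic neighborhoods. Every emitted artifact is
# paired with its generating truth so downstream stages can be scored
# exactly. Indels are not simulated, so the family's true alignment is the
# trivial positional one.

#' Simulation configuration for the two-round duplication scenario
#'
#' @param seed Integer seed driving all randomness.
#' @param protein_length Ancestor protein length in residues (default 300).
#' @param n_introns Ancestral intron count (default 8).
#' @param duplication_depths Branch lengths (substitutions/site) evolved
#'   after round-1 and round-2 duplication (defaults 0.4, 0.25).
#' @param terminal_depth Additional terminal branch length (default 0.15).
#' @param gamma_shape Optional Gamma shape for site-rate heterogeneity.
#' @param n_rate_categories Discrete-Gamma categories (default 5).
#' @param intron_loss_rate Per-branch probability that each intron is lost.
#' @param intron_gain_rate Per-branch expected number of gained introns
#'   (Poisson).
#' @param flankers_per_side Flanking genes per side of the focal locus
#'   (default 4).
#' @param neighbor_retention_p Probability that a flanking gene survives
#'   each duplication (default 0.7).
#' @param gene_loss Character vector of family members (`"m1"`..`"m4"`)
#'   lost in their lineage.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed, protein_length = 300L, n_introns = 8L,
                              duplication_depths = c(0.4, 0.25),
                              terminal_depth = 0.15, gamma_shape = NULL,
                              n_rate_categories = 5L,
                              intron_loss_rate = 0, intron_gain_rate = 0,
                              flankers_per_side = 4L,
                              neighbor_retention_p = 0.7,
                              gene_loss = character(0)) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            protein_length >= 10L, n_introns >= 0L,
            length(duplication_depths) == 2L, all(duplication_depths >= 0),
            terminal_depth >= 0,
            is.null(gamma_shape) || gamma_shape > 0,
            intron_loss_rate >= 0, intron_loss_rate <= 1,
            intron_gain_rate >= 0,
            flankers_per_side >= 0L,
            neighbor_retention_p >= 0, neighbor_retention_p <= 1,
            all(gene_loss %in% c("m1", "m2", "m3", "m4")))
  structure(list(seed = as.integer(seed),
                 protein_length = as.integer(protein_length),
                 n_introns = as.integer(n_introns),
                 duplication_depths = duplication_depths,
                 terminal_depth = terminal_depth,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 intron_loss_rate = intron_loss_rate,
                 intron_gain_rate = intron_gain_rate,
                 flankers_per_side = as.integer(flankers_per_side),
                 neighbor_retention_p = neighbor_retention_p,
                 gene_loss = gene_loss),
            class = "simulation_config")
}

#' Random protein at JTT equilibrium
#'
#' @param n Length in residues.
#' @return Protein string drawn i.i.d. from the JTT equilibrium
#'   frequencies (uses the current RNG state).
#' @export
random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = jtt_frequencies()),
        collapse = "")
}

#' Evolve a protein along a branch under the JTT model
#'
#' Each site substitutes according to `exp(Q r t)` with `Q` the JTT rate
#' matrix; with `gamma_shape` set, site rates `r` are drawn from the
#' discrete-Gamma categories. Length is preserved (no indels). Uses the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param seq Protein string (20 standard residues).
#' @param branch_length Branch length in substitutions/site.
#' @param gamma_shape Optional Gamma shape.
#' @param k Rate categories when `gamma_shape` is set.
#' @return The evolved protein string.
#' @export
evolve_sequence <- function(seq, branch_length, gamma_shape = NULL, k = 5L) {
  stopifnot(branch_length >= 0)
  idx <- aa_index(seq)
  if (branch_length == 0) return(seq)
  L <- length(idx)
  rates <- .rates_from(gamma_shape, k)
  cat_of <- if (length(rates) == 1L) rep(1L, L)
            else sample.int(length(rates), L, replace = TRUE)
  out <- integer(L)
  for (kk in seq_along(rates)) {
    sites <- which(cat_of == kk)
    if (!length(sites)) next
    p <- jtt_prob_matrix(branch_length, rates[kk])
    for (a in unique(idx[sites])) {
      sel <- sites[idx[sites] == a]
      out[sel] <- sample.int(20L, length(sel), replace = TRUE, prob = p[a, ])
    }
  }
  paste(AA_ALPHABET[out], collapse = "")
}

# random codon per residue (standard code), plus a TAA stop
reverse_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste0(paste(codons, collapse = ""), "TAA")
}

# canonical GT...AG intron of the given length (>= 4)
random_intron_seq <- function(len) {
  stopifnot(len >= 4L)
  paste0("GT", paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE),
                     collapse = ""), "AG")
}

# exon intervals from exon/intron lengths; `anchor` is the genomic start
# (leftmost base) of the transcription-first exon on '+', or its half-open
# end on '-'
rebuild_exons <- function(strand, anchor, ex_lens, in_lens) {
  n <- length(ex_lens)
  exons <- matrix(0L, n, 2L, dimnames = list(NULL, c("start", "end")))
  pos <- anchor
  for (i in seq_len(n)) {
    if (strand == "+") {
      exons[i, ] <- c(pos, pos + ex_lens[i])
      pos <- pos + ex_lens[i] + if (i < n) in_lens[i] else 0L
    } else {
      exons[i, ] <- c(pos - ex_lens[i], pos)
      pos <- pos - ex_lens[i] - if (i < n) in_lens[i] else 0L
    }
  }
  exons
}

# internal intron-structure record: sorted offsets + ids + genomic lengths
.mutate_introns <- function(offsets, ids, lengths, loss_rate, gain_rate,
                            cds_len, id_prefix) {
  events <- data.frame(event = character(0), intron_id = character(0),
                       cds_offset = integer(0), stringsAsFactors = FALSE)
  keep <- rep(TRUE, length(offsets))
  if (length(offsets) && loss_rate > 0) {
    keep <- runif(length(offsets)) >= loss_rate
    for (i in which(!keep))
      events <- rbind(events, data.frame(event = "loss", intron_id = ids[i],
                                         cds_offset = offsets[i]))
  }
  offsets <- offsets[keep]; ids <- ids[keep]; lengths <- lengths[keep]
  n_gain <- if (gain_rate > 0) rpois(1L, gain_rate) else 0L
  if (n_gain > 0L) {
    # one intron per codon at most, so projected anchors stay unique
    free <- setdiff(seq_len(cds_len %/% 3L - 1L), offsets %/% 3L)
    n_gain <- min(n_gain, length(free))
    anchors <- free[sample.int(length(free), n_gain)]
    new_off <- sort(3L * anchors + sample(0:2, n_gain, replace = TRUE))
    new_ids <- paste0(id_prefix, "_g", seq_len(n_gain))
    new_len <- sample(80:300, n_gain, replace = TRUE)
    for (i in seq_len(n_gain))
      events <- rbind(events, data.frame(event = "gain", intron_id = new_ids[i],
                                         cds_offset = new_off[i]))
    ord <- order(c(offsets, new_off))
    lengths <- c(lengths, new_len)[ord]
    ids <- c(ids, new_ids)[ord]
    offsets <- sort(c(offsets, new_off))
  }
  list(offsets = offsets, ids = ids, lengths = lengths, events = events)
}

#' Mutate the intron structure of a gene model
#'
#' Each intron is lost with probability `loss_rate` (its flanking exons
#' fuse); `Poisson(gain_rate)` new introns are inserted at uniformly
#' random coding offsets. The CDS (and protein) is unchanged. Uses the
#' current RNG state.
#'
#' @param model A [gene_model()].
#' @param loss_rate Per-intron loss probability.
#' @param gain_rate Expected number of gained introns.
#' @return List with `model` (the mutated [gene_model()]) and `events`
#'   (data.frame `event, intron_id, cds_offset`; empty when nothing
#'   happened).
#' @export
mutate_gene_structure <- function(model, loss_rate, gain_rate) {
  stopifnot(inherits(model, "gene_model"))
  introns <- extract_introns(model)
  lens <- abs(introns$genomic_end - introns$genomic_start)
  mut <- .mutate_introns(introns$cds_offset,
                         paste0(model$gene_id, "_i", introns$index),
                         lens, loss_rate, gain_rate,
                         nchar(model$cds_seq), model$gene_id)
  cds_len <- nchar(model$cds_seq)
  ex_lens <- diff(c(0L, mut$offsets, cds_len))
  anchor <- if (model$strand == "+") model$exons[1, 1] else model$exons[1, 2]
  exons <- rebuild_exons(model$strand, anchor, ex_lens, mut$lengths)
  list(model = gene_model(model$gene_id, model$seqid, model$strand, exons,
                          cds_seq = model$cds_seq),
       events = mut$events)
}

#' Duplicate a neighborhood with per-gene retention
#'
#' Models neighborhood decay after a (whole-genome) duplication: each
#' flanking gene survives independently with probability `retention_p` in
#' each of the two daughter copies. Uses the current RNG state.
#'
#' @param nbhd A [extract_neighborhood()] result.
#' @param retention_p Survival probability per flanker per copy.
#' @param suffixes Identifier suffixes for the two copies.
#' @return List of two `neighborhood` objects.
#' @export
duplicate_neighborhood <- function(nbhd, retention_p,
                                   suffixes = c("_a", "_b")) {
  stopifnot(inherits(nbhd, "neighborhood"))
  copy <- function(sfx) {
    keep <- runif(nrow(nbhd$flankers)) < retention_p
    fl <- nbhd$flankers[keep, , drop = FALSE]
    fl$gene_id <- paste0(fl$gene_id, sfx)
    rownames(fl) <- NULL
    structure(list(focal_gene_id = paste0(nbhd$focal_gene_id, sfx),
                   species = nbhd$species,
                   seqid = paste0(nbhd$seqid, sfx), flankers = fl),
              class = "neighborhood")
  }
  list(copy(suffixes[1]), copy(suffixes[2]))
}

# build the chromosome-level annotation table for one member: focal gene
# with mRNA/CDS (absolute coords), retained flankers, and one RNA gene
# between the focal gene and the first downstream flanker
.member_annotations <- function(member, seqid, focal_start, region_len,
                                exons_rel, families_present, all_families,
                                flanker_spacing = 50000L,
                                flanker_len = 1000L) {
  rows <- list()
  gid <- member
  tx <- paste0(member, "_t1")
  rows[[1]] <- data.frame(seqid = seqid, feature_type = "gene",
                          start = focal_start, end = focal_start + region_len,
                          strand = "+", gene_id = gid, transcript_id = NA,
                          name = gid, biotype = "protein_coding")
  rows[[2]] <- data.frame(seqid = seqid, feature_type = "mRNA",
                          start = focal_start, end = focal_start + region_len,
                          strand = "+", gene_id = gid, transcript_id = tx,
                          name = gid, biotype = "protein_coding")
  for (i in seq_len(nrow(exons_rel))) {
    rows[[length(rows) + 1L]] <-
      data.frame(seqid = seqid, feature_type = "CDS",
                 start = focal_start + exons_rel[i, 1],
                 end = focal_start + exons_rel[i, 2],
                 strand = "+", gene_id = gid, transcript_id = tx,
                 name = gid, biotype = "protein_coding")
  }
  k <- length(all_families) %/% 2L
  for (i in seq_along(all_families)) {
    fam <- all_families[i]
    if (!fam %in% families_present) next     # lost after duplication
    if (i <= k) {         # upstream slot i: nearest = slot 1
      gap <- i * flanker_spacing
      s <- focal_start - gap - flanker_len
    } else {              # downstream slot
      gap <- (i - k) * flanker_spacing
      s <- focal_start + region_len + gap
    }
    rows[[length(rows) + 1L]] <-
      data.frame(seqid = seqid, feature_type = "gene",
                 start = s, end = s + flanker_len,
                 strand = if (i %% 2L == 0L) "-" else "+",
                 gene_id = paste0(fam, "_", member), transcript_id = NA,
                 name = fam, biotype = "protein_coding")
  }
  rna_s <- focal_start + region_len + 10000L
  rows[[length(rows) + 1L]] <-
    data.frame(seqid = seqid, feature_type = "rna_gene",
               start = rna_s, end = rna_s + 80L, strand = "+",
               gene_id = paste0("TRNA_", member), transcript_id = NA,
               name = paste0("TRNA_", member), biotype = "RNA")
  ann <- do.call(rbind, rows)
  ann$transcript_id <- as.character(ann$transcript_id)
  class(ann) <- c("annotation_table", "data.frame")
  validate_annotation_table(ann)
  ann
}

#' Simulate a two-round duplication gene family with full ground truth
#'
#' Builds an ancestor (JTT-equilibrium protein, random intron structure,
#' a neighborhood of uniquely named flanker families), applies two rounds
#' of duplication with per-branch substitution and intron gain/loss,
#' duplicates the neighborhood with per-gene retention at each round, and
#' applies configured lineage-specific gene losses. The true tree is
#' `((m1,m2),(m3,m4))` with the round-1 split deepest.
#'
#' @param config A [simulation_config()].
#' @return An object of class `family_truth`: list with `config`,
#'   `true_tree` (rooted `"phylo"` over all four members), `members`
#'   (per emitted member: `protein`, `cds`, `model` (region-relative
#'   [gene_model()]), `region_seq`, `introns` (with `intron_id` homology
#'   labels), `families`, `neighborhood`, `annotations`), `events`
#'   (per-branch intron event log), `alignment` (trivial positional
#'   alignment of the emitted proteins), `ancestor`, and `lost`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$protein_length
  cds_len <- 3L * (L + 1L)
  gs <- config$gamma_shape; kk <- config$n_rate_categories

  anc_protein <- random_protein(L)
  # one intron per codon: distinct anchor residues, uniform phase
  anc_anchor <- sort(sample(seq_len(L - 1L), min(config$n_introns, L - 1L)))
  anc_off <- 3L * anc_anchor + sample(0:2, length(anc_anchor), replace = TRUE)
  anc_ids <- sprintf("anc_i%02d", seq_along(anc_off))
  anc_lens <- sample(80:300, length(anc_off), replace = TRUE)
  n_fam <- 2L * config$flankers_per_side
  all_families <- sprintf("FAM%03d", seq_len(max(n_fam, 0L)))

  # round 1: two copies evolve duplication_depths[1]
  d1 <- config$duplication_depths[1]
  d_term <- config$duplication_depths[2] + config$terminal_depth
  events <- list()
  branch <- function(parent_seq, parent_str, t, name) {
    seq <- evolve_sequence(parent_seq, t, gs, kk)
    mut <- .mutate_introns(parent_str$offsets, parent_str$ids,
                           parent_str$lengths, config$intron_loss_rate,
                           config$intron_gain_rate, cds_len, name)
    if (nrow(mut$events))
      events[[length(events) + 1L]] <<- cbind(branch = name, mut$events)
    list(seq = seq, str = mut)
  }
  anc_str <- list(offsets = anc_off, ids = anc_ids, lengths = anc_lens)
  A <- branch(anc_protein, anc_str, d1, "A")
  B <- branch(anc_protein, anc_str, d1, "B")
  terminals <- list(m1 = branch(A$seq, A$str, d_term, "m1"),
                    m2 = branch(A$seq, A$str, d_term, "m2"),
                    m3 = branch(B$seq, B$str, d_term, "m3"),
                    m4 = branch(B$seq, B$str, d_term, "m4"))

  # neighborhood retention: per round, per copy, per family
  p <- config$neighbor_retention_p
  retain <- function(parent) parent & (runif(n_fam) < p)
  ret_anc <- rep(TRUE, n_fam)
  ret_A <- retain(ret_anc); ret_B <- retain(ret_anc)
  ret <- list(m1 = retain(ret_A), m2 = retain(ret_A),
              m3 = retain(ret_B), m4 = retain(ret_B))

  emitted <- setdiff(names(terminals), config$gene_loss)
  focal_start <- 600000L
  members <- list(); annotations <- list()
  for (m in emitted) {
    tr <- terminals[[m]]
    cds <- reverse_translate(tr$seq)
    offs <- tr$str$offsets
    ex_lens <- diff(c(0L, offs, cds_len))
    in_lens <- tr$str$lengths
    exons_rel <- rebuild_exons("+", 0L, ex_lens, in_lens)
    region_parts <- character(0)
    for (i in seq_along(ex_lens)) {
      region_parts <- c(region_parts,
                        substring(cds, c(0L, offs)[i] + 1L, c(offs, cds_len)[i]))
      if (i <= length(in_lens))
        region_parts <- c(region_parts, random_intron_seq(in_lens[i]))
    }
    region_seq <- paste(region_parts, collapse = "")
    seqid_region <- paste0(m, "_region")
    model <- gene_model(m, seqid_region, "+", exons_rel, cds_seq = cds)
    introns <- extract_introns(model)
    introns$intron_id <- tr$str$ids
    fams <- all_families[ret[[m]]]
    ann <- .member_annotations(m, paste0("chr_", m), focal_start,
                               nchar(region_seq), exons_rel, fams,
                               all_families)
    # identity family map: the synthetic FAM tokens ARE the family labels
    nbhd <- extract_neighborhood(ann, m, k = config$flankers_per_side,
                                 window = 500000L, species = m,
                                 family_map = setNames(all_families,
                                                       all_families))
    members[[m]] <- list(protein = tr$seq, cds = cds, model = model,
                         region_seq = region_seq, introns = introns,
                         families = fams, neighborhood = nbhd)
    annotations[[m]] <- ann
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(branch = character(0), event = character(0),
                        intron_id = character(0), cds_offset = integer(0))
  tt <- sprintf("((m1:%g,m2:%g)A:%g,(m3:%g,m4:%g)B:%g)R;",
                d_term, d_term, d1, d_term, d_term, d1)
  structure(list(config = config,
                 true_tree = ape::read.tree(text = tt),
                 members = members, annotations = annotations,
                 events = ev,
                 alignment = alignment(vapply(members, `[[`, "", "protein")),
                 ancestor = list(protein = anc_protein, offsets = anc_off,
                                 ids = anc_ids, lengths = anc_lens,
                                 families = all_families),
                 retention = ret,
                 lost = config$gene_loss),
            class = "family_truth")
}

#' @export
print.family_truth <- function(x, ...) {
  cat("family_truth:", length(x$members), "members (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write all simulator artifacts to a directory
#'
#' Emits `proteins.fasta`, `cds.fasta`, `regions.fasta` (genomic slices),
#' `regions.gff3` (region-relative gene models), `genes.gff3`
#' (chromosome-level annotation incl. flankers), `alignment.fasta`,
#' `introns.tsv`, `neighborhoods.tsv`, `truth.nwk`, `events.tsv`.
#'
#' @param truth A [simulate_family()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(truth, dir) {
  stopifnot(inherits(truth, "family_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mem <- truth$members
  write_fasta(vapply(mem, `[[`, "", "protein"), file.path(dir, "proteins.fasta"))
  write_fasta(vapply(mem, `[[`, "", "cds"), file.path(dir, "cds.fasta"))
  regions <- vapply(mem, `[[`, "", "region_seq")
  names(regions) <- paste0(names(mem), "_region")
  write_fasta(regions, file.path(dir, "regions.fasta"))
  write_alignment(truth$alignment, file.path(dir, "alignment.fasta"))
  introns <- do.call(rbind, lapply(mem, function(m)
    m$introns[, c("gene_id", "index", "cds_offset", "phase",
                  "protein_anchor", "genomic_start", "genomic_end")]))
  write_introns_tsv(introns, file.path(dir, "introns.tsv"))
  # region-relative gene models (CDS rows only, seqid = <member>_region)
  region_ann <- do.call(rbind, lapply(names(mem), function(m) {
    x <- mem[[m]]$model
    rbind(
      data.frame(seqid = x$seqid, feature_type = "gene",
                 start = min(x$exons), end = max(x$exons), strand = "+",
                 gene_id = m, transcript_id = NA_character_, name = m,
                 biotype = "protein_coding"),
      data.frame(seqid = x$seqid, feature_type = "mRNA",
                 start = min(x$exons), end = max(x$exons), strand = "+",
                 gene_id = m, transcript_id = paste0(m, "_t1"), name = m,
                 biotype = "protein_coding"),
      data.frame(seqid = x$seqid, feature_type = "CDS",
                 start = x$exons[, 1], end = x$exons[, 2], strand = "+",
                 gene_id = m, transcript_id = paste0(m, "_t1"), name = m,
                 biotype = "protein_coding"))
  }))
  class(region_ann) <- c("annotation_table", "data.frame")
  write_gff3(region_ann, file.path(dir, "regions.gff3"))
  chrom_ann <- do.call(rbind, truth$annotations)
  class(chrom_ann) <- c("annotation_table", "data.frame")
  write_gff3(chrom_ann, file.path(dir, "genes.gff3"))
  write_neighborhoods_tsv(lapply(mem, `[[`, "neighborhood"),
                          file.path(dir, "neighborhoods.tsv"))
  write_newick(truth$true_tree, file.path(dir, "truth.nwk"))
  con <- file(file.path(dir, "events.tsv"), "w")
  writeLines("#branch\tevent\tintron_id\tcds_offset", con)
  if (nrow(truth$events))
    write.table(truth$events, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(dir)
}
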