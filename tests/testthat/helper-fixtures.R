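# Shared fixtures and independent oracles. Everything is generated in code
# at test time; oracles are deliberately naive (grid search, exhaustive
# path enumeration) and independent of the optimized implementation paths
# they check.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random protein with optional gaps, for round-trip property tests
random_gapped_seq <- function(n, gap_p = 0.15) {
  chars <- sample(AA_ALPHABET, n, replace = TRUE)
  gaps <- runif(n) < gap_p
  chars[gaps] <- "-"
  paste(chars, collapse = "")
}

# gene model with the given coding-exon lengths (and intron lengths) built
# around a random coherent CDS; strand-aware coordinates
gene_from_lengths <- function(exon_lens, strand = "+", intron_lens = NULL,
                              anchor = 100L, gene_id = "g1") {
  stopifnot(sum(exon_lens) %% 3L == 0L)
  if (is.null(intron_lens))
    intron_lens <- rep(50L, max(length(exon_lens) - 1L, 0L))
  protein <- random_protein(sum(exon_lens) / 3L - 1L)
  cds <- paralogr:::reverse_translate(protein)
  exons <- paralogr:::rebuild_exons(strand,
                                    if (strand == "+") anchor
                                    else anchor + sum(exon_lens) + sum(intron_lens),
                                    exon_lens, intron_lens)
  gene_model(gene_id, "chr1", strand, exons, cds_seq = cds)
}

# Independent grid-search oracle for the JTT ML distance: assembles the
# likelihood directly from the eigendecomposition of the rate matrix in
# vectorized R and scans a fixed grid of branch lengths.
jtt_grid_distance <- function(a, b, gamma_shape = NULL, k = 5L,
                              tmax = 10, step = 1e-4) {
  pi <- jtt_frequencies()
  q <- jtt_rate_matrix()
  sp <- sqrt(pi)
  B <- (sp %o% (1 / sp)) * q
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ia <- match(strsplit(a, "", fixed = TRUE)[[1]], AA_ALPHABET)
  ib <- match(strsplit(b, "", fixed = TRUE)[[1]], AA_ALPHABET)
  N <- matrix(tabulate((ia - 1L) * 20L + ib, 400L), 20L, byrow = TRUE)
  cells <- which(N > 0, arr.ind = TRUE)
  C <- e$vectors[cells[, 1], , drop = FALSE] *
       e$vectors[cells[, 2], , drop = FALSE] *
       (sp[cells[, 1]] * sp[cells[, 2]])
  rates <- if (is.null(gamma_shape)) 1 else discrete_gamma_rates(gamma_shape, k)
  n_counts <- N[cells]
  ts <- seq(step, tmax, by = step)
  best_t <- NA_real_; best_ll <- -Inf
  for (chunk in split(ts, ceiling(seq_along(ts) / 20000L))) {
    f <- matrix(0, nrow(cells), length(chunk))
    for (r in rates) f <- f + C %*% exp(outer(e$values * r, chunk))
    ll <- colSums(n_counts * log(pmax(f / length(rates), 1e-300)))
    if (max(ll) > best_ll) {
      best_ll <- max(ll)
      best_t <- chunk[which.max(ll)]
    }
  }
  best_t
}

# random unrooted tree with strictly positive branch lengths
random_unrooted_tree <- function(n, min_len = 0.05, max_len = 1) {
  tr <- ape::rtree(n, br = NULL)
  tr <- ape::unroot(tr)
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  tr
}

# annotation table of evenly spaced single-interval protein-coding genes;
# default names carry no paralog suffix, so each gene is its own family
spaced_genes <- function(n, spacing = 50000L, len = 1000L, seqid = "chrT",
                         names = paste0(LETTERS[seq_len(n)], "GENE")) {
  starts <- (seq_len(n) - 1L) * spacing + 1000L
  annotation_table(seqid = seqid, feature_type = "gene",
                   start = starts, end = starts + len, strand = "+",
                   gene_id = names, name = names)
}

# three-fixture set for homology classification: full-length, PH-only and
# CC-restricted coverage against a 400-residue query with PH at [10,110)
# and CC at [250,350)
coverage_fixtures <- function() {
  domains <- data.frame(query_id = "q1",
                        name = c("PH", "CC"),
                        start = c(10L, 250L), end = c(110L, 350L))
  hit <- function(qs, qe, ev) data.frame(
    query_id = "q1", subject_id = "s1", pct_identity = 40,
    length = qe - qs + 1L, mismatch = 0L, gapopen = 0L,
    qstart = qs, qend = qe, sstart = 1L, send = qe - qs + 1L,
    evalue = ev, bitscore = 100)
  list(domains = domains, query_length = 400L,
       full = rbind(hit(1L, 300L, 1e-80), hit(280L, 390L, 1e-40)),
       ph = hit(15L, 105L, 1e-30),
       cc = hit(255L, 345L, 1e-25))
}
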