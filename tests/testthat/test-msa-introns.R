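# Projection of intron anchors into alignment columns, conservation
# scoring, the alignment filters applied before tree building, and
# per-column information content.

test_that("residue_to_column maps ungapped indices through gaps", {
  expect_equal(residue_to_column("M-KV", 1L), 2L)
  expect_equal(residue_to_column("MKVL", 0:3), 0:3)   # no gaps: identity
  expect_error(residue_to_column("M-KV", 3L), "out of range")
})

test_that("residue-to-column projection is strictly increasing", {
  set.seed(51)
  for (rep in 1:20) {
    row <- random_gapped_seq(80, gap_p = 0.3)
    n_res <- nchar(gsub("-", "", row))
    cols <- residue_to_column(row, seq_len(n_res) - 1L)
    expect_true(all(diff(cols) > 0))
  }
})

test_that("project_introns maps anchors consistently across gap patterns", {
  introns <- data.frame(gene_id = c("a", "b"), protein_anchor = c(2L, 2L),
                        phase = c(1L, 1L))
  # identical rows -> identical columns
  aln2 <- alignment(c(a = "MKVLE", b = "MKVLE"))
  map2 <- project_introns(aln2, introns)
  expect_equal(map2$msa_column, c(2L, 2L))
  # a leading gap shifts the projected column by exactly the gap
  aln3 <- alignment(c(a = "-MKVLE", b = "MKVLE-"))
  map3 <- project_introns(aln3, introns)
  expect_equal(map3$msa_column, c(3L, 2L))
  expect_error(project_introns(aln3, data.frame(gene_id = "zz",
                                                protein_anchor = 0L,
                                                phase = 0L)),
               "absent from the alignment.*zz")
  expect_error(project_introns(aln3, data.frame(gene_id = "a",
                                                protein_anchor = 9L,
                                                phase = 0L)),
               "out of range")
})

test_that("projection commutes with row permutation", {
  tru <- simulate_family(simulation_config(seed = 52))
  introns <- do.call(rbind, lapply(tru$members, `[[`, "introns"))
  map1 <- project_introns(tru$alignment, introns)
  perm <- alignment(rev(tru$alignment$seqs))
  map2 <- project_introns(perm, introns)
  key <- function(m) m[order(m$row_id, m$msa_column),
                       c("row_id", "msa_column", "phase")]
  expect_equal(key(map1), key(map2), ignore_attr = TRUE)
})

test_that("intron_conservation separates shared and phase-conflict sites", {
  shared3 <- data.frame(row_id = c("r1", "r2", "r3"),
                        msa_column = 40L, phase = 1L)
  cons <- intron_conservation(shared3)
  expect_equal(nrow(cons$shared), 1L)
  expect_equal(cons$shared$n_carriers, 3L)
  expect_equal(nrow(cons$conflicts), 0L)
  confl <- data.frame(row_id = c("r1", "r2"), msa_column = 40L,
                      phase = c(1L, 2L))
  cons2 <- intron_conservation(confl)
  expect_equal(nrow(cons2$conflicts), 1L)
  expect_equal(cons2$conflicts$phases, "1,2")
  expect_equal(nrow(cons2$shared), 0L)
})

test_that("a family without intron events has all sites fully shared", {
  for (seed in c(61, 62)) {
    tru <- simulate_family(simulation_config(seed = seed))
    introns <- do.call(rbind, lapply(tru$members, `[[`, "introns"))
    cons <- intron_conservation(project_introns(tru$alignment, introns))
    expect_equal(nrow(cons$conflicts), 0L)
    expect_true(all(cons$columns$status == "shared"))
    expect_true(all(cons$columns$n_carriers == length(tru$members)))
  }
})

test_that("shared-site fraction decreases with the intron loss rate", {
  frac_shared <- function(loss) {
    vals <- vapply(71:75, function(seed) {
      tru <- simulate_family(simulation_config(seed = seed,
                                               intron_loss_rate = loss))
      introns <- do.call(rbind, lapply(tru$members, `[[`, "introns"))
      cons <- intron_conservation(project_introns(tru$alignment, introns))
      mean(cons$columns$n_carriers == length(tru$members))
    }, 0)
    mean(vals)
  }
  f0 <- frac_shared(0); f25 <- frac_shared(0.25); f60 <- frac_shared(0.6)
  expect_equal(f0, 1)
  expect_gt(f0, f25)
  expect_gt(f25, f60)
})

test_that("complete deletion retains exactly the clean columns", {
  aln <- alignment(c(r1 = "MK-V", r2 = "MKLV"))
  out <- complete_deletion(aln)
  expect_equal(attr(out, "columns"), c(0L, 1L, 3L))
  expect_equal(unname(out$seqs), c("MKV", "MKV"))
  clean <- alignment(c(r1 = "MKVL", r2 = "MKIL"))
  expect_equal(complete_deletion(clean)$seqs, clean$seqs)
  with_x <- alignment(c(r1 = "MKVLEX", r2 = "MKVLEA"))
  expect_equal(attr(complete_deletion(with_x), "columns"), 0:4)
  expect_warning(res <- complete_deletion(alignment(c(a = "-X", b = "?-"))),
                 "every column")
  expect_equal(res$n_cols, 0L)
})

test_that("complete deletion never leaves gap or missing characters", {
  set.seed(81)
  for (rep in 1:15) {
    seqs <- setNames(vapply(1:4, function(i) random_gapped_seq(60), ""),
                     paste0("r", 1:4))
    out <- complete_deletion(alignment(seqs))
    expect_false(any(grepl("[-X?]", out$seqs)))
  }
})

test_that("gap share filter drops heavy-gap rows under both readings", {
  clean <- alignment(c(a = "MKVL", b = "MKIL", c = "MKML"))
  expect_equal(gap_fraction_filter(clean), c("a", "b", "c"))
  # one row carries 9 of 10 gap characters (share 0.9 > 0.20)
  seqs <- c(h = paste0(strrep("-", 9), strrep("A", 11)),
            r1 = paste0("-", strrep("A", 19)),
            r2 = strrep("A", 20), r3 = strrep("A", 20),
            r4 = strrep("A", 20))
  expect_equal(gap_fraction_filter(alignment(seqs), 0.20),
               c("r1", "r2", "r3", "r4"))
  # two rows with 50% of the gaps each survive a 0.6 threshold
  two <- c(a = "--AAAA", b = "AA--AA", c = "AAAAAA")
  expect_equal(gap_fraction_filter(alignment(two), 0.6), c("a", "b", "c"))
  # per-row-fraction reading: h has 45% own gaps
  expect_false("h" %in% gap_fraction_filter(alignment(seqs), 0.20,
                                            mode = "row_fraction"))
  expect_error(gap_fraction_filter(clean, 0), "threshold")
  expect_error(gap_fraction_filter(clean, 1.5), "threshold")
})

test_that("column information spans 0 to log2(20) bits", {
  full <- column_information_bits(rep("A", 50))
  expect_equal(full, log2(20))
  expect_equal(round(full, 1), 4.3)          # the logo y-axis ceiling
  expect_equal(column_information_bits(AA_ALPHABET), 0)
  expect_equal(column_information_bits(c(rep("A", 10), rep("V", 10))),
               log2(20) - 1)
  corrected <- column_information_bits(rep("A", 50),
                                       small_sample_correction = TRUE)
  expect_equal(corrected, log2(20) - 19 / (2 * log(2) * 50))
  expect_error(column_information_bits(c("-", "-", "X")), "no scorable")
})

test_that("information is maximal iff one residue, zero iff uniform", {
  set.seed(91)
  for (rep in 1:10) {
    col <- sample(AA_ALPHABET, 30, replace = TRUE)
    bits <- column_information_bits(col)
    expect_gte(bits, 0)
    if (length(unique(col)) > 1L) expect_lt(bits, log2(20))
  }
  aln <- alignment(c(a = "AAC", b = "AVC", c = "AIC"))
  bits <- alignment_information(aln)
  expect_equal(bits[1], log2(20))
  expect_equal(bits[3], log2(20))
  expect_lt(bits[2], log2(20))
})
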