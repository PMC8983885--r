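# Neighborhood extraction (four coding flankers per side within the
# window, RNA genes excluded), gene-symbol family normalization, and
# Jaccard-scored conserved blocks.

test_that("a dense locus yields four flankers per side, sorted by distance", {
  ann <- spaced_genes(9)                  # 50 kb spacing, focal in middle
  nb <- extract_neighborhood(ann, "EGENE")
  expect_equal(sum(nb$flankers$side == "up"), 4L)
  expect_equal(sum(nb$flankers$side == "down"), 4L)
  up <- nb$flankers[nb$flankers$side == "up", ]
  expect_true(all(diff(abs(up$distance)) > 0))
  expect_true(all(abs(nb$flankers$distance) <= 500000L))
})

test_that("chromosome ends and sparse loci give fewer flankers", {
  ann <- spaced_genes(5)
  nb <- extract_neighborhood(ann, "AGENE")  # focal at chromosome start
  expect_equal(sum(nb$flankers$side == "up"), 0L)
  expect_equal(sum(nb$flankers$side == "down"), 4L)
  # genes beyond the window are not collected
  far <- annotation_table(seqid = "chrT", feature_type = "gene",
                          start = c(1000L, 900000L), end = c(2000L, 901000L),
                          strand = "+", gene_id = c("F1", "F2"),
                          name = c("F1", "F2"))
  nb2 <- extract_neighborhood(far, "F1")
  expect_equal(nrow(nb2$flankers), 0L)
})

test_that("RNA genes are skipped and do not count toward k", {
  base <- spaced_genes(6)
  trna <- annotation_table(seqid = "chrT", feature_type = "rna_gene",
                           start = 6000L, end = 6100L, strand = "+",
                           gene_id = "tRNA1", name = "tRNA1", biotype = "RNA")
  ann <- rbind(base, trna)
  class(ann) <- c("annotation_table", "data.frame")
  nb <- extract_neighborhood(ann, "AGENE")
  expect_false("tRNA1" %in% nb$flankers$gene_id)
  expect_equal(sum(nb$flankers$side == "down"), 4L)   # coding genes only
  expect_error(extract_neighborhood(ann, "tRNA1"), "not protein-coding")
  expect_error(extract_neighborhood(ann, "nope"), "not found")
})

test_that("extraction never exceeds k flankers per side", {
  set.seed(121)
  for (rep in 1:10) {
    n <- sample(3:25, 1)
    starts <- sort(sample.int(400000L, n))
    ann <- annotation_table(seqid = "c", feature_type = "gene",
                            start = starts, end = starts + 500L,
                            strand = "+",
                            gene_id = paste0("g", seq_len(n)),
                            name = paste0("g", seq_len(n)))
    focal <- paste0("g", sample.int(n, 1))
    k <- sample(1:5, 1)
    nb <- extract_neighborhood(ann, focal, k = k)
    expect_lte(sum(nb$flankers$side == "up"), k)
    expect_lte(sum(nb$flankers$side == "down"), k)
  }
})

test_that("family assignment strips paralog suffixes as in the field", {
  expect_equal(assign_family(c("Sox6", "Sox13")), c("SOX", "SOX"))
  expect_equal(assign_family(c("Pik3c2a", "Pik3c2b", "Pik3c2g")),
               rep("PIK3C2", 3))
  expect_equal(assign_family("INSC"), "INSC")
  expect_equal(assign_family("Kcnj11", c(KCNJ11 = "KCN")), "KCN")
  expect_error(assign_family(c("Sox6", "")), "empty gene symbol")
})

test_that("conserved blocks score Jaccard overlap of family sets", {
  ann <- spaced_genes(9)
  nb <- extract_neighborhood(ann, "EGENE")
  self_block <- conserved_blocks(nb, nb)
  expect_equal(self_block$score, 1)
  expect_equal(nrow(self_block$shared), 8L)
  # disjoint family sets
  ann2 <- spaced_genes(9, names = paste0(LETTERS[10:18], "GENE"))
  nb2 <- extract_neighborhood(ann2, "NGENE")
  expect_equal(conserved_blocks(nb, nb2)$score, 0)
  expect_equal(nrow(conserved_blocks(nb, nb2)$shared), 0L)
})

test_that("a 2-of-14 overlap scores 2/14 and is symmetric", {
  mk <- function(names, focal) {
    ann <- spaced_genes(9, names = c(names[1:4], focal, names[5:8]))
    extract_neighborhood(ann, focal)
  }
  # 6 private families each + SJA/SJB present on both sides: union is 14
  nb_a <- mk(c("ALPHA1", "BRAVO1", "CHARLIE1", "DELTA1", "ECHO1", "FOX1",
               "SJA1", "SJB1"), "FOC1")
  nb_b <- mk(c("GOLF1", "HOTEL1", "INDIA1", "JULIET1", "KILO1", "LIMA1",
               "SJA2", "SJB2"), "FOC2")
  bl <- conserved_blocks(nb_a, nb_b)
  expect_equal(bl$score, 2 / 14)
  expect_equal(bl$shared$family_label, c("SJA", "SJB"))
  bl_rev <- conserved_blocks(nb_b, nb_a)
  expect_equal(bl_rev$score, bl$score)
  expect_equal(bl_rev$shared$family_label, bl$shared$family_label)
})

test_that("shared flankers after one duplication follow 8 p^2", {
  ann <- spaced_genes(9, names = c(sprintf("FAM%03d", 1:4), "FOCAL",
                                   sprintf("FAM%03d", 5:8)))
  full <- extract_neighborhood(ann, "FOCAL",
                               family_map = setNames(sprintf("FAM%03d", 1:8),
                                                     sprintf("FAM%03d", 1:8)))
  expect_equal(nrow(full$flankers), 8L)
  set.seed(132)
  p <- 0.7
  shared <- vapply(1:200, function(i) {
    copies <- duplicate_neighborhood(full, p)
    nrow(conserved_blocks(copies[[1]], copies[[2]])$shared)
  }, 0)
  expected <- 8 * p^2
  se <- sqrt(8 * p^2 * (1 - p^2)) / sqrt(200)
  expect_lt(abs(mean(shared) - expected), 3 * se)
})
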