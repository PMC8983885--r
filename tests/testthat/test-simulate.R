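# The two-round duplication simulator: substitution against the model's
# closed form, intron event bookkeeping, neighborhood decay, and the
# emitted ground truth.

test_that("evolution at branch length zero is the identity, and seeded", {
  set.seed(151)
  a <- random_protein(100)
  expect_identical(evolve_sequence(a, 0), a)
  set.seed(5); x1 <- evolve_sequence(a, 0.3)
  set.seed(5); x2 <- evolve_sequence(a, 0.3)
  expect_identical(x1, x2)
  expect_error(evolve_sequence("MK-", 0.1), "non-standard")
})

test_that("the realized substitution fraction matches the closed form", {
  set.seed(152)
  n <- 10000L
  a <- random_protein(n)
  b <- evolve_sequence(a, 0.1)
  changed <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  p <- jtt_prob_matrix(0.1)
  pi <- jtt_frequencies()
  expected <- 1 - sum(pi * diag(p))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(changed - expected), 3 * se)
})

test_that("intron mutation respects its rates and logs every event", {
  set.seed(153)
  g <- gene_from_lengths(c(30L, 60L, 30L, 60L))
  same <- mutate_gene_structure(g, 0, 0)
  expect_equal(same$model$exons, g$exons)
  expect_equal(nrow(same$events), 0L)
  gone <- mutate_gene_structure(g, 1, 0)
  expect_equal(nrow(gone$model$exons), 1L)
  expect_equal(sum(gone$events$event == "loss"), 3L)
  # CDS and protein survive any structure mutation
  both <- mutate_gene_structure(g, 0.5, 2)
  expect_identical(both$model$cds_seq, g$cds_seq)
  expect_identical(both$model$protein_seq, g$protein_seq)
})

test_that("mean intron losses follow the binomial expectation", {
  set.seed(154)
  g <- gene_from_lengths(rep(30L, 9))   # 8 introns
  losses <- vapply(1:500, function(i)
    sum(mutate_gene_structure(g, 0.25, 0)$events$event == "loss"), 0)
  expected <- 8 * 0.25
  se <- sqrt(8 * 0.25 * 0.75) / sqrt(500)
  expect_lt(abs(mean(losses) - expected), 3 * se)
})

test_that("default simulations produce the 2R family with its true tree", {
  tru <- simulate_family(simulation_config(seed = 155))
  expect_equal(names(tru$members), c("m1", "m2", "m3", "m4"))
  expected <- ape::read.tree(text = "((m1:1,m2:1):1,(m3:1,m4:1):1);")
  expect_equal(rf_distance(ape::unroot(tru$true_tree),
                           ape::unroot(expected)), 0L)
  # branch depths: terminal = round-2 + terminal depth, internal = round-1
  lens <- tru$true_tree$edge.length
  tips <- tru$true_tree$edge[, 2] <= 4
  expect_true(all(abs(lens[tips] - 0.4) < 1e-9))
  expect_true(all(abs(lens[!tips] - 0.4) < 1e-9))
  # same seed, same family
  tru2 <- simulate_family(simulation_config(seed = 155))
  expect_identical(tru$members$m2$protein, tru2$members$m2$protein)
})

test_that("lineage-specific gene loss drops members but not the truth", {
  tru <- simulate_family(simulation_config(seed = 156, gene_loss = "m3"))
  expect_equal(names(tru$members), c("m1", "m2", "m4"))
  expect_equal(tru$lost, "m3")
  expect_equal(sort(tru$true_tree$tip.label), c("m1", "m2", "m3", "m4"))
})

test_that("full neighbor retention gives identical neighborhoods", {
  tru <- simulate_family(simulation_config(seed = 157,
                                           neighbor_retention_p = 1))
  nbs <- lapply(tru$members, `[[`, "neighborhood")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(conserved_blocks(nbs[[i]], nbs[[j]])$score, 1)
  }
})

test_that("synteny truth: shared families equal the joint retention draws", {
  for (seed in c(158, 159)) {
    tru <- simulate_family(simulation_config(seed = seed))
    for (pair in list(c("m1", "m2"), c("m1", "m3"), c("m2", "m4"))) {
      bl <- conserved_blocks(tru$members[[pair[1]]]$neighborhood,
                             tru$members[[pair[2]]]$neighborhood)
      truth_shared <- sort(intersect(tru$members[[pair[1]]]$families,
                                     tru$members[[pair[2]]]$families))
      expect_equal(bl$shared$family_label, truth_shared)
    }
  }
})

test_that("intron absences match the simulator event log exactly", {
  path_of <- list(m1 = c("A", "m1"), m2 = c("A", "m2"),
                  m3 = c("B", "m3"), m4 = c("B", "m4"))
  for (seed in 161:163) {
    tru <- simulate_family(simulation_config(seed = seed,
                                             intron_loss_rate = 0.25))
    ev <- tru$events
    for (m in names(tru$members)) {
      have <- tru$members[[m]]$introns$intron_id
      lost_on_path <- ev$intron_id[ev$event == "loss" &
                                   ev$branch %in% path_of[[m]]]
      expect_equal(sort(setdiff(tru$ancestor$ids, have)),
                   sort(unique(lost_on_path)))
    }
  }
})

test_that("simulator artifacts round trip through their formats", {
  tru <- simulate_family(simulation_config(seed = 164))
  dir <- tempfile()
  write_family(tru, dir)
  prot <- read_fasta(file.path(dir, "proteins.fasta"), "protein")
  expect_equal(setNames(prot$seq, prot$id),
               vapply(tru$members, `[[`, "", "protein"))
  tt <- read_newick(file.path(dir, "truth.nwk"))
  expect_equal(rf_distance(tt, tru$true_tree), 0L)
  intr <- read_introns_tsv(file.path(dir, "introns.tsv"))
  expect_equal(nrow(intr),
               sum(vapply(tru$members, function(m) nrow(m$introns), 0L)))
})
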