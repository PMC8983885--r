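# Distance phylogeny: JTT ML distances against a grid-search oracle and
# an independent reference implementation, NJ consistency on additive
# matrices, bootstrap determinism, midpoint rooting against brute-force
# longest-path search, and RF distances.

test_that("jtt_distance is ~0 for identical sequences and symmetric", {
  set.seed(101)
  a <- random_protein(150)
  expect_lt(jtt_distance(a, a), 1e-5)
  for (rep in 1:8) {
    x <- random_protein(120)
    y <- evolve_sequence(x, runif(1, 0.05, 1.2))
    expect_equal(as.numeric(jtt_distance(x, y)),
                 as.numeric(jtt_distance(y, x)), tolerance = 1e-8)
  }
  expect_error(jtt_distance("MKV", "MK"), "length")
  expect_error(jtt_distance("", ""), "zero overlapping sites|length")
  expect_error(jtt_distance("MK-", "MKV"), "non-standard residue")
  # unrelated short sequences push the optimizer to its upper bound
  set.seed(1)
  sat <- jtt_distance(random_protein(30), random_protein(30))
  expect_true(attr(sat, "saturated"))
})

test_that("jtt_distance matches the grid-search oracle", {
  set.seed(102)
  # the canonical near-zero case: 100 sites, one difference
  a <- random_protein(100)
  b <- a
  substr(b, 50, 50) <- setdiff(AA_ALPHABET, substr(a, 50, 50))[1]
  expect_lt(abs(as.numeric(jtt_distance(a, b)) - jtt_grid_distance(a, b)),
            1e-3)
  for (rep in 1:6) {
    x <- random_protein(200)
    y <- evolve_sequence(x, runif(1, 0.1, 1.0))
    expect_lt(abs(as.numeric(jtt_distance(x, y)) - jtt_grid_distance(x, y)),
              1e-3)
    shape <- runif(1, 0.5, 3)
    expect_lt(abs(as.numeric(jtt_distance(x, y, gamma_shape = shape)) -
                  jtt_grid_distance(x, y, gamma_shape = shape)),
              1e-3)
  }
})

test_that("jtt_distance agrees with an independent JTT implementation", {
  skip_if_not_installed("phangorn")
  set.seed(103)
  for (rep in 1:5) {
    a <- random_protein(250)
    b <- evolve_sequence(a, runif(1, 0.1, 0.9))
    pd <- phangorn::phyDat(rbind(a = strsplit(a, "")[[1]],
                                 b = strsplit(b, "")[[1]]), type = "AA")
    ref <- as.numeric(phangorn::dist.ml(pd, model = "JTT"))
    expect_equal(as.numeric(jtt_distance(a, b)), ref, tolerance = 1e-4)
  }
})

test_that("jtt_distance grows with the number of differing sites", {
  set.seed(104)
  a <- random_protein(200)
  chars <- strsplit(a, "")[[1]]
  prev <- 0
  for (ndiff in c(5, 20, 50, 90, 140)) {
    b <- chars
    idx <- seq_len(ndiff)
    b[idx] <- vapply(chars[idx],
                     function(r) setdiff(AA_ALPHABET, r)[1], "")
    d <- as.numeric(jtt_distance(a, paste(b, collapse = "")))
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("NJ solves the three-taxon closed form exactly", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  tree <- neighbor_joining(d)
  lens <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                          tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(lens[["a"]], (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-9)
  expect_equal(lens[["b"]], (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(lens[["c"]], (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-9)
})

test_that("NJ recovers trees exactly from additive matrices", {
  skip_if_not_installed("phangorn")
  set.seed(105)
  for (rep in 1:25) {
    tr <- random_unrooted_tree(sample(4:10, 1))
    d <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(d)
    expect_equal(rf_distance(nj, tr), 0L)
    # branch lengths are reproduced on additive input
    expect_equal(sum(nj$edge.length), sum(tr$edge.length), tolerance = 1e-6)
    # independent cross-check of the whole construction
    expect_equal(phangorn::RF.dist(nj, ape::nj(d)), 0)
  }
})

test_that("NJ ties break toward the lowest index pair, deterministically", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(paste0("t", 1:4), paste0("t", 1:4))
  n1 <- ape::write.tree(neighbor_joining(d))
  n2 <- ape::write.tree(neighbor_joining(d))
  expect_identical(n1, n2)
  # t1 and t2 are joined first, so they form a cherry
  expect_true(grepl("t1:[0-9.e-]+,t2:", n1))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d[1, 2] <- d[2, 1] <- Inf
  expect_error(neighbor_joining(d), "non-finite")
})

test_that("bootstrap support is deterministic and bounded", {
  tru <- simulate_family(simulation_config(seed = 106))
  cfg <- phylo_config(n_bootstrap = 50L, seed = 9L)
  t1 <- bootstrap_support(tru$alignment, cfg)
  t2 <- bootstrap_support(tru$alignment, cfg)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_true(all(attr(t1, "support") >= 0 & attr(t1, "support") <= 100))
  # only internal (non-trivial) edges are reported
  expect_equal(length(attr(t1, "support")),
               length(tree_bipartitions(t1)))
})

test_that("clearly separated groups get full bootstrap support", {
  set.seed(107)
  anc1 <- random_protein(200)
  anc2 <- evolve_sequence(anc1, 2.5)      # long internal branch
  seqs <- c(a1 = evolve_sequence(anc1, 0.02), a2 = evolve_sequence(anc1, 0.02),
            a3 = evolve_sequence(anc1, 0.02),
            b1 = evolve_sequence(anc2, 0.02), b2 = evolve_sequence(anc2, 0.02),
            b3 = evolve_sequence(anc2, 0.02))
  tree <- bootstrap_support(alignment(seqs),
                            phylo_config(n_bootstrap = 100L, seed = 3L))
  support <- attr(tree, "support")
  split_key <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  expect_true(split_key %in% names(support))
  expect_equal(unname(support[split_key]), 100)
})

test_that("midpoint rooting balances the two deepest leaves", {
  sym <- read_newick(write_tmp("((a:1,b:1):0.5,(c:1,d:1):0.5);", ".nwk"))
  rooted <- midpoint_root(ape::unroot(sym))
  dm <- ape::dist.nodes(rooted)
  root <- length(rooted$tip.label) + 1L
  depths <- unname(dm[root, seq_along(rooted$tip.label)])
  expect_equal(max(depths), sort(depths, decreasing = TRUE)[2],
               tolerance = 1e-9)
  # caterpillar with one long terminal branch: root lands on that branch
  cat_tree <- read_newick(write_tmp("(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:2);",
                                    ".nwk"))
  r2 <- midpoint_root(cat_tree)
  root_kids <- r2$edge[r2$edge[, 1] == length(r2$tip.label) + 1L, 2]
  d_idx <- which(r2$tip.label == "d")
  expect_true(d_idx %in% root_kids)
  len_d <- r2$edge.length[r2$edge[, 2] == d_idx]
  # diameter is d..a = 2 + 0.1 + 0.1 + 0.1 = 2.3, so d keeps half of it
  expect_equal(len_d, 2.3 / 2, tolerance = 1e-9)
  flat <- ape::rtree(4); flat$edge.length <- rep(0, nrow(flat$edge))
  expect_error(midpoint_root(flat), "midpoint undefined")
})

test_that("midpoint agrees with exhaustive longest-path search", {
  skip_if_not_installed("phangorn")
  set.seed(108)
  for (rep in 1:20) {
    tr <- random_unrooted_tree(sample(4:12, 1))
    # brute force: all-pairs path lengths
    cp <- ape::cophenetic.phylo(tr)
    diameter <- max(cp)
    lp <- longest_leaf_path(tr)
    expect_equal(lp$length, diameter, tolerance = 1e-9)
    rooted <- midpoint_root(tr)
    dm <- ape::dist.nodes(rooted)
    root <- length(rooted$tip.label) + 1L
    depths <- unname(dm[root, seq_along(rooted$tip.label)])
    expect_equal(max(depths), diameter / 2, tolerance = 1e-9)
    expect_equal(max(depths), sort(depths, decreasing = TRUE)[2],
                 tolerance = 1e-9)
    expect_equal(phangorn::RF.dist(rooted, phangorn::midpoint(tr)), 0)
  }
})

test_that("RF distance counts bipartition differences symmetrically", {
  skip_if_not_installed("phangorn")
  t1 <- read_newick(write_tmp("((a:1,b:1):1,(c:1,d:1):1);", ".nwk"))
  t2 <- read_newick(write_tmp("((a:1,c:1):1,(b:1,d:1):1);", ".nwk"))
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  set.seed(109)
  for (rep in 1:10) {
    x <- random_unrooted_tree(8); y <- random_unrooted_tree(8)
    expect_equal(rf_distance(x, y), rf_distance(y, x))
    expect_equal(rf_distance(x, y), phangorn::RF.dist(x, y))
  }
  t3 <- read_newick(write_tmp("((a:1,b:1):1,(c:1,e:1):1);", ".nwk"))
  expect_error(rf_distance(t1, t3), "leaf sets differ")
})
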