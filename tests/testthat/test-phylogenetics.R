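test_that("pairwise deletion and Poisson correction behave as defined", {
  expect_equal(pairwise_distance("AAAA", "AAAA", "p"), 0)
  expect_equal(pairwise_distance("AAAA", "AAAC", "p"), 0.25)
  expect_equal(pairwise_distance("AAAA", "AAAC", "poisson"), -log(0.75))
  expect_equal(pairwise_distance("A-AA", "AAAA", "p"), 0)
  expect_equal(pairwise_distance("AXAA", "AAAA", "p"), 0)
  expect_error(pairwise_distance("--", "AA"), "no comparable")
  expect_error(pairwise_distance("AC", "CA", "poisson"), "Poisson")
})

test_that("Poisson correction is monotone in p and never below p", {
  p <- seq(0.01, 0.95, by = 0.01)
  d <- -log(1 - p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("two- and three-taxon trees match the closed forms", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(0.2, 0.2))
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[["A"]], 0.5, tolerance = 1e-9)
  expect_equal(lens[["B"]], 1.5, tolerance = 1e-9)
  expect_equal(lens[["C"]], 2.5, tolerance = 1e-9)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(neighbor_joining(-d2), "negative")
})

test_that("NJ recovers the topology of additive matrices (RF = 0)", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  for (i in 1:40) {
    tr <- random_additive_tree(sample(4:12, 1))
    d <- tree_distance_matrix(tr)
    nj_t <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(nj_t, tr), 0)
  }
})

test_that("NJ topology agrees with the reference implementation in ape", {
  skip_if_not_installed("phangorn")
  set.seed(77)
  for (i in 1:20) {
    tr <- random_additive_tree(sample(4:10, 1))
    d <- tree_distance_matrix(tr)
    expect_equal(phangorn::RF.dist(neighbor_joining(d), ape::nj(d)), 0)
  }
})

test_that("perfectly clade-separating alignments give 100% support", {
  aln <- tibble::tibble(
    name = c("A", "B", "C", "D"),
    row = c(paste0(strrep("K", 20), strrep("W", 10)),
            paste0(strrep("K", 18), "RR", strrep("W", 10)),
            paste0(strrep("E", 20), strrep("W", 10)),
            paste0(strrep("E", 18), "QQ", strrep("W", 10))))
  b <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  supports <- suppressWarnings(as.numeric(b$tree$node.label))
  supports <- supports[!is.na(supports)]
  expect_equal(supports, 100)
  expect_true(all(supports >= 0 & supports <= 100))
})

test_that("bootstrap is reproducible under a seed and leaf-order invariant", {
  g <- simulate_alignment_on_tree(random_additive_tree(6), 80, seed = 42)
  b1 <- bootstrap_support(g, n_replicates = 50, seed = 3)
  b2 <- bootstrap_support(g, n_replicates = 50, seed = 3)
  expect_identical(b1$tree$node.label, b2$tree$node.label)
  perm <- g[sample(nrow(g)), ]
  b3 <- bootstrap_support(perm, n_replicates = 50, seed = 3)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b3$tree))
})

test_that("supports equal an independent bipartition recount", {
  set.seed(18)
  tr <- random_additive_tree(5)
  aln <- simulate_alignment_on_tree(tr, 60, seed = 21)
  b <- bootstrap_support(aln, n_replicates = 200, seed = 9,
                         keep_replicates = TRUE)
  # oracle: recount each original bipartition across the saved replicate trees
  tips <- sort(b$tree$tip.label)
  ref <- tips[[1]]
  split_set <- function(tree) {
    pp <- ape::prop.part(tree)
    out <- character()
    for (cl in pp) {
      side <- tree$tip.label[cl]
      if (ref %in% side) side <- setdiff(tips, side)
      if (length(side) >= 2 && length(side) <= length(tips) - 2) {
        out <- c(out, paste(sort(side), collapse = "|"))
      }
    }
    unique(out)
  }
  orig <- split_set(b$tree)
  counts <- setNames(rep(0L, length(orig)), orig)
  for (rt in b$replicate_trees) {
    hit <- intersect(orig, split_set(rt))
    counts[hit] <- counts[hit] + 1L
  }
  oracle_support <- round(100 * counts / b$n_replicates)
  ntip <- length(b$tree$tip.label)
  pp <- ape::prop.part(b$tree)
  for (k in seq_along(pp)) {
    side <- b$tree$tip.label[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2 || length(side) > ntip - 2) next
    key <- paste(sort(side), collapse = "|")
    expect_equal(as.numeric(b$tree$node.label[[k]]),
                 as.numeric(oracle_support[[key]]))
  }
})

test_that("collapse is strict at the 50% boundary", {
  tr <- ape::read.tree(text = "((A:1,B:1)50:1,(C:1,D:1)51:1,E:1);")
  col <- collapse_low_support(tr, 50)
  expect_equal(ape::Ntip(col), 5)
  expect_equal(col$Nnode, 2)  # the 50 edge went, the 51 edge stayed
  all100 <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)100:1,E:1);")
  kept <- collapse_low_support(all100, 50)
  expect_equal(kept$Nnode, all100$Nnode)
})

test_that("random collapses match a brute-force contraction oracle", {
  skip_if_not_installed("phangorn")
  set.seed(60)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(sample(5:10, 1)))
    nint <- tr$Nnode
    sup <- sample(0:100, nint, replace = TRUE)
    tr$node.label <- c("", as.character(sup[-1]))
    thr <- sample(c(30, 50, 70), 1)
    got <- collapse_low_support(tr, thr)
    expect_setequal(got$tip.label, tr$tip.label)
    expect_lte(nrow(got$edge), nrow(tr$edge))
    # oracle: surviving internal edges = original splits whose support > thr
    ntip <- ape::Ntip(tr)
    surviving <- 0L
    pp <- ape::prop.part(tr)
    for (k in 2:length(pp)) {  # skip root part
      if (as.numeric(tr$node.label[[k]]) > thr) surviving <- surviving + 1L
    }
    expect_equal(got$Nnode, surviving + 1L)
  }
})

test_that("Newick files round-trip with lengths and supports intact", {
  skip_if_not_installed("phangorn")
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", p)
  t0 <- read_newick(p)
  expect_equal(sort(t0$tip.label), c("A", "B"))
  set.seed(2)
  tr <- random_additive_tree(8)
  write_newick(tr, p)
  back <- read_newick(p)
  expect_equal(phangorn::RF.dist(back, tr), 0)
  m1 <- tree_distance_matrix(tr)
  m2 <- tree_distance_matrix(back)[rownames(m1), colnames(m1)]
  expect_equal(m1, m2, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1;", bad)
  expect_error(read_newick(bad))
})
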