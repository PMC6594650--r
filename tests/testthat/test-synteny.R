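test_that("BLAST tables parse, drop self-hits, and report bad lines", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), p)
  expect_equal(nrow(read_blast_tabular(p)), 0L)
  writeLines("g1\tg1\t100.00\t200\t0\t0\t1\t200\t1\t200\t1e-100\t500", p)
  expect_equal(nrow(read_blast_tabular(p)), 0L)  # self-hit removed
  writeLines(c("g1\tg2\t95.00\t200\t5\t0\t1\t200\t1\t200\t1e-80\t400",
               "g1\tg3\tbroken"), p)
  expect_error(read_blast_tabular(p), "line 2")
})

test_that("synthetic homology tables round-trip through the parser", {
  g <- simulate_genome_pair(seed = 6)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(g$ortholog_hits, p)
  back <- read_blast_tabular(p)
  expect_equal(nrow(back), nrow(g$ortholog_hits))
  expect_equal(back$query_gene, g$ortholog_hits$query_gene)
  expect_equal(back$subject_gene, g$ortholog_hits$subject_gene)
})

test_that("tandem detection applies the rank-difference-1 rule", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "h1", "h2"),
    chromosome = c(rep("chr1", 4), "chr2", "chr2"),
    start = c(100, 200, 300, 400, 100, 5000))
  rk <- assign_gene_ranks(genes)
  empty <- detect_tandem_arrays(
    tibble::tibble(query_gene = character(), subject_gene = character()), rk)
  expect_equal(nrow(empty), 0L)
  hits <- tibble::tibble(query_gene = c("g1", "g2"),
                         subject_gene = c("g3", "g3"))
  td <- detect_tandem_arrays(hits, rk)
  expect_equal(nrow(td), 1L)
  expect_equal(c(td$gene_a, td$gene_b), c("g2", "g3"))
  # adjacent ranks on different chromosomes do not qualify
  cross <- tibble::tibble(query_gene = "g1", subject_gene = "h1")
  expect_equal(nrow(detect_tandem_arrays(cross, rk)), 0L)
  expect_error(detect_tandem_arrays(
    tibble::tibble(query_gene = "g1", subject_gene = "nope"), rk), "missing")
})

test_that("tandem output always satisfies the rule's invariants", {
  g <- simulate_genome_pair(seed = 13)
  rkb <- assign_gene_ranks(g$genes_b)
  td <- detect_tandem_arrays(g$paralog_hits_b, rkb)
  expect_true(all(abs(td$rank_a - td$rank_b) == 1L))
  hit_pairs <- paste(pmin(g$paralog_hits_b$query_gene,
                          g$paralog_hits_b$subject_gene),
                     pmax(g$paralog_hits_b$query_gene,
                          g$paralog_hits_b$subject_gene))
  expect_true(all(paste(td$gene_a, td$gene_b) %in% hit_pairs))
})

mk_rank <- function(ids, chrom = "c1") {
  tibble::tibble(gene_id = ids, chromosome = chrom,
                 start = seq_along(ids) * 1000) |> assign_gene_ranks()
}

test_that("a planted diagonal chains into one block; short ones are dropped", {
  a <- mk_rank(sprintf("a%02d", 1:10))
  b <- mk_rank(sprintf("b%02d", 1:10))
  diag6 <- tibble::tibble(query_gene = sprintf("a%02d", 2:7),
                          subject_gene = sprintf("b%02d", 3:8))
  blk <- chain_collinear_blocks(diag6, a, b, min_anchors = 5L)
  expect_equal(length(unique(blk$block_id)), 1L)
  expect_equal(nrow(blk), 6L)
  expect_equal(blk$orientation, rep("same", 6))
  expect_true(all(diff(blk$a_rank) > 0) && all(diff(blk$b_rank) > 0))
  diag4 <- diag6[1:4, ]
  expect_equal(nrow(chain_collinear_blocks(diag4, a, b, min_anchors = 5L)), 0L)
})

test_that("an anti-diagonal is reported as an inverted block", {
  a <- mk_rank(sprintf("a%02d", 1:10))
  b <- mk_rank(sprintf("b%02d", 1:10))
  anti <- tibble::tibble(query_gene = sprintf("a%02d", 1:7),
                         subject_gene = sprintf("b%02d", 9:3))
  blk <- chain_collinear_blocks(anti, a, b, min_anchors = 5L)
  expect_equal(length(unique(blk$block_id)), 1L)
  expect_equal(nrow(blk), 7L)
  expect_equal(unique(blk$orientation), "inverted")
  expect_true(all(diff(blk$b_rank) < 0))
})

test_that("planted genome pairs are recovered exactly at noiseless settings", {
  g <- simulate_genome_pair(seed = 21)
  rka <- assign_gene_ranks(g$genes_a)
  rkb <- assign_gene_ranks(g$genes_b)
  blk <- chain_collinear_blocks(g$ortholog_hits, rka, rkb)
  truth <- g$truth$blocks
  expect_setequal(paste(blk$gene_a, blk$gene_b),
                  paste(truth$gene_a, truth$gene_b))
  td <- detect_tandem_arrays(g$paralog_hits_b, rkb)
  tt <- g$truth$tandem_pairs
  expect_setequal(paste(td$gene_a, td$gene_b),
                  paste(pmin(tt$gene_a, tt$gene_b),
                        pmax(tt$gene_a, tt$gene_b)))
  # orientation labels match the planted inversions
  inv_chrom <- unique(truth$chrom_a[truth$inverted])
  got_inv <- unique(blk$chrom_a[blk$orientation == "inverted"])
  expect_setequal(got_inv, inv_chrom)
})

test_that("noise hits never produce blocks below the anchor threshold", {
  g <- simulate_genome_pair(noise_hits = 40L, seed = 33)
  rka <- assign_gene_ranks(g$genes_a)
  rkb <- assign_gene_ranks(g$genes_b)
  blk <- chain_collinear_blocks(g$ortholog_hits, rka, rkb, min_anchors = 5L)
  sizes <- table(blk$block_id)
  expect_true(all(sizes >= 5L))
  # every planted anchor still recovered
  truth <- g$truth$blocks
  expect_true(all(paste(truth$gene_a, truth$gene_b) %in%
                    paste(blk$gene_a, blk$gene_b)))
})

test_that("ortholog extraction keeps the minimum-Ks partner", {
  blocks <- tibble::tibble(
    block_id = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    chrom_a = "c1", chrom_b = "c1", orientation = "same",
    gene_a = c(sprintf("a%d", 1:5), "a1", sprintf("a%d", 6:9)),
    gene_b = c(sprintf("b%d", 1:5), "b9", sprintf("b%d", 10:13)),
    a_rank = c(1:5, 1L, 6:9), b_rank = c(1:5, 9L, 10:13), score = 5)
  fake_ks <- function(a, b) {
    if (b == "b9") list(ka = 0.05, ks = 0.9, omega = 0.056)
    else list(ka = 0.02, ks = 0.2, omega = 0.1)
  }
  op <- extract_ortholog_pairs(blocks, c("a1", "a9", "zz"), character(),
                               fake_ks)
  expect_equal(op$gene_b[op$gene_a == "a1"], "b1")  # Ks 0.2 beats 0.9
  expect_equal(attr(op, "unpaired"), "zz")
  expect_equal(unique(op$selection_class), "purifying")
  # saturation guard drops pairs with huge Ks
  sat <- extract_ortholog_pairs(blocks, "a1", character(),
                                function(a, b) list(ka = 1, ks = 5,
                                                    omega = 0.2))
  expect_equal(nrow(sat), 0L)
  expect_equal(attr(sat, "unpaired"), "a1")
})

test_that("planted 1:1 orthology is recovered through Ka/Ks", {
  g <- simulate_genome_pair(seed = 44)
  rka <- assign_gene_ranks(g$genes_a)
  rkb <- assign_gene_ranks(g$genes_b)
  blk <- chain_collinear_blocks(g$ortholog_hits, rka, rkb)
  fam_a <- unique(g$truth$blocks$gene_a)[1:8]
  kf <- make_kaks_fn(c(g$cds_a, g$cds_b))
  op <- extract_ortholog_pairs(blk, fam_a, character(), kf)
  truth_map <- g$truth$ortholog_map
  expect_equal(nrow(op), 8L)
  expect_true(all(paste(op$gene_a, op$gene_b) %in%
                    paste(truth_map$gene_a, truth_map$gene_b)))
  expect_true(all(op$ks >= 0 & op$ka >= 0))
})

test_that("tandem percentages reproduce the reported family shares", {
  expect_equal(tandem_percentage(2, 37), 5.4)
  expect_equal(tandem_percentage(4, 32), 12.5)
})
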