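test_that("a minimal one-gene GFF parses to one single-exon model", {
  path <- withr::local_tempfile(fileext = ".gff3")
  minimal_gff(path)
  genes <- read_gff_genes(path)
  expect_equal(nrow(genes), 1L)
  expect_equal(genes$gene_id, "g1")
  expect_equal(exon_count(genes), 1L)
  expect_equal(genes$start, 100)
})

test_that("the longest mRNA's exons are retained", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t1000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=g1.t1",
    "chr1\tsrc\texon\t300\t400\t.\t+\t.\tID=e2;Parent=g1.t1",
    "chr1\tsrc\texon\t500\t600\t.\t+\t.\tID=e3;Parent=g1.t1",
    "chr1\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tsrc\texon\t100\t220\t.\t+\t.\tID=f1;Parent=g1.t2",
    "chr1\tsrc\texon\t300\t420\t.\t+\t.\tID=f2;Parent=g1.t2",
    "chr1\tsrc\texon\t500\t620\t.\t+\t.\tID=f3;Parent=g1.t2",
    "chr1\tsrc\texon\t700\t820\t.\t+\t.\tID=f4;Parent=g1.t2",
    "chr1\tsrc\texon\t900\t1000\t.\t+\t.\tID=f5;Parent=g1.t2"
  ), path)
  genes <- read_gff_genes(path)
  expect_equal(genes$exon_count, 5L)
  expect_equal(genes$exons[[1]]$start[1], 100)
})

test_that("malformed GFF lines are reported with their line numbers", {
  p1 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tsrc\tgene\t500\t100\t.\t+\t.\tID=g1"),
             p1)
  expect_error(read_gff_genes(p1), "line 2")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=t1"), p2)
  expect_error(read_gff_genes(p2), "line 3.*Parent")
})

test_that("generator GFFs round-trip through the parser", {
  g <- simulate_genome_pair(n_chromosomes = 2L,
                            seed = 4)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g$genes_a, path)
  back <- read_gff_genes(path)
  expect_setequal(back$gene_id, g$genes_a$gene_id)
  ord <- match(g$genes_a$gene_id, back$gene_id)
  expect_equal(back$start[ord], g$genes_a$start)
  expect_equal(back$exon_count[ord], g$genes_a$exon_count)
  expect_equal(back$chromosome[ord], g$genes_a$chromosome)
})

test_that("ranks follow physical start order with lexicographic ties", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chromosome = "chr1",
    start = c(500, 100, 300))
  rk <- assign_gene_ranks(genes)
  expect_equal(rk$rank[match(c("g1", "g2", "g3"), rk$gene_id)], c(3L, 1L, 2L))
  two <- tibble::tibble(gene_id = c("a1", "a2", "b1"),
                        chromosome = c("c1", "c1", "c2"),
                        start = c(10, 20, 99))
  rk2 <- assign_gene_ranks(two)
  expect_equal(rk2$rank[rk2$chromosome == "c2"], 1L)
  expect_error(assign_gene_ranks(rbind(genes, genes[1, ])), "duplicate")
})

test_that("ranks equal an independent sort oracle and form a bijection", {
  set.seed(12)
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", sample(1000)),
    chromosome = sample(sprintf("chr%d", 1:5), 1000, replace = TRUE),
    start = sample.int(1e7, 1000))
  rk <- assign_gene_ranks(genes)
  for (chr in unique(genes$chromosome)) {
    sub <- rk[rk$chromosome == chr, ]
    expect_setequal(sub$rank, seq_len(nrow(sub)))  # bijection 1..n
    oracle <- sub$gene_id[order(sub$start, sub$gene_id)]
    expect_equal(sub$gene_id[order(sub$rank)], oracle)
  }
  # idempotent under re-ranking of a shuffled copy
  rk2 <- assign_gene_ranks(rk[sample(nrow(rk)), names(genes)])
  expect_equal(dplyr::arrange(rk2, gene_id), dplyr::arrange(rk, gene_id))
})

test_that("chromosome distribution counts members and keeps zero rows", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:9),
    chromosome = rep(c("chr1", "chr2", "chr3"), each = 3),
    start = rep(c(100, 200, 300), 3), end = rep(c(150, 250, 350), 3))
  dist0 <- chromosome_distribution(character(), genes)
  expect_equal(dist0$n_members, c(0L, 0L, 0L))
  dist <- chromosome_distribution(c("g01", "g02", "g07"), genes)
  expect_equal(dist$n_members[dist$chromosome == "chr1"], 2L)
  expect_equal(dist$n_members[dist$chromosome == "chr2"], 0L)
  expect_equal(sum(dist$n_members), 3L)
  expect_error(chromosome_distribution("missing", genes), "missing")
})

test_that("linked pairs match a brute-force all-pairs scan", {
  set.seed(31)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:120),
    chromosome = sample(c("c1", "c2", "c3"), 120, replace = TRUE),
    start = sample.int(1e6, 120))
  rk <- assign_gene_ranks(genes)
  members <- sample(genes$gene_id, 25)
  got <- linked_pairs(members, rk, max_rank_gap = 10L)
  # brute force O(n^2)
  oracle <- list()
  mem <- rk[rk$gene_id %in% members, ]
  for (i in seq_len(nrow(mem))) for (j in seq_len(nrow(mem))) {
    if (i >= j) next
    if (mem$chromosome[[i]] != mem$chromosome[[j]]) next
    if (abs(mem$rank[[i]] - mem$rank[[j]]) > 10) next
    oracle[[length(oracle) + 1L]] <- sort(c(mem$gene_id[[i]], mem$gene_id[[j]]))
  }
  expect_equal(nrow(got), length(oracle))
  expect_setequal(paste(got$gene_a, got$gene_b),
                  vapply(oracle, paste, "", collapse = " "))
  expect_equal(anyDuplicated(paste(got$gene_a, got$gene_b)), 0L)
  # distinct chromosomes only -> empty
  far <- tibble::tibble(gene_id = c("x", "y"), chromosome = c("c8", "c9"),
                        start = c(1, 1))
  expect_equal(nrow(linked_pairs(c("x", "y"), assign_gene_ranks(far))), 0L)
})

test_that("chromosome maps are deterministic SVG with one tick per member", {
  g <- simulate_genome_pair(n_chromosomes = 2L,
                            seed = 8)
  members <- g$genes_a$gene_id[c(3, 10, 25)]
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  render_chromosome_map(members, g$genes_a, p1)
  render_chromosome_map(members, g$genes_a, p2)
  expect_identical(readLines(p1), readLines(p2))
  svg <- readLines(p1)
  expect_equal(sum(grepl("<line ", svg)), 3L)
  expect_equal(sum(grepl("<rect ", svg)), 2L)
  empty <- withr::local_tempfile(fileext = ".svg")
  render_chromosome_map(character(), g$genes_a, empty)
  expect_equal(sum(grepl("<line ", readLines(empty))), 0L)
})
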