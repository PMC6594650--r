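# shared fixture builders; everything is generated in code at test time

aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa_seq <- function(n, g_freq = 0.07) {
  p <- rep((1 - g_freq) / 19, 20)
  p[aa20 == "G"] <- g_freq
  paste(sample(aa20, n, replace = TRUE, prob = p), collapse = "")
}

# independent exhaustive window scan: maximum G count over every window
oracle_max_gly <- function(seq, window = 20L) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  if (n < window) return(sum(chars == "G") / n)
  best <- 0
  for (s in seq_len(n - window + 1L)) {
    best <- max(best, sum(chars[s:(s + window - 1L)] == "G"))
  }
  best / window
}

# a sequence of given length whose maximum 20-window G count is exactly k,
# built by placing G's spaced so no window exceeds k
seq_with_max_g <- function(len, k, window = 20L) {
  chars <- rep("A", len)
  chars[seq_len(k)] <- "G"
  paste(chars, collapse = "")
}

# random unrooted tree with positive branch lengths (additive-matrix source)
random_additive_tree <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.6))
  ape::unroot(tr)
}

tree_distance_matrix <- function(tr) {
  d <- ape::cophenetic.phylo(tr)
  d[sort(rownames(d)), sort(rownames(d))]
}

# one domtblout-dialect data line with controllable fields
domtbl_line <- function(protein = "P1", acc = "PF00076", full_e = 1e-10,
                        i_e = 1e-10, score = 100, env = c(5L, 84L)) {
  sprintf("%s - 200 Prof %s 80 %.3g %.1f 0.0 1 1 %.3g %.3g %.1f 0.0 1 80 %d %d %d %d 0.90 -",
          protein, acc, full_e, score, i_e, i_e, score,
          env[[1]], env[[2]], env[[1]], env[[2]])
}

write_domtbl <- function(lines, path = withr::local_tempfile(fileext = ".domtbl",
                                                             .local_envir = parent.frame())) {
  writeLines(c("# comment header", lines), path)
  path
}

# minimal GFF3 with one gene, configurable mRNA/exon structure
minimal_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t100\t500\t.\t+\t.\tID=g1.t1.e1;Parent=g1.t1"
  ), path)
  path
}
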