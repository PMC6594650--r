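#' Parse a 12-column BLAST tabular file
#'
#' Standard `-outfmt 6` columns: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' E-value, bit score. Self-hits (query == subject) are dropped on ingest;
#' an optional E-value cutoff can be applied.
#'
#' @param path Path to the tabular file.
#' @param e_max Optional E-value cutoff (keep hits with `e_value <= e_max`).
#' @return Tibble with `query_gene`, `subject_gene`, `percent_identity`,
#'   `e_value`, `bit_score`.
#' @export
read_blast_tabular <- function(path, e_max = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) {
    return(tibble(query_gene = character(), subject_gene = character(),
                  percent_identity = double(), e_value = double(),
                  bit_score = double()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L) {
    abort(sprintf("BLAST table: line %d has %d columns, expected 12",
                  keep[bad[[1]]], lengths(fields)[bad[[1]]]))
  }
  out <- tibble(
    query_gene = map_chr(fields, 1L),
    subject_gene = map_chr(fields, 2L),
    percent_identity = as.numeric(map_chr(fields, 3L)),
    e_value = as.numeric(map_chr(fields, 11L)),
    bit_score = as.numeric(map_chr(fields, 12L))
  )
  out <- filter(out, .data$query_gene != .data$subject_gene)
  if (!is.null(e_max)) out <- filter(out, .data$e_value <= e_max)
  out
}

#' Write homology hits in the 12-column BLAST tabular dialect
#'
#' @param hits Tibble with at least `query_gene`, `subject_gene`; missing
#'   numeric columns are filled with plausible placeholders.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  n <- nrow(hits)
  pid <- hits$percent_identity %||% rep(90, n)
  ev <- hits$e_value %||% rep(1e-50, n)
  bs <- hits$bit_score %||% rep(200, n)
  lines <- sprintf("%s\t%s\t%.2f\t200\t10\t0\t1\t200\t1\t200\t%.3g\t%.1f",
                   hits$query_gene, hits$subject_gene, pid, ev, bs)
  writeLines(lines, path)
  invisible(path)
}

#' Detect tandem duplicate pairs
#'
#' Two genes are tandem duplicates when a homology hit connects them and
#' they sit at adjacent ranks (rank difference of exactly 1) on the same
#' chromosome. Each unordered pair is reported once.
#'
#' @param hits Tibble with `query_gene`, `subject_gene`.
#' @param ranked_genes Tibble from [assign_gene_ranks()] covering every gene
#'   appearing in `hits`.
#' @return Tibble with `gene_a`, `gene_b` (lexicographic), `chromosome`,
#'   `rank_a`, `rank_b`.
#' @export
detect_tandem_arrays <- function(hits, ranked_genes) {
  genes_in_hits <- unique(c(hits$query_gene, hits$subject_gene))
  missing <- setdiff(genes_in_hits, ranked_genes$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("detect_tandem_arrays: genes missing from rank index: %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(hits) == 0L) {
    return(tibble(gene_a = character(), gene_b = character(),
                  chromosome = character(), rank_a = integer(),
                  rank_b = integer()))
  }
  rk <- select(ranked_genes, "gene_id", "chromosome", "rank")
  hits |>
    mutate(gene_a = pmin(.data$query_gene, .data$subject_gene),
           gene_b = pmax(.data$query_gene, .data$subject_gene)) |>
    distinct(.data$gene_a, .data$gene_b) |>
    inner_join(rename(rk, gene_a = "gene_id", chrom_a = "chromosome",
                      rank_a = "rank"), by = "gene_a") |>
    inner_join(rename(rk, gene_b = "gene_id", chrom_b = "chromosome",
                      rank_b = "rank"), by = "gene_b") |>
    filter(.data$chrom_a == .data$chrom_b,
           abs(.data$rank_a - .data$rank_b) == 1L) |>
    mutate(chromosome = .data$chrom_a) |>
    select("gene_a", "gene_b", "chromosome", "rank_a", "rank_b") |>
    arrange(.data$gene_a, .data$gene_b)
}

# best-scoring chain by dynamic programming over anchors sorted by a_rank;
# transitions require strictly increasing a_rank and b_rank with both gaps
# <= max_gap; score = +1 per anchor - (skipped ranks)/max_gap
chain_dp <- function(anc, max_gap) {
  n <- nrow(anc)
  score <- rep(1, n)
  prev <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    for (l in seq_len(k - 1L)) {
      da <- anc$a_rank[[k]] - anc$a_rank[[l]]
      db <- anc$b_rank[[k]] - anc$b_rank[[l]]
      if (da <= 0L || db <= 0L || da > max_gap || db > max_gap) next
      gap <- (da - 1L) + (db - 1L)
      s <- score[[l]] + 1 - gap / max_gap
      if (s > score[[k]]) {
        score[[k]] <- s
        prev[[k]] <- l
      }
    }
  }
  best <- which.max(score)
  chain <- integer()
  k <- best
  while (!is.na(k)) {
    chain <- c(k, chain)
    k <- prev[[k]]
  }
  list(idx = chain, score = score[[best]])
}

#' Chain homology anchors into collinear blocks
#'
#' Within each chromosome pair, anchors (homology hits between a genome-A
#' and a genome-B gene, positioned by gene rank) are chained by dynamic
#' programming. Chains must be strictly monotone in both genomes — rank
#' gaps up to `max_gap` are allowed at a penalty of `gap/max_gap` per
#' skipped rank — and same-orientation and inverted chains are searched
#' separately (inversion = B-ranks strictly decreasing). Maximal-score
#' chains with at least `min_anchors` anchors are reported greedily; an
#' anchor joins at most one block per orientation.
#'
#' @param hits Tibble with `query_gene` (genome A), `subject_gene`
#'   (genome B).
#' @param ranked_a,ranked_b Rank tables from [assign_gene_ranks()] for the
#'   two genomes.
#' @param min_anchors Minimum anchors per reported block (default 5).
#' @param max_gap Maximum rank gap on either axis (default 25).
#' @return Tibble with one row per anchor: `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation` (`"same"`/`"inverted"`), `gene_a`, `gene_b`,
#'   `a_rank`, `b_rank`, `score`.
#' @export
chain_collinear_blocks <- function(hits, ranked_a, ranked_b,
                                   min_anchors = 5L, max_gap = 25L) {
  empty <- tibble(block_id = integer(), chrom_a = character(),
                  chrom_b = character(), orientation = character(),
                  gene_a = character(), gene_b = character(),
                  a_rank = integer(), b_rank = integer(), score = double())
  if (nrow(hits) == 0L) return(empty)
  rka <- select(ranked_a, gene_a = "gene_id", chrom_a = "chromosome",
                a_rank = "rank")
  rkb <- select(ranked_b, gene_b = "gene_id", chrom_b = "chromosome",
                b_rank = "rank")
  anchors <- hits |>
    distinct(gene_a = .data$query_gene, gene_b = .data$subject_gene) |>
    inner_join(rka, by = "gene_a") |>
    inner_join(rkb, by = "gene_b")
  if (nrow(anchors) == 0L) return(empty)
  blocks <- list()
  bid <- 0L
  for (ca in unique(anchors$chrom_a)) {
    for (cb in unique(anchors$chrom_b)) {
      sub <- filter(anchors, .data$chrom_a == ca, .data$chrom_b == cb)
      if (nrow(sub) < min_anchors) next
      for (orient in c("same", "inverted")) {
        pool <- arrange(sub, .data$a_rank, .data$b_rank)
        if (orient == "inverted") pool$b_rank <- -pool$b_rank
        repeat {
          if (nrow(pool) < min_anchors) break
          res <- chain_dp(pool, max_gap)
          if (length(res$idx) < min_anchors) break
          bid <- bid + 1L
          blk <- pool[res$idx, ]
          if (orient == "inverted") blk$b_rank <- -blk$b_rank
          blk$block_id <- bid
          blk$orientation <- orient
          blk$score <- res$score
          blocks[[length(blocks) + 1L]] <- blk
          pool <- pool[-res$idx, ]
        }
      }
    }
  }
  if (length(blocks) == 0L) return(empty)
  bind_rows(blocks) |>
    select("block_id", "chrom_a", "chrom_b", "orientation", "gene_a",
           "gene_b", "a_rank", "b_rank", "score") |>
    arrange(.data$block_id, .data$a_rank)
}

#' Extract ortholog pairs for family genes from collinear blocks
#'
#' For each family gene appearing as a block anchor, its candidate partners
#' are its anchor mates across all blocks; the partner with minimum Ks is
#' kept, provided Ks does not exceed the saturation guard `ks_max`.
#' One-to-many and many-to-one relations are flagged via partner
#' multiplicities. Family genes in no block are returned in the `unpaired`
#' attribute.
#'
#' @param blocks Tibble from [chain_collinear_blocks()].
#' @param family_a,family_b Character vectors of family gene ids in genomes
#'   A and B.
#' @param kaks_fn Function `(gene_a, gene_b) -> list(ka, ks, omega)`; see
#'   [make_kaks_fn()].
#' @param ks_max Saturation guard on Ks (default 3).
#' @return Tibble of class `grpfam_orthologs` with `gene_a`, `gene_b`,
#'   `ka`, `ks`, `omega`, `selection_class`, `multiplicity_a`,
#'   `multiplicity_b`; attribute `unpaired` lists family genes without a
#'   partner.
#' @export
extract_ortholog_pairs <- function(blocks, family_a, family_b, kaks_fn,
                                   ks_max = 3.0) {
  fam_anchors <- filter(blocks, .data$gene_a %in% family_a |
                          .data$gene_b %in% family_b) |>
    distinct(.data$gene_a, .data$gene_b)
  pairs <- list()
  unpaired <- character()
  for (g in sort(union(family_a, family_b))) {
    cand <- if (g %in% family_a) {
      filter(fam_anchors, .data$gene_a == g)
    } else {
      filter(fam_anchors, .data$gene_b == g)
    }
    if (nrow(cand) == 0L) {
      unpaired <- c(unpaired, g)
      next
    }
    kk <- pmap(list(cand$gene_a, cand$gene_b), function(a, b) kaks_fn(a, b))
    cand$ka <- map_dbl(kk, "ka")
    cand$ks <- map_dbl(kk, "ks")
    cand$omega <- map_dbl(kk, ~ .x$omega %||% NA_real_)
    cand <- filter(cand, .data$ks <= ks_max)
    if (nrow(cand) == 0L) {
      unpaired <- c(unpaired, g)
      next
    }
    best <- arrange(cand, .data$ks, .data$gene_a, .data$gene_b) |> slice(1L)
    pairs[[length(pairs) + 1L]] <- best
  }
  if (length(pairs) == 0L) {
    out <- tibble(gene_a = character(), gene_b = character(), ka = double(),
                  ks = double(), omega = double(),
                  selection_class = character(), multiplicity_a = integer(),
                  multiplicity_b = integer())
  } else {
    out <- bind_rows(pairs) |>
      distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
      group_by(.data$gene_a) |> mutate(multiplicity_a = n()) |> ungroup() |>
      group_by(.data$gene_b) |> mutate(multiplicity_b = n()) |> ungroup() |>
      mutate(selection_class = map_chr(.data$omega, classify_selection)) |>
      select("gene_a", "gene_b", "ka", "ks", "omega", "selection_class",
             "multiplicity_a", "multiplicity_b") |>
      arrange(.data$gene_a, .data$gene_b)
  }
  attr(out, "unpaired") <- unique(unpaired)
  class(out) <- c("grpfam_orthologs", class(out))
  out
}

#' Tandem duplication percentage
#'
#' Share of family members involved in tandem duplication, as a percentage
#' rounded to one decimal (e.g. 2 of 37 genes gives 5.4).
#'
#' @param n_tandem_genes Number of family genes in tandem duplicates.
#' @param n_family Family size.
#' @return Percentage rounded to one decimal place.
#' @export
tandem_percentage <- function(n_tandem_genes, n_family) {
  stopifnot(n_family > 0, n_tandem_genes >= 0)
  round(100 * n_tandem_genes / n_family, 1)
}
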