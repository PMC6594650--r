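#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon features and aggregates, for each gene, the exons of
#' its longest mRNA (longest by summed exon length, matching the
#' longest-isoform rule used for proteomes; ties broken by mRNA id). All
#' coordinates are 1-based inclusive, the native GFF3 convention.
#'
#' A structural pre-scan reports malformed lines (wrong column count,
#' `end < start`, mRNA/exon without a `Parent`) with their line numbers
#' before the file is imported.
#'
#' @param path GFF3 file path.
#' @return Tibble with `gene_id`, `chromosome`, `start`, `end`, `strand`,
#'   `exon_count`, and a list-column `exons` of (start, end) tibbles sorted
#'   by start.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("GFF not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      abort(sprintf("GFF line %d: expected 9 tab-separated columns, got %d",
                    i, length(f)))
    }
    st <- suppressWarnings(as.numeric(f[[4]]))
    en <- suppressWarnings(as.numeric(f[[5]]))
    if (is.na(st) || is.na(en) || en < st) {
      abort(sprintf("GFF line %d: invalid coordinates (%s, %s)",
                    i, f[[4]], f[[5]]))
    }
    if (f[[3]] %in% c("mRNA", "exon") && !grepl("Parent=", f[[9]])) {
      abort(sprintf("GFF line %d: %s feature without Parent attribute",
                    i, f[[3]]))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  get_parent <- function(p) map_chr(p, ~ if (length(.x) == 0L) NA_character_
                                    else .x[[1]])
  genes <- meta[meta$type == "gene", ]
  mrnas <- meta[meta$type == "mRNA", ]
  exons <- meta[meta$type == "exon", ]
  mrnas$parent_gene <- get_parent(mrnas$Parent)
  exons$parent_mrna <- get_parent(exons$Parent)

  exon_by_mrna <- split(exons[, c("start", "end")], exons$parent_mrna)
  gene_rows <- map(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[[i]]
    mr <- mrnas[!is.na(mrnas$parent_gene) & mrnas$parent_gene == gid, ]
    if (nrow(mr) == 0L) {
      ex <- tibble(start = genes$start[[i]], end = genes$end[[i]])
    } else {
      lens <- map_dbl(mr$ID, function(mid) {
        e <- exon_by_mrna[[mid]]
        if (is.null(e)) 0 else sum(e$end - e$start + 1)
      })
      best <- mr$ID[order(-lens, mr$ID)][[1]]
      e <- exon_by_mrna[[best]]
      ex <- if (is.null(e)) tibble(start = mr$start[[1]], end = mr$end[[1]])
            else as_tibble(e[order(e$start), ])
    }
    list(gene_id = gid, chromosome = as.character(genes$seqnames[[i]]),
         start = genes$start[[i]], end = genes$end[[i]],
         strand = as.character(genes$strand[[i]]), exons = ex)
  })
  tibble(
    gene_id = map_chr(gene_rows, "gene_id"),
    chromosome = map_chr(gene_rows, "chromosome"),
    start = map_dbl(gene_rows, "start"),
    end = map_dbl(gene_rows, "end"),
    strand = map_chr(gene_rows, "strand"),
    exon_count = map_int(gene_rows, ~ nrow(.x$exons)),
    exons = map(gene_rows, "exons")
  )
}

#' Number of exons of a gene model
#'
#' @param gene One row of the tibble from [read_gff_genes()] (or the whole
#'   tibble, in which case a vector is returned).
#' @return Integer exon count(s).
#' @export
exon_count <- function(gene) {
  gene$exon_count
}

#' Assign per-chromosome gene ranks
#'
#' Ranks are 1-based positions in the start-coordinate order of each
#' chromosome (ties broken lexicographically by gene id); they are the
#' substrate of the tandem-duplicate rule (rank difference of 1). Strand is
#' ignored: physical order only.
#'
#' @param genes Tibble with `gene_id`, `chromosome`, `start`.
#' @return The input with an added integer `rank` column.
#' @export
assign_gene_ranks <- function(genes) {
  if (anyDuplicated(genes$gene_id)) {
    abort("assign_gene_ranks: duplicate gene ids")
  }
  genes |>
    group_by(.data$chromosome) |>
    arrange(.data$start, .data$gene_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    arrange(.data$chromosome, .data$rank)
}

#' Per-chromosome counts of family members
#'
#' @param members Character vector of family gene ids.
#' @param genes Tibble from [read_gff_genes()] (all genes of the genome).
#' @return Tibble with `chromosome`, `n_members`, including zero-count
#'   chromosomes present in the gene set.
#' @export
chromosome_distribution <- function(members, genes) {
  missing <- setdiff(members, genes$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("chromosome_distribution: ids missing from gene set: %s",
                  paste(missing, collapse = ", ")))
  }
  chroms <- sort(unique(genes$chromosome))
  hits <- filter(genes, .data$gene_id %in% members)
  counts <- table(factor(hits$chromosome, levels = chroms))
  tibble(chromosome = chroms, n_members = as.integer(counts))
}

#' Pairs of family members linked on a chromosome
#'
#' Reports each unordered pair of family members that sit on the same
#' chromosome within `max_rank_gap` gene ranks of each other. Set
#' `max_rank_gap = 1` to restrict to immediate neighbours.
#'
#' @param members Character vector of family gene ids.
#' @param ranked_genes Tibble from [assign_gene_ranks()].
#' @param max_rank_gap Maximum allowed rank difference (default 10).
#' @return Tibble with `gene_a`, `gene_b` (lexicographically ordered),
#'   `chromosome`, `rank_gap`.
#' @export
linked_pairs <- function(members, ranked_genes, max_rank_gap = 10L) {
  mem <- filter(ranked_genes, .data$gene_id %in% members)
  out <- tibble(gene_a = character(), gene_b = character(),
                chromosome = character(), rank_gap = integer())
  if (nrow(mem) < 2L) return(out)
  pairs <- list()
  for (chr in unique(mem$chromosome)) {
    m <- filter(mem, .data$chromosome == chr)
    if (nrow(m) < 2L) next
    idx <- utils::combn(nrow(m), 2L)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1L, k]; j <- idx[2L, k]
      gap <- abs(m$rank[[i]] - m$rank[[j]])
      if (gap <= max_rank_gap) {
        g <- sort(c(m$gene_id[[i]], m$gene_id[[j]]))
        pairs[[length(pairs) + 1L]] <-
          tibble(gene_a = g[[1]], gene_b = g[[2]], chromosome = chr,
                 rank_gap = as.integer(gap))
      }
    }
  }
  if (length(pairs) == 0L) return(out)
  bind_rows(pairs) |> distinct() |> arrange(.data$gene_a, .data$gene_b)
}

#' Render a chromosome map of family members as SVG
#'
#' Draws one vertical bar per chromosome, scaled to its length (maximum gene
#' end), with a tick per family member at its scaled start position. Output
#' is deterministic: identical input yields byte-identical SVG.
#'
#' @param members Character vector of family gene ids.
#' @param genes Tibble from [read_gff_genes()].
#' @param path Output SVG path.
#' @return `path`, invisibly.
#' @export
render_chromosome_map <- function(members, genes, path) {
  chroms <- sort(unique(genes$chromosome))
  chrom_len <- map_dbl(chroms, ~ max(genes$end[genes$chromosome == .x]))
  max_len <- max(chrom_len)
  bar_w <- 18; gap <- 50; top <- 30; height <- 400
  width <- gap * (length(chroms) + 1L)
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height + 2L * top),
    '<style>text{font-family:sans-serif;font-size:10px;}</style>'
  )
  for (i in seq_along(chroms)) {
    x <- gap * i - bar_w / 2
    h <- height * chrom_len[[i]] / max_len
    svg <- c(svg, sprintf(
      '<rect x="%.1f" y="%d" width="%d" height="%.1f" rx="8" fill="#d9d9d9" stroke="#555"/>',
      x, top, bar_w, h))
    svg <- c(svg, sprintf('<text x="%.1f" y="%d" text-anchor="middle">%s</text>',
                          gap * i, top + as.integer(height) + 15L, chroms[[i]]))
    mem <- genes[genes$gene_id %in% members &
                   genes$chromosome == chroms[[i]], , drop = FALSE]
    if (nrow(mem) > 0L) {
      mem <- mem[order(mem$start, mem$gene_id), , drop = FALSE]
      for (j in seq_len(nrow(mem))) {
        y <- top + h * mem$start[[j]] / chrom_len[[i]]
        svg <- c(svg, sprintf(
          '<line x1="%.1f" y1="%.2f" x2="%.1f" y2="%.2f" stroke="#c0392b" stroke-width="2"/>',
          x, y, x + bar_w, y))
        svg <- c(svg, sprintf('<text x="%.1f" y="%.2f">%s</text>',
                              x + bar_w + 3, y + 3, mem$gene_id[[j]]))
      }
    }
  }
  svg <- c(svg, "</svg>")
  writeLines(svg, path)
  invisible(path)
}
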