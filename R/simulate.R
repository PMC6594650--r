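# Seeded synthetic inputs with planted ground truth for every pipeline
# stage. Each generator draws from its own RNG stream derived from
# (seed, generator name), so adding a generator never perturbs the others.

derive_stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483646) + 1L
}

# background amino-acid frequencies: glycine at ~7% (proteome-typical),
# the rest uniform, so domain-only decoys are non-trivially hard
bg_aa_probs <- function(g_freq = 0.07) {
  p <- rep((1 - g_freq) / 19, 20)
  names(p) <- AA20
  p[["G"]] <- g_freq
  p
}

random_peptide <- function(n, probs = bg_aa_probs()) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# force the maximum G count of any `window`-length stretch to at most max_g
cap_glycine <- function(seq, window = 20L, max_g = 9L) {
  repeat {
    prof <- glycine_profile(seq, window, threshold = 0)
    cnt <- round(prof$max_window_fraction * min(window, nchar(seq)))
    if (cnt <= max_g) return(seq)
    start <- prof$best_window_start
    win <- str_sub(seq, start, min(start + window - 1L, nchar(seq)))
    gpos <- which(strsplit(win, "")[[1]] == "G")
    hit <- start + gpos[[1L]] - 1L
    str_sub(seq, hit, hit) <- "A"
  }
}

# a 20-mer with exactly n_g glycines at random positions
glycine_window <- function(n_g = 14L, window = 20L) {
  chars <- sample(setdiff(AA20, "G"), window, replace = TRUE)
  chars[sample.int(window, n_g)] <- "G"
  paste(chars, collapse = "")
}

ARCH_BY_CLASS <- list(
  IVa = c("RRM"),
  IVb = c("RRM", "ZnF_CCHC"),
  IVc = c("CSD", "ZnF_CCHC", "ZnF_CCHC"),
  IVd = c("RRM", "RRM")
)
DOMAIN_LEN <- c(RRM = 80L, CSD = 65L, ZnF_CCHC = 18L, ZnF_RanBP2 = 24L)
DOMAIN_ACC <- c(RRM = "PF00076", CSD = "PF00313", ZnF_CCHC = "PF00098",
                ZnF_RanBP2 = "PF00641")

#' Simulate a proteome with planted family members and decoys
#'
#' Builds background proteins at proteome-typical glycine frequency, plants
#' family members of the requested class mix (domain envelopes laid out
#' left to right per class architecture, plus a glycine-rich 20-residue
#' window outside the envelopes), and two kinds of decoys: domain hits
#' without glycine richness (their windows are capped at 9 G per 20), and
#' glycine-rich proteins without an RRM/CSD hit. Domain-table rows carry
#' E-values below the mining threshold for planted hits; a configurable
#' fraction of extra noise rows sits above it.
#'
#' @param n_family Named integer vector: members per class, e.g.
#'   `c(IVa = 4, IVb = 3, IVc = 2, IVd = 3)`.
#' @param n_decoy_domain,n_decoy_glycine,n_background Decoy and background
#'   counts.
#' @param gly_window_g Glycines planted in each member's 20-residue window
#'   (default 14; must be >= 11 to pass the strict > 50% filter).
#' @param noise_rows Extra domain-table rows with E-values above 1e-4.
#' @param seed Integer seed.
#' @return List with `proteome` (tibble as [read_proteome()]),
#'   `domain_hits` (tibble as [read_domain_table()]) and `truth`
#'   (tibble: `protein_id`, `gene_id`, `role`, `family_class`,
#'   `gly_window_start`).
#' @export
simulate_proteome <- function(n_family = c(IVa = 4L, IVb = 3L, IVc = 2L,
                                           IVd = 3L),
                              n_decoy_domain = 4L, n_decoy_glycine = 4L,
                              n_background = 30L, gly_window_g = 14L,
                              noise_rows = 0L, seed = 1L) {
  set.seed(derive_stream_seed(seed, "proteome"))
  probs <- bg_aa_probs()
  proteins <- list(); hits <- list(); truth <- list()
  ev_low <- function() 10^(-runif(1, 6, 30))   # below the 1e-4 threshold
  ev_high <- function() 10^(-runif(1, 0, 3.5)) # above it

  add_member <- function(pid, cls) {
    arch <- ARCH_BY_CLASS[[cls]]
    parts <- random_peptide(sample(10:25, 1), probs)
    envs <- list()
    for (dom in arch) {
      start <- nchar(parts) + 1L
      parts <- paste0(parts, random_peptide(DOMAIN_LEN[[dom]], probs))
      envs[[length(envs) + 1L]] <- list(domain = dom, start = start,
                                        end = nchar(parts))
      parts <- paste0(parts, random_peptide(sample(10:20, 1), probs))
    }
    gly_start <- nchar(parts) + 1L
    parts <- paste0(parts, glycine_window(gly_window_g))
    parts <- paste0(parts, random_peptide(sample(10:30, 1), probs))
    proteins[[length(proteins) + 1L]] <<-
      tibble(protein_id = pid, gene_id = pid, sequence = parts,
             length = nchar(parts))
    for (e in envs) {
      hits[[length(hits) + 1L]] <<- tibble(
        protein_id = pid, accession = DOMAIN_ACC[[e$domain]],
        domain_class = e$domain, env_start = e$start, env_end = e$end,
        full_seq_evalue = ev_low(), domain_ievalue = ev_low(),
        bit_score = round(runif(1, 50, 300), 1))
    }
    truth[[length(truth) + 1L]] <<-
      tibble(protein_id = pid, gene_id = pid, role = "member",
             family_class = cls, gly_window_start = gly_start)
  }

  k <- 0L
  for (cls in names(n_family)) {
    for (i in seq_len(n_family[[cls]])) {
      k <- k + 1L
      add_member(sprintf("FAM%03d", k), cls)
    }
  }
  for (i in seq_len(n_decoy_domain)) {
    pid <- sprintf("DECA%02d", i)
    seq <- cap_glycine(random_peptide(sample(150:300, 1), probs))
    start <- sample(10:40, 1)
    proteins[[length(proteins) + 1L]] <- tibble(
      protein_id = pid, gene_id = pid, sequence = seq, length = nchar(seq))
    hits[[length(hits) + 1L]] <- tibble(
      protein_id = pid, accession = "PF00076", domain_class = "RRM",
      env_start = start, env_end = start + 79L,
      full_seq_evalue = ev_low(), domain_ievalue = ev_low(),
      bit_score = round(runif(1, 50, 300), 1))
    truth[[length(truth) + 1L]] <- tibble(
      protein_id = pid, gene_id = pid, role = "decoy_domain",
      family_class = NA_character_, gly_window_start = NA_integer_)
  }
  for (i in seq_len(n_decoy_glycine)) {
    pid <- sprintf("DECB%02d", i)
    seq <- paste0(random_peptide(sample(40:120, 1), probs),
                  glycine_window(gly_window_g),
                  random_peptide(sample(40:120, 1), probs))
    proteins[[length(proteins) + 1L]] <- tibble(
      protein_id = pid, gene_id = pid, sequence = seq, length = nchar(seq))
    truth[[length(truth) + 1L]] <- tibble(
      protein_id = pid, gene_id = pid, role = "decoy_glycine",
      family_class = NA_character_, gly_window_start = NA_integer_)
  }
  for (i in seq_len(n_background)) {
    pid <- sprintf("BG%03d", i)
    seq <- random_peptide(sample(100:400, 1), probs)
    proteins[[length(proteins) + 1L]] <- tibble(
      protein_id = pid, gene_id = pid, sequence = seq, length = nchar(seq))
    truth[[length(truth) + 1L]] <- tibble(
      protein_id = pid, gene_id = pid, role = "background",
      family_class = NA_character_, gly_window_start = NA_integer_)
  }
  proteome <- bind_rows(proteins)
  for (i in seq_len(noise_rows)) {
    pid <- sample(proteome$protein_id, 1)
    start <- sample(5:60, 1)
    hits[[length(hits) + 1L]] <- tibble(
      protein_id = pid, accession = "PF00076", domain_class = "RRM",
      env_start = start, env_end = start + 79L,
      full_seq_evalue = ev_high(), domain_ievalue = ev_high(),
      bit_score = round(runif(1, 5, 25), 1))
  }
  domain_hits <- if (length(hits) > 0L) bind_rows(hits) else
    tibble(protein_id = character(), accession = character(),
           domain_class = character(), env_start = integer(),
           env_end = integer(), full_seq_evalue = double(),
           domain_ievalue = double(), bit_score = double())
  list(proteome = proteome, domain_hits = domain_hits, truth = bind_rows(truth))
}

# partition a gene span into n_exons non-overlapping intervals
make_exons <- function(start, end, n_exons) {
  span <- end - start + 1
  if (n_exons == 1L) return(tibble(start = start, end = end))
  cuts <- sort(sample(seq_len(span - 1L), 2L * n_exons - 2L))
  bounds <- c(0L, cuts, span)
  idx <- seq(1L, length(bounds) - 1L, by = 2L)
  tibble(start = start + bounds[idx],
         end = start + bounds[idx + 1L] - 1L)
}

#' Simulate a pair of genomes with planted collinear blocks and tandems
#'
#' Genome A holds `genes_per_chromosome` ordered genes per chromosome.
#' Genome B chromosomes are built by copying ordered A segments (the planted
#' collinear blocks, the second of each chromosome inverted), interleaved
#' with unique B genes; at `gap_rate` an orthologous copy is skipped.
#' Selected A genes outside blocks are duplicated at adjacent ranks in B
#' (the planted tandem pairs, connected by a within-B homology hit).
#' Homology hits are emitted for every surviving ortholog pair plus
#' `noise_hits` uniform random non-orthologous A-B pairs. CDS are generated
#' for each ortholog pair by evolving an ancestral coding sequence at the
#' stated `omega_true` and divergence.
#'
#' @param n_chromosomes Chromosomes per genome (default 3).
#' @param genes_per_chromosome Genes per A chromosome (default 40).
#' @param block_length Genes per planted collinear block (default 8).
#' @param n_tandem Planted tandem pairs in genome B (default 3).
#' @param gap_rate Per-gene probability of dropping an orthologous copy
#'   inside a block (default 0).
#' @param noise_hits Random spurious A-B hits (default 0).
#' @param omega_true,t Codon-evolution parameters for ortholog CDS
#'   (defaults 0.2 and 0.1 proposals/site).
#' @param cds_codons CDS length in codons (default 100).
#' @param seed Integer seed.
#' @return List with `genes_a`, `genes_b` (tibbles as [read_gff_genes()]),
#'   `ortholog_hits` (A-B), `paralog_hits_b` (B-B), `cds_a`, `cds_b`
#'   (named vectors) and `truth` (list: `blocks`, `tandem_pairs`,
#'   `ortholog_map`).
#' @export
simulate_genome_pair <- function(n_chromosomes = 3L,
                                 genes_per_chromosome = 40L,
                                 block_length = 8L, n_tandem = 3L,
                                 gap_rate = 0, noise_hits = 0L,
                                 omega_true = 0.2, t = 0.1,
                                 cds_codons = 100L, seed = 1L) {
  set.seed(derive_stream_seed(seed, "genomes"))
  if (2L * block_length + 21L > genes_per_chromosome) {
    abort("simulate_genome_pair: blocks longer than chromosome allows")
  }
  genes_a <- list(); genes_b <- list()
  blocks_truth <- list(); tandem_truth <- list(); ortho_map <- list()
  a_gene <- function(chrom, i) sprintf("A_%s_g%03d", chrom, i)

  new_gene_row <- function(gid, chrom, idx) {
    start <- idx * 5000
    end <- start + sample(1200:3000, 1)
    n_ex <- sample(1:8, 1)
    tibble(gene_id = gid, chromosome = chrom, start = start, end = end,
           strand = sample(c("+", "-"), 1), exon_count = n_ex,
           exons = list(make_exons(start, end, n_ex)))
  }

  # pre-assign tandem sources: A genes at ranks 1-5 (outside every block);
  # their duplicated copies are planted between the two block segments so
  # they cannot extend either chain
  all_chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  src_pool <- unlist(map(all_chroms, function(ch) sprintf("A_%s_g%03d", ch, 1:5)))
  chosen <- sample(src_pool, min(n_tandem, length(src_pool)))
  paralog_hits <- list()
  for (c_i in seq_len(n_chromosomes)) {
    chrom <- all_chroms[[c_i]]
    for (i in seq_len(genes_per_chromosome)) {
      genes_a[[length(genes_a) + 1L]] <- new_gene_row(a_gene(chrom, i), chrom, i)
    }
    # B chromosome: unique - block(same) - unique - block(inverted) - unique
    b_idx <- 0L; b_id <- function() {
      b_idx <<- b_idx + 1L
      sprintf("B_%s_g%03d", chrom, b_idx)
    }
    add_b <- function(src_a = NA_character_) {
      gid <- b_id()
      genes_b[[length(genes_b) + 1L]] <<- new_gene_row(gid, chrom, b_idx)
      if (!is.na(src_a)) {
        ortho_map[[length(ortho_map) + 1L]] <<-
          tibble(gene_a = src_a, gene_b = gid)
      }
      gid
    }
    block_starts <- c(6L, 6L + block_length + 15L)
    for (u in 1:5) add_b()
    for (bk in 1:2) {
      a_ranks <- block_starts[[bk]]:(block_starts[[bk]] + block_length - 1L)
      if (bk == 2L) a_ranks <- rev(a_ranks)  # inverted block
      anchors <- list()
      for (r in a_ranks) {
        if (runif(1) < gap_rate) next
        gid <- add_b(src_a = a_gene(chrom, r))
        anchors[[length(anchors) + 1L]] <-
          tibble(gene_a = a_gene(chrom, r), gene_b = gid)
      }
      if (length(anchors) > 0L) {
        blocks_truth[[length(blocks_truth) + 1L]] <-
          mutate(bind_rows(anchors), chrom_a = chrom, chrom_b = chrom,
                 inverted = (bk == 2L))
      }
      if (bk == 1L) {
        # tandem pairs for this chromosome: adjacent duplicated copies of
        # an A source gene, placed between the two block segments
        for (src in chosen[startsWith(chosen, paste0("A_", chrom, "_"))]) {
          g1 <- add_b(src_a = src)
          g2 <- add_b(src_a = src)
          paralog_hits[[length(paralog_hits) + 1L]] <-
            tibble(query_gene = g1, subject_gene = g2)
          tandem_truth[[length(tandem_truth) + 1L]] <-
            tibble(gene_a = g1, gene_b = g2, chromosome = chrom)
        }
        for (u in 1:5) add_b()
      }
    }
    for (u in 1:5) add_b()
  }
  genes_a <- bind_rows(genes_a)
  genes_b <- bind_rows(genes_b)
  ortho_map <- bind_rows(ortho_map)

  ortholog_hits <- tibble(query_gene = ortho_map$gene_a,
                          subject_gene = ortho_map$gene_b,
                          percent_identity = round(runif(nrow(ortho_map), 80, 99), 2),
                          e_value = 10^(-runif(nrow(ortho_map), 20, 120)),
                          bit_score = round(runif(nrow(ortho_map), 150, 900), 1))
  if (noise_hits > 0L) {
    non_pairs <- list()
    while (length(non_pairs) < noise_hits) {
      qa <- sample(genes_a$gene_id, 1)
      sb <- sample(genes_b$gene_id, 1)
      if (any(ortho_map$gene_a == qa & ortho_map$gene_b == sb)) next
      non_pairs[[length(non_pairs) + 1L]] <-
        tibble(query_gene = qa, subject_gene = sb,
               percent_identity = round(runif(1, 30, 60), 2),
               e_value = 10^(-runif(1, 3, 10)),
               bit_score = round(runif(1, 40, 80), 1))
    }
    ortholog_hits <- bind_rows(ortholog_hits, bind_rows(non_pairs))
  }
  paralog_hits_b <- if (length(paralog_hits) > 0L) {
    mutate(bind_rows(paralog_hits),
           percent_identity = 95, e_value = 1e-100, bit_score = 500)
  } else {
    tibble(query_gene = character(), subject_gene = character(),
           percent_identity = double(), e_value = double(),
           bit_score = double())
  }

  # CDS per ortholog pair: shared ancestor for tandem-duplicated copies
  cds_a <- character(); cds_b <- character()
  for (ga in unique(ortho_map$gene_a)) {
    pair_seed <- derive_stream_seed(seed, paste0("cds_", ga))
    partners <- ortho_map$gene_b[ortho_map$gene_a == ga]
    sim <- simulate_codon_pair(cds_codons, omega_true, t, seed = pair_seed)
    cds_a[[ga]] <- sim$seq_a
    cds_b[[partners[[1]]]] <- sim$seq_b
    if (length(partners) > 1L) {
      for (p in partners[-1]) {
        sim2 <- simulate_codon_pair(cds_codons, omega_true, t,
                                    seed = pair_seed + 7L)
        cds_b[[p]] <- sim2$seq_b
      }
    }
  }
  list(genes_a = genes_a, genes_b = genes_b, ortholog_hits = ortholog_hits,
       paralog_hits_b = paralog_hits_b, cds_a = cds_a, cds_b = cds_b,
       truth = list(blocks = bind_rows(blocks_truth),
                    tandem_pairs = bind_rows(tandem_truth),
                    ortholog_map = ortho_map))
}

#' Simulate a diverged codon pair with known selective regime
#'
#' Draws an ancestor of uniform sense codons and evolves a descendant by
#' per-site nucleotide proposals (Poisson with mean `t` per site); proposals
#' creating stop codons are rejected, synonymous changes are always
#' accepted, nonsynonymous changes are accepted with probability
#' `omega_true`.
#'
#' @param length_codons Number of codons.
#' @param omega_true Acceptance probability for nonsynonymous changes.
#' @param t Expected proposals per nucleotide site (default 0.21, which
#'   lands the realized synonymous divergence near Ks of 0.2).
#' @param seed Integer seed.
#' @return List with `seq_a` (ancestor), `seq_b` (descendant) and `truth`
#'   (`n_syn`, `n_nonsyn` realized substitutions, `omega_true`, `t`).
#' @export
simulate_codon_pair <- function(length_codons, omega_true, t = 0.21,
                                seed = 1L) {
  stopifnot(length_codons >= 1L, t >= 0, omega_true >= 0)
  set.seed(derive_stream_seed(seed, "codons"))
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  anc <- sample(sense, length_codons, replace = TRUE)
  der <- matrix(unlist(strsplit(anc, "")), nrow = 3)
  n_syn <- 0L; n_nonsyn <- 0L
  n_prop <- rpois(3L * length_codons, t)
  for (site in which(n_prop > 0L)) {
    codon_i <- (site - 1L) %/% 3L + 1L
    pos <- (site - 1L) %% 3L + 1L
    for (rep_i in seq_len(n_prop[[site]])) {
      cur <- der[, codon_i]
      nt <- sample(setdiff(NTS, cur[[pos]]), 1L)
      cand <- cur
      cand[[pos]] <- nt
      aa_cur <- codon_aa(paste(cur, collapse = ""))
      aa_new <- codon_aa(paste(cand, collapse = ""))
      if (aa_new == "*") next
      if (aa_new == aa_cur) {
        der[, codon_i] <- cand
        n_syn <- n_syn + 1L
      } else if (runif(1) < omega_true) {
        der[, codon_i] <- cand
        n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  list(seq_a = paste(anc, collapse = ""),
       seq_b = paste(der, collapse = ""),
       truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn,
                    omega_true = omega_true, t = t))
}

#' Simulate an alignment along a tree under a Poisson substitution model
#'
#' Sites evolve independently: along a branch of length `b`, the number of
#' substitutions is Poisson(`b`), each replacing the residue with a
#' uniformly random different one — the model whose pairwise distances the
#' Poisson correction `-ln(1 - p)` (approximately) linearizes.
#'
#' @param tree A `phylo` with branch lengths.
#' @param n_sites Alignment columns.
#' @param seed Integer seed.
#' @return Alignment tibble (`name`, `row`) over the tree's tips.
#' @export
simulate_alignment_on_tree <- function(tree, n_sites, seed = 1L) {
  set.seed(derive_stream_seed(seed, "alignment"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(AA20, n_sites, replace = TRUE)
  edge_order <- order(tree$edge[, 1])  # parents before children (root first)
  # traverse edges in preorder: repeatedly process edges whose parent is done
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining) > 0L) {
    ready <- remaining[!map_lgl(tree$edge[remaining, 1],
                                ~ is.null(seqs[[.x]]))]
    for (e in ready) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      len <- tree$edge.length[[e]]
      s <- seqs[[parent]]
      nsub <- rpois(n_sites, len)
      for (site in which(nsub > 0L)) {
        for (k in seq_len(nsub[[site]])) {
          s[[site]] <- sample(setdiff(AA20, s[[site]]), 1L)
        }
      }
      seqs[[child]] <- s
    }
    remaining <- setdiff(remaining, ready)
  }
  tibble(name = tree$tip.label,
         row = map_chr(seq_len(ntip), ~ paste(seqs[[.x]], collapse = "")))
}

#' Simulate a qPCR Ct table with known per-sample effects
#'
#' The reference gene's Ct is a constant plus Gaussian noise in every
#' sample; each target gene's Ct is its baseline minus the sample's planted
#' log2 effect plus noise, so the recoverable log2 fold change equals the
#' planted effect.
#'
#' @param effects Named numeric vector of log2 fold effects per sample (the
#'   control sample must be present with effect 0), or a matrix with one
#'   row per target gene (rownames = genes, colnames = samples).
#' @param control_sample Name of the calibrator sample.
#' @param noise_sd Gaussian Ct noise standard deviation (default 0.2).
#' @param replicates Technical replicates per (gene, sample) (default 3).
#' @param reference_gene Reference gene name (default `"actin"`).
#' @param baseline_ct Target-gene baseline Ct (default 25).
#' @param reference_ct Reference-gene Ct (default 20).
#' @param seed Integer seed.
#' @return List with `ct_table` (tibble: `sample`, `gene`, `replicate`,
#'   `ct`) and `truth` (tibble: `gene`, `sample`, `log2_effect`).
#' @export
simulate_ct_table <- function(effects, control_sample, noise_sd = 0.2,
                              replicates = 3L, reference_gene = "actin",
                              baseline_ct = 25, reference_ct = 20,
                              seed = 1L) {
  set.seed(derive_stream_seed(seed, "ct"))
  if (is.null(dim(effects))) {
    effects <- matrix(effects, nrow = 1,
                      dimnames = list("target", names(effects)))
  }
  samples <- colnames(effects)
  if (!control_sample %in% samples) {
    abort("simulate_ct_table: control sample missing from effects")
  }
  rows <- list(); truth <- list()
  for (s in samples) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- tibble(
        sample = s, gene = reference_gene, replicate = r,
        ct = reference_ct + rnorm(1, 0, noise_sd))
    }
    for (g in rownames(effects)) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- tibble(
          sample = s, gene = g, replicate = r,
          ct = baseline_ct - effects[g, s] + rnorm(1, 0, noise_sd))
      }
      truth[[paste(g, s)]] <- tibble(gene = g, sample = s,
                                     log2_effect = effects[g, s])
    }
  }
  list(ct_table = bind_rows(rows), truth = bind_rows(truth))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon features (one mRNA per gene) so the output
#' round-trips through [read_gff_genes()]. Coordinates are 1-based
#' inclusive.
#'
#' @param genes Tibble with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` and list-column `exons`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chromosome, as.integer(g$start), as.integer(g$end),
                       g$strand, g$gene_id), con)
    mid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chromosome, as.integer(g$start), as.integer(g$end),
                       g$strand, mid, g$gene_id), con)
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf(
        "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g$chromosome, as.integer(ex$start[[j]]), as.integer(ex$end[[j]]),
        g$strand, mid, j, mid), con)
    }
  }
  invisible(path)
}

#' Write a Ct table as TSV
#'
#' @param ct_table Tibble with `sample`, `gene`, `replicate`, `ct`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct_table, path) {
  readr::write_tsv(ct_table, path)
  invisible(path)
}

#' Read a long-format Ct table
#'
#' @param path TSV with columns `sample`, `gene`, `replicate`, `ct`.
#' @return Tibble with those columns.
#' @export
read_ct_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(out))) {
    abort(sprintf("read_ct_table: missing columns: %s",
                  paste(setdiff(need, names(out)), collapse = ", ")))
  }
  out
}
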