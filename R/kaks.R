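# Nei-Gojobori (1986) counting with Jukes-Cantor correction.
#
# Site fractions and pathway-averaged difference counts are precomputed per
# codon (pair) in a package-level cache, one table per stop-handling mode.

.ng86_cache <- new.env(parent = emptyenv())

NTS <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# per-codon synonymous site count; with stop exclusion the per-position
# denominator shrinks to the non-stop changes (renormalization keeps S+N=3)
ng86_syn_sites <- function(exclude_stops) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  out <- setNames(numeric(length(sense)), sense)
  for (codon in sense) {
    aa0 <- codon_aa(codon)
    chars <- strsplit(codon, "", fixed = TRUE)[[1]]
    s_total <- 0
    for (pos in 1:3) {
      s_pos <- 0; v_pos <- 0
      for (nt in setdiff(NTS, chars[[pos]])) {
        mut <- chars
        mut[[pos]] <- nt
        mut_codon <- paste(mut, collapse = "")
        aa1 <- codon_aa(mut_codon)
        if (aa1 == "*" && exclude_stops) next
        v_pos <- v_pos + 1
        if (aa1 == aa0) s_pos <- s_pos + 1
      }
      if (exclude_stops) {
        if (v_pos > 0) s_total <- s_total + s_pos / v_pos
      } else {
        s_total <- s_total + s_pos / 3
      }
    }
    out[[codon]] <- s_total
  }
  out
}

# pathway-averaged (syn, nonsyn) difference counts between two sense codons;
# pathways through stop codons are excluded (fallback: all pathways when
# every ordering is blocked), or allowed when exclude_stops is FALSE
ng86_path_diffs <- function(c1, c2, exclude_stops) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a <- strsplit(c1, "", fixed = TRUE)[[1]]
  b <- strsplit(c2, "", fixed = TRUE)[[1]]
  pos <- which(a != b)
  perms <- if (length(pos) == 1L) list(pos) else {
    pr <- list()
    permute <- function(v, acc) {
      if (length(v) == 0L) { pr[[length(pr) + 1L]] <<- acc; return() }
      for (i in seq_along(v)) permute(v[-i], c(acc, v[[i]]))
    }
    permute(pos, integer())
    pr
  }
  score_path <- function(order, allow_stops) {
    cur <- a
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[[p]] <- b[[p]]
      aa_cur <- codon_aa(paste(cur, collapse = ""))
      aa_nxt <- codon_aa(paste(nxt, collapse = ""))
      if (aa_nxt == "*" && !allow_stops) {
        return(NULL)  # pathway passes through a stop codon
      }
      if (identical(aa_cur, aa_nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  scored <- purrr::compact(map(perms, score_path,
                               allow_stops = !exclude_stops))
  if (length(scored) == 0L) {
    scored <- map(perms, score_path, allow_stops = TRUE)
  }
  Reduce(`+`, scored) / length(scored)
}

ng86_tables <- function(exclude_stops) {
  key <- if (exclude_stops) "exclude" else "nonsyn"
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  syn <- ng86_syn_sites(exclude_stops)
  diffs <- new.env(parent = emptyenv())
  tabs <- list(syn = syn, diffs = diffs, sense = sense,
               exclude_stops = exclude_stops)
  .ng86_cache[[key]] <- tabs
  tabs
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences) and differences by averaging over all orderings of the
#' substitution pathway between differing codons. By default mutations to
#' stop codons are excluded from the site fractions (with per-position
#' renormalization, so S + N remains 3 per codon) and pathways through stop
#' codons are discarded; set `stop_handling = "nonsyn"` to count them as
#' nonsynonymous instead. The proportions `ps = Sd/S` and `pn = Nd/N` are
#' Jukes-Cantor corrected, `d = -(3/4) ln(1 - (4/3) p)`, giving Ks and Ka.
#'
#' @param seq_a,seq_b Equal-length gap-free nucleotide strings over ACGT,
#'   length divisible by 3, no internal stop codons (a shared terminal stop
#'   is trimmed).
#' @param stop_handling `"exclude"` (default) or `"nonsyn"`.
#' @return A list: `ka`, `ks`, `omega` (`NA` when Ks = 0), `s_sites`,
#'   `n_sites`, `sd`, `nd`, `ps`, `pn`.
#' @export
#' @examples
#' ng86_kaks(strrep("GCT", 10), paste0("GCC", strrep("GCT", 9)))
ng86_kaks <- function(seq_a, seq_b, stop_handling = c("exclude", "nonsyn")) {
  stop_handling <- match.arg(stop_handling)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("ng86_kaks: sequences have unequal lengths")
  }
  if (nchar(seq_a) %% 3 != 0L || nchar(seq_a) == 0L) {
    abort("ng86_kaks: length must be a positive multiple of 3")
  }
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b)) {
    abort("ng86_kaks: sequences must be over ACGT only")
  }
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  aa_a <- map_chr(ca, codon_aa)
  aa_b <- map_chr(cb, codon_aa)
  nc <- length(ca)
  # shared terminal stop is tolerated and trimmed
  if (aa_a[[nc]] == "*" && aa_b[[nc]] == "*") {
    ca <- ca[-nc]; cb <- cb[-nc]
    aa_a <- aa_a[-nc]; aa_b <- aa_b[-nc]
    nc <- nc - 1L
    if (nc == 0L) abort("ng86_kaks: no sense codons")
  }
  if (any(aa_a == "*") || any(aa_b == "*")) {
    abort("ng86_kaks: internal stop codon")
  }
  tabs <- ng86_tables(stop_handling == "exclude")
  s_sites <- (sum(tabs$syn[ca]) + sum(tabs$syn[cb])) / 2
  n_sites <- 3 * nc - s_sites
  sd <- 0; nd <- 0
  for (k in seq_len(nc)) {
    if (ca[[k]] == cb[[k]]) next
    key <- paste0(ca[[k]], cb[[k]])
    hit <- tabs$diffs[[key]]
    if (is.null(hit)) {
      hit <- ng86_path_diffs(ca[[k]], cb[[k]], tabs$exclude_stops)
      assign(key, hit, envir = tabs$diffs)
      assign(paste0(cb[[k]], ca[[k]]), hit, envir = tabs$diffs)
    }
    sd <- sd + hit[["sd"]]
    nd <- nd + hit[["nd"]]
  }
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p, what) {
    if (p >= 0.75) {
      abort(sprintf("ng86_kaks: %s proportion %.3f >= 3/4 (saturated)",
                    what, p))
    }
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps, "synonymous")
  ka <- jc(pn, "nonsynonymous")
  omega <- if (ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, omega = omega, s_sites = s_sites, n_sites = n_sites,
       sd = sd, nd = nd, ps = ps, pn = pn)
}

#' Build a pairwise codon alignment from CDS sequences
#'
#' When the two CDS have equal lengths they are aligned codon-for-codon
#' directly. Otherwise the translated proteins are globally aligned
#' (Biostrings) and the alignment is back-translated against each CDS
#' (error if a CDS length is not 3x its protein length); codon columns with
#' a gap in either row are removed pairwise.
#'
#' @param cds_a,cds_b Nucleotide coding sequences (ACGT).
#' @return A list with gap-free, equal-length `seq_a`, `seq_b`.
#' @export
codon_alignment_from_cds <- function(cds_a, cds_b) {
  trim_stop <- function(x) {
    nc <- nchar(x)
    if (nc %% 3 == 0L && nc >= 3L &&
        codon_aa(substr(x, nc - 2L, nc)) == "*") {
      substr(x, 1L, nc - 3L)
    } else x
  }
  cds_a <- trim_stop(cds_a); cds_b <- trim_stop(cds_b)
  if (nchar(cds_a) %% 3 != 0L || nchar(cds_b) %% 3 != 0L) {
    abort("codon_alignment_from_cds: CDS length not a multiple of 3")
  }
  if (nchar(cds_a) == nchar(cds_b)) {
    return(list(seq_a = cds_a, seq_b = cds_b))
  }
  prot <- function(x) {
    as.character(Biostrings::translate(Biostrings::DNAString(x)))
  }
  pa <- prot(cds_a); pb <- prot(cds_b)
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(pa),
                                       Biostrings::AAString(pb),
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  ra <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  rb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ka <- split_codons(cds_a)
  kb <- split_codons(cds_b)
  ia <- 0L; ib <- 0L
  out_a <- character(); out_b <- character()
  for (k in seq_along(ra)) {
    ga <- ra[[k]] == "-"; gb <- rb[[k]] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      out_a <- c(out_a, ka[[ia]])
      out_b <- c(out_b, kb[[ib]])
    }
  }
  list(seq_a = paste(out_a, collapse = ""), seq_b = paste(out_b, collapse = ""))
}

#' Ka/Ks evaluator over a CDS collection
#'
#' Returns a function `(gene_a, gene_b) -> list(ka, ks, omega)` that builds
#' the codon alignment from the named CDS collection and applies
#' [ng86_kaks()], as required by [extract_ortholog_pairs()].
#'
#' @param cds Named character vector of CDS, keyed by gene id.
#' @param stop_handling Passed on to [ng86_kaks()].
#' @return A function of two gene ids.
#' @export
make_kaks_fn <- function(cds, stop_handling = "exclude") {
  force(cds)
  function(gene_a, gene_b) {
    miss <- setdiff(c(gene_a, gene_b), names(cds))
    if (length(miss) > 0L) {
      abort(sprintf("make_kaks_fn: no CDS for %s", paste(miss, collapse = ", ")))
    }
    aln <- codon_alignment_from_cds(cds[[gene_a]], cds[[gene_b]])
    ng86_kaks(aln$seq_a, aln$seq_b, stop_handling)
  }
}

#' Classify selection from a Ka/Ks ratio
#'
#' Purifying selection when Ka is below Ks (omega < 1), neutral when they
#' are equal (within `tol`), positive when Ka exceeds Ks; undefined when
#' omega itself is undefined (Ks = 0).
#'
#' @param omega Ka/Ks ratio (may be `NA`).
#' @param tol Equality tolerance for the neutral call (default `1e-9`).
#' @return One of `"purifying"`, `"neutral"`, `"positive"`, `"undefined"`.
#' @export
classify_selection <- function(omega, tol = 1e-9) {
  if (is.na(omega)) return("undefined")
  if (abs(omega - 1) <= tol) return("neutral")
  if (omega < 1) return("purifying")
  "positive"
}

#' Divergence time from synonymous divergence
#'
#' `T = Ks / (2 r)` where `r` is the synonymous substitution rate per site
#' per year. No default rate is assumed: it is lineage-specific and must be
#' supplied.
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param rate Substitutions per synonymous site per year (> 0).
#' @return Divergence time in years.
#' @export
#' @examples
#' divergence_time(0.52, 2.6e-9) # 1e8 years
divergence_time <- function(ks, rate) {
  stopifnot(is.numeric(ks), is.numeric(rate))
  if (any(ks < 0)) abort("divergence_time: ks must be >= 0")
  if (any(rate <= 0)) abort("divergence_time: rate must be > 0")
  ks / (2 * rate)
}
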