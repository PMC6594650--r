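# independent brute-force NG86 oracle: fresh implementations of site
# counting and pathway enumeration, shared across test files
GC <- Biostrings::GENETIC_CODE

oracle_sites <- function(codon) {
  aa0 <- GC[[codon]]
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
    muts <- vapply(alts, function(nt) {
      x <- codon
      substr(x, pos, pos) <- nt
      x
    }, "")
    keep <- muts[GC[muts] != "*"]
    if (length(keep) > 0) s <- s + sum(GC[keep] == aa0) / length(keep)
  }
  s
}

oracle_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1) list(pos) else if (length(pos) == 2) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  paths <- list()
  for (pm in perms) {
    cur <- c1
    steps <- c(0, 0)
    blocked <- FALSE
    for (p in pm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC[[nxt]] == "*") { blocked <- TRUE; break }
      if (GC[[nxt]] == GC[[cur]]) steps[1] <- steps[1] + 1
      else steps[2] <- steps[2] + 1
      cur <- nxt
    }
    if (!blocked) paths[[length(paths) + 1L]] <- steps
  }
  if (length(paths) == 0) {
    for (pm in perms) {
      cur <- c1
      steps <- c(0, 0)
      for (p in pm) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (GC[[nxt]] == GC[[cur]]) steps[1] <- steps[1] + 1
        else steps[2] <- steps[2] + 1
        cur <- nxt
      }
      paths[[length(paths) + 1L]] <- steps
    }
  }
  Reduce(`+`, paths) / length(paths)
}

sense_codons <- names(GC)[GC != "*"]

# draw a random codon pair whose oracle-computed proportions stay safely
# below the Jukes-Cantor saturation bound, so correction is defined
draw_codon_pair_fixture <- function(n_range = 3:12, max_mut = 3L) {
  repeat {
    n <- sample(n_range, 1)
    ca <- sample(sense_codons, n, replace = TRUE)
    cb <- ca
    for (k in sample(n, sample(seq_len(min(n, max_mut)), 1))) {
      repeat {
        cand <- strsplit(ca[[k]], "")[[1]]
        for (p in sample(1:3, sample(1:2, 1))) {
          cand[[p]] <- sample(c("A", "C", "G", "T"), 1)
        }
        cand <- paste(cand, collapse = "")
        if (GC[[cand]] != "*") { cb[[k]] <- cand; break }
      }
    }
    s_sites <- (sum(vapply(ca, oracle_sites, 0)) +
                  sum(vapply(cb, oracle_sites, 0))) / 2
    d <- Reduce(`+`, Map(oracle_diffs, ca, cb))
    ps <- if (s_sites > 0) d[[1]] / s_sites else 0
    pn <- if (3 * n - s_sites > 0) d[[2]] / (3 * n - s_sites) else 0
    if (ps < 0.7 && pn < 0.7) {
      return(list(ca = ca, cb = cb, s_sites = s_sites, sd = d[[1]],
                  nd = d[[2]]))
    }
  }
}
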