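# quote a label for Newick when it contains characters outside the safe set
nwk_label <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.]", x), paste0("'", x, "'"), x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion. Ties in Q are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest leaf), so the result is deterministic. Negative branch
#' lengths arising from the closed-form estimates are clamped to zero with
#' the clamped amount transferred to the sibling edge, the common practice
#' in distance-matrix software. The result is unrooted (root trifurcation
#' for n >= 3).
#'
#' @param d Symmetric numeric matrix with zero diagonal, non-negative
#'   entries and row/column labels.
#' @return An [ape::read.tree()] `phylo` object with `n` leaves.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("neighbor_joining: d must be a square matrix")
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-8) abort("neighbor_joining: matrix not symmetric")
  if (any(d < 0)) abort("neighbor_joining: negative distances")
  n <- nrow(d)
  if (n < 2L) abort("neighbor_joining: need at least 2 taxa")
  labels <- rownames(d)
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", nwk_label(labels[[1]]), fmt(d[1, 2] / 2),
                   nwk_label(labels[[2]]), fmt(d[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  # active clusters: newick fragment + representative (smallest) leaf label
  frag <- nwk_label(labels)
  rep_lab <- labels
  D <- d
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[[ij[[1]]]], rep_lab[[ij[[2]]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[[1]], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- D[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[[i]], fmt(li), frag[[j]], fmt(lj))
    new_rep <- min(rep_lab[[i]], rep_lab[[j]])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[m - 1L, seq_along(keep)] <- D2[seq_along(keep), m - 1L] <- dk[keep]
    D <- D2
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # final trifurcation
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[[1]], fmt(l1),
                 frag[[2]], fmt(l2), frag[[3]], fmt(l3))
  ape::read.tree(text = txt)
}

# non-trivial splits of an unrooted phylo, as canonical strings:
# the side not containing the alphabetically first tip, sorted, "|"-joined.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ref <- min(tips)
  pp <- ape::prop.part(tree)
  out <- character()
  for (cl in pp) {
    side <- tips[cl]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# distances from a character matrix (taxa x sites) with pairwise deletion;
# returns NULL when any pair has no comparable sites or p >= 1 (poisson)
mat_distances <- function(mat, correction) {
  n <- nrow(mat)
  ok <- !(mat == "-" | mat == "X")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      nc <- sum(use)
      if (nc == 0L) return(NULL)
      p <- sum(mat[i, use] != mat[j, use]) / nc
      if (correction == "poisson") {
        if (p >= 1) return(NULL)
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement (original length) `n_replicates` times, rebuilds
#' the tree for each replicate, and annotates each internal edge of the
#' original tree with the percentage of replicate trees containing the same
#' leaf bipartition (rounded to the nearest integer). Replicates on which a
#' distance is undefined (no comparable sites, or saturation under the
#' Poisson correction) are redrawn and counted.
#'
#' @param alignment Tibble with `name`, `row` (as from [read_alignment()]).
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed; same seed, same supports.
#' @param correction Distance correction, `"poisson"` (default) or `"p"`.
#' @param keep_replicates Keep the replicate trees in the result (for
#'   diagnostics; off by default).
#' @return An object of class `grpfam_boot`: list with `tree` (a `phylo`
#'   whose `node.label` holds integer supports, root label empty),
#'   `n_replicates`, `n_redraws`, and optionally `replicate_trees`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L,
                              correction = c("poisson", "p"),
                              keep_replicates = FALSE) {
  correction <- match.arg(correction)
  if (n_replicates < 1L) abort("bootstrap_support: n_replicates must be >= 1")
  alignment <- arrange(alignment, .data$name)  # leaf-order invariance
  mat <- do.call(rbind, strsplit(alignment$row, "", fixed = TRUE))
  rownames(mat) <- alignment$name
  n_sites <- ncol(mat)
  d0 <- mat_distances(mat, correction)
  if (is.null(d0)) abort("bootstrap_support: distances undefined on full alignment")
  tree <- neighbor_joining(d0)
  target <- tree_splits(tree)
  counts <- setNames(integer(length(target)), target)
  set.seed(as.integer(seed))
  n_redraws <- 0L
  reps <- if (keep_replicates) vector("list", n_replicates) else NULL
  for (b in seq_len(n_replicates)) {
    repeat {
      cols <- sample.int(n_sites, n_sites, replace = TRUE)
      db <- mat_distances(mat[, cols, drop = FALSE], correction)
      if (!is.null(db)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100L * n_replicates) {
        abort("bootstrap_support: too many degenerate replicates")
      }
    }
    tb <- neighbor_joining(db)
    sb <- tree_splits(tb)
    hit <- intersect(target, sb)
    counts[hit] <- counts[hit] + 1L
    if (keep_replicates) reps[[b]] <- tb
  }
  support <- round(100 * counts / n_replicates)
  # map supports onto internal nodes of the original tree
  ntip <- length(tree$tip.label)
  node_lab <- character(tree$Nnode)
  pp <- ape::prop.part(tree)
  tips <- tree$tip.label
  ref <- min(tips)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > ntip - 2L) {
      node_lab[[k]] <- ""
      next
    }
    node_lab[[k]] <- as.character(support[[paste(sort(side), collapse = "|")]])
  }
  tree$node.label <- node_lab
  out <- list(tree = tree, n_replicates = as.integer(n_replicates),
              n_redraws = n_redraws, correction = correction)
  if (keep_replicates) out$replicate_trees <- reps
  structure(out, class = "grpfam_boot")
}

#' @export
print.grpfam_boot <- function(x, ...) {
  cat(sprintf("Neighbor-joining tree with bootstrap supports (%d replicates, %d redraws)\n",
              x$n_replicates, x$n_redraws))
  print(x$tree)
  invisible(x)
}

#' Collapse poorly supported edges into polytomies
#'
#' Internal edges whose support is less than or equal to `threshold` are
#' contracted (only supports strictly above the threshold survive). The leaf
#' set is unchanged; contracted edge lengths are discarded, children keep
#' their own lengths.
#'
#' @param tree A `phylo` with integer supports in `node.label` (as produced
#'   by [bootstrap_support()]), or a `grpfam_boot` object.
#' @param threshold Support percentage at or below which an edge is
#'   collapsed (default 50).
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  if (inherits(tree, "grpfam_boot")) tree <- tree$tree
  if (is.null(tree$node.label)) {
    abort("collapse_low_support: tree has no support labels")
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  lens <- split(tree$edge.length, tree$edge[, 1])
  supp <- suppressWarnings(as.numeric(tree$node.label))
  collapse_node <- function(node) {
    node > ntip && node != root && !is.na(supp[[node - ntip]]) &&
      supp[[node - ntip]] <= threshold
  }
  # render_child returns a character vector: one part normally, or the
  # spliced parts of a contracted node (recursing so nested contractions work)
  render_child <- function(kid, len) {
    if (collapse_node(kid)) {
      parts <- map2(children[[as.character(kid)]],
                    lens[[as.character(kid)]], render_child)
      return(unlist(parts))
    }
    if (kid <= ntip) {
      return(sprintf("%s:%.12g", nwk_label(tree$tip.label[[kid]]), len))
    }
    parts <- unlist(map2(children[[as.character(kid)]],
                         lens[[as.character(kid)]], render_child))
    sprintf("(%s)%s:%.12g", paste(parts, collapse = ","),
            tree$node.label[[kid - ntip]], len)
  }
  parts <- unlist(map2(children[[as.character(root)]],
                       lens[[as.character(root)]], render_child))
  ape::read.tree(text = sprintf("(%s);", paste(parts, collapse = ",")))
}
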