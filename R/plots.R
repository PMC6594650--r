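#' Plot the subfamily composition of a family roster
#'
#' Bar chart of member counts per subfamily class.
#'
#' @param object A `grpfam_roster` from [identify_family_members()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grpfam_roster
#' @export
autoplot.grpfam_roster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$family_class)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "Subfamily class", y = "Members",
                  title = "Family roster by subfamily") +
    ggplot2::theme_minimal()
}

#' Plot Ka against Ks for ortholog pairs
#'
#' Scatter of Ka versus Ks with the neutral expectation (Ka = Ks) as a
#' reference line; points colored by selection class.
#'
#' @param object A `grpfam_orthologs` from [extract_ortholog_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grpfam_orthologs
#' @export
autoplot.grpfam_orthologs <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ks, y = .data$ka,
                                       color = .data$selection_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Ks (synonymous substitutions/site)",
                  y = "Ka (nonsynonymous substitutions/site)",
                  color = "Selection") +
    ggplot2::theme_minimal()
}

#' Plot relative expression across samples
#'
#' Fold changes (2^-ddCt) per sample, with the control level (fold = 1)
#' marked.
#'
#' @param object A `grpfam_expression` from [compute_ddct()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grpfam_expression
#' @export
autoplot.grpfam_expression <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample,
                                       y = .data$fold_change)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Sample", y = "Relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
}

#' Chromosome distribution plot of family members
#'
#' @param members Character vector of family gene ids.
#' @param genes Gene table from [read_gff_genes()].
#' @return A ggplot object: member positions along each chromosome.
#' @export
plot_chromosome_map <- function(members, genes) {
  lens <- genes |>
    group_by(.data$chromosome) |>
    summarise(len = max(.data$end), .groups = "drop")
  mem <- filter(genes, .data$gene_id %in% members)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = lens,
                          ggplot2::aes(x = .data$chromosome,
                                       xend = .data$chromosome,
                                       y = 0, yend = .data$len / 1e6),
                          linewidth = 4, colour = "grey80", lineend = "round") +
    ggplot2::geom_point(data = mem,
                        ggplot2::aes(x = .data$chromosome,
                                     y = .data$start / 1e6),
                        shape = 95, size = 6, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Position (Mb)") +
    ggplot2::theme_minimal()
}

#' Tidy the edges of a bootstrapped tree
#'
#' @param x A `grpfam_boot` from [bootstrap_support()].
#' @param ... Unused.
#' @return Tibble with one row per edge: `parent`, `child`, `length`,
#'   `support` (NA on pendant and root edges), `child_label` for tips.
#' @method tidy grpfam_boot
#' @export
tidy.grpfam_boot <- function(x, ...) {
  tree <- x$tree
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  support <- rep(NA_real_, nrow(tree$edge))
  internal <- child > ntip
  lab <- tree$node.label[child[internal] - ntip]
  support[internal] <- suppressWarnings(as.numeric(lab))
  tibble(
    parent = tree$edge[, 1],
    child = child,
    length = tree$edge.length,
    support = support,
    child_label = ifelse(child <= ntip, tree$tip.label[child], NA_character_)
  )
}

#' One-row summary of a bootstrapped tree
#'
#' @param x A `grpfam_boot` from [bootstrap_support()].
#' @param ... Unused.
#' @return Tibble with `n_tips`, `n_replicates`, `n_redraws`,
#'   `mean_support`, `min_support`.
#' @method glance grpfam_boot
#' @export
glance.grpfam_boot <- function(x, ...) {
  s <- tidy(x)$support
  s <- s[!is.na(s)]
  tibble(n_tips = length(x$tree$tip.label),
         n_replicates = x$n_replicates,
         n_redraws = x$n_redraws,
         mean_support = if (length(s)) mean(s) else NA_real_,
         min_support = if (length(s)) min(s) else NA_real_)
}
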