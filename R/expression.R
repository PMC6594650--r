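#' Relative expression by the comparative Ct method
#'
#' Implements 2^-ddCt relative quantification: replicate Ct values are
#' averaged on the Ct scale per (gene, sample); dCt = Ct(target) - Ct(reference)
#' per sample; ddCt = dCt(sample) - dCt(control); fold change = E^-ddCt with
#' amplification efficiency E = 2 per cycle by default (an
#' efficiency-corrected variant is available via `efficiency`).
#'
#' @param ct_table Long-format tibble with columns `sample`, `gene`,
#'   `replicate`, `ct` (cycles, > 0).
#' @param target_gene Gene of interest.
#' @param reference_gene Internal reference (e.g. beta-actin).
#' @param control_sample Calibrator sample; its fold change is 1 by
#'   construction.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return Tibble of class `grpfam_expression`: `gene`, `sample`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
compute_ddct <- function(ct_table, target_gene, reference_gene,
                         control_sample, efficiency = 2) {
  stopifnot(all(c("sample", "gene", "replicate", "ct") %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) abort("compute_ddct: Ct values must be > 0")
  samples <- unique(ct_table$sample)
  if (!control_sample %in% samples) {
    abort(sprintf("compute_ddct: control sample '%s' not present",
                  control_sample))
  }
  means <- ct_table |>
    filter(.data$gene %in% c(target_gene, reference_gene)) |>
    group_by(.data$sample, .data$gene) |>
    summarise(ct = mean(.data$ct), n_rep = n(), .groups = "drop")
  for (s in samples) {
    m <- filter(means, .data$sample == s)
    if (!reference_gene %in% m$gene) {
      abort(sprintf("compute_ddct: reference gene missing in sample '%s'", s))
    }
    if (!target_gene %in% m$gene) {
      abort(sprintf("compute_ddct: target gene missing in sample '%s'", s))
    }
  }
  wide <- means |>
    select("sample", "gene", "ct") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  dct <- wide[[target_gene]] - wide[[reference_gene]]
  dct_control <- dct[wide$sample == control_sample]
  out <- tibble(
    gene = target_gene,
    sample = wide$sample,
    delta_ct = dct,
    delta_delta_ct = dct - dct_control,
    fold_change = efficiency^(-(dct - dct_control))
  )
  class(out) <- c("grpfam_expression", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, take
#' `q_i = min over j >= i of p_j * m / j`, cap at 1, return in the original
#' order. Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Gene-by-sample expression matrix with optional transform
#'
#' @param data Tibble in long (`gene`, `sample`, `value`) or wide form (a
#'   `gene` column plus one numeric column per sample).
#' @param transform `"none"`, `"log2p1"` (log2(x + 1)) or `"zscore_rows"`
#'   (per-gene standardization; constant rows map to 0).
#' @return Numeric matrix, genes as rows, samples as columns.
#' @export
expression_matrix <- function(data, transform = c("none", "log2p1",
                                                  "zscore_rows")) {
  transform <- match.arg(transform)
  if (all(c("gene", "sample", "value") %in% names(data))) {
    n_per <- count(data, .data$gene)
    if (length(unique(n_per$n)) > 1L) {
      abort("expression_matrix: ragged input (unequal samples per gene)")
    }
    wide <- tidyr::pivot_wider(data, id_cols = "gene",
                               names_from = "sample", values_from = "value")
  } else if ("gene" %in% names(data)) {
    wide <- data
  } else {
    abort("expression_matrix: need long (gene, sample, value) or wide input")
  }
  m <- as.matrix(wide[, setdiff(names(wide), "gene")])
  if (anyNA(m)) abort("expression_matrix: ragged input (missing cells)")
  rownames(m) <- wide$gene
  if (transform == "log2p1") {
    m <- log2(m + 1)
  } else if (transform == "zscore_rows") {
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    s[s == 0] <- 1
    m <- (m - mu) / s
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Matrix from [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- as_tibble(m, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}
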