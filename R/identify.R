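#' Identify RB-GRP family members from a proteome and domain evidence
#'
#' The full identification stage: reduce the proteome to the longest
#' translated isoform per gene locus, filter domain hits at the E-value
#' threshold, require at least one RRM or CSD hit, require a glycine-rich
#' window, resolve each survivor's domain architecture, classify it into
#' subfamilies IVa-IVd, and attach physicochemical properties. Proteins
#' whose architecture classifies as UNCLASSIFIED are dropped.
#'
#' Two E-values are used: the full-sequence E-value decides family
#' inclusion, the per-domain independent E-value decides which hits become
#' architecture tokens (both at the same threshold).
#'
#' @param proteome Tibble from [read_proteome()] (or a path to a FASTA).
#' @param domain_hits Tibble from [read_domain_table()] (or a path).
#' @param e_max Full-sequence and per-domain E-value threshold
#'   (default `1e-4`, strict inequality).
#' @param window,threshold Glycine window length and fraction passed to
#'   [glycine_profile()].
#' @param accession_map Used only when `domain_hits` is a path.
#' @param allow_x Tolerate `X` residues in property calculations.
#' @return A tibble of class `grpfam_roster`: `protein_id`, `gene_id`,
#'   `architecture_string`, `family_class`, `length`, `mw_kda`, `pi`,
#'   `max_window_fraction`, `best_window_start`.
#' @export
identify_family_members <- function(proteome, domain_hits, e_max = 1e-4,
                                    window = 20L, threshold = 0.5,
                                    accession_map = default_accession_map(),
                                    allow_x = FALSE) {
  if (is.character(proteome)) proteome <- read_proteome(proteome)
  if (is.character(domain_hits)) {
    domain_hits <- read_domain_table(domain_hits, accession_map)
  }
  empty <- tibble(protein_id = character(), gene_id = character(),
                  architecture_string = character(), family_class = character(),
                  length = integer(), mw_kda = double(), pi = double(),
                  max_window_fraction = double(), best_window_start = integer())
  class(empty) <- c("grpfam_roster", class(empty))
  if (nrow(proteome) == 0L) return(empty)

  # longest translated isoform per gene locus (ties by protein_id)
  iso <- proteome |>
    arrange(desc(.data$length), .data$protein_id) |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup()

  # family inclusion: full-sequence E-value, >=1 RRM or CSD hit
  incl <- filter_domain_hits(domain_hits, e_max) |>
    filter(.data$domain_class %in% c("RRM", "CSD"))
  candidates <- filter(iso, .data$protein_id %in% incl$protein_id)
  if (nrow(candidates) == 0L) return(empty)

  # glycine-rich window required
  gly <- glycine_profile(candidates$sequence, window, threshold)
  candidates <- dplyr::bind_cols(candidates, gly) |>
    filter(.data$is_glycine_rich)
  if (nrow(candidates) == 0L) return(empty)

  # architecture tokens: per-domain independent E-value
  arch_hits <- filter(domain_hits, .data$domain_ievalue < e_max,
                      .data$protein_id %in% candidates$protein_id)
  arch <- map(candidates$protein_id, function(pid) {
    resolve_architecture(filter(arch_hits, .data$protein_id == pid))
  })
  candidates$architecture_string <- map_chr(arch,
                                            ~ architecture_string(.x$domain_class))
  candidates$family_class <- map_chr(arch, ~ classify_family(.x$domain_class))
  roster <- filter(candidates, .data$family_class != "UNCLASSIFIED")
  if (nrow(roster) == 0L) return(empty)

  roster$mw_kda <- compute_molecular_weight(roster$sequence, allow_x = allow_x)
  roster$pi <- compute_isoelectric_point(roster$sequence)
  out <- select(roster, "protein_id", "gene_id", "architecture_string",
                "family_class", "length", "mw_kda", "pi",
                "max_window_fraction", "best_window_start")
  class(out) <- c("grpfam_roster", class(out))
  out
}

#' Write a family roster as TSV
#'
#' Column order mirrors the conventional family tables (gene, position if
#' available, domain string, class, size, Mw, pI).
#'
#' @param roster Tibble from [identify_family_members()], optionally joined
#'   with gene coordinates (`chromosome`, `start`, `end`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  cols <- c("gene_id", "chromosome", "start", "end", "architecture_string",
            "family_class", "length", "mw_kda", "pi")
  readr::write_tsv(roster[, intersect(cols, names(roster))], path)
  invisible(path)
}
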