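#' Default Pfam accession to domain-class map
#'
#' Maps the Pfam profiles used for RB-GRP mining to the coarse domain classes
#' the architecture classifier understands. Seven RRM-family profiles and the
#' cold-shock-domain profile form the family-inclusion evidence; the CCHC and
#' RanBP2 zinc-finger profiles only refine the architecture. Accessions absent
#' from the map are classed `OTHER` and never block classification.
#'
#' @return A named character vector: names are Pfam accessions, values are
#'   domain classes (`RRM`, `CSD`, `ZnF_CCHC`, `ZnF_RanBP2`).
#' @export
#' @examples
#' default_accession_map()[["PF00313"]]
default_accession_map <- function() {
  c(PF00076 = "RRM", PF04059 = "RRM", PF08777 = "RRM", PF10378 = "RRM",
    PF10598 = "RRM", PF13893 = "RRM", PF14259 = "RRM",
    PF00313 = "CSD",
    PF00098 = "ZnF_CCHC",
    PF00641 = "ZnF_RanBP2")
}

#' Read an accession map from a key-value text file
#'
#' Each non-comment line holds `ACCESSION<whitespace>CLASS`. Classes other
#' than `RRM`, `CSD`, `ZnF_CCHC`, `ZnF_RanBP2` are rejected.
#'
#' @param path Path to a two-column whitespace-separated text file.
#' @return Named character vector as in [default_accession_map()].
#' @export
read_accession_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- str_trim(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character())
  parts <- str_split(lines, "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("accession map: expected 2 fields on line %d", bad[[1]]))
  }
  cls <- map_chr(parts, 2L)
  ok <- cls %in% c("RRM", "CSD", "ZnF_CCHC", "ZnF_RanBP2")
  if (!all(ok)) {
    abort(sprintf("accession map: unknown domain class '%s'", cls[!ok][[1]]))
  }
  setNames(cls, map_chr(parts, 1L))
}

#' Parse a domain-hit table (HMMER domtblout dialect)
#'
#' Reads the whitespace-separated, `#`-commented per-domain table emitted by
#' profile-HMM searches. Column positions follow the domtblout layout: target
#' (protein) name, its accession and length, query (profile) name and
#' accession, full-sequence E-value and score, the per-domain conditional and
#' independent E-values, bit score and envelope coordinates. The profile
#' accession is mapped to a coarse domain class via `accession_map`; unknown
#' accessions become `OTHER`.
#'
#' @param path Path to a domain table file.
#' @param accession_map Named character vector mapping accessions to domain
#'   classes; defaults to [default_accession_map()].
#' @return A tibble with one row per domain hit: `protein_id`, `accession`,
#'   `domain_class`, `env_start`, `env_end`, `full_seq_evalue`,
#'   `domain_ievalue`, `bit_score`.
#' @export
read_domain_table <- function(path, accession_map = default_accession_map()) {
  if (!file.exists(path)) abort(sprintf("domain table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep_idx <- which(nzchar(str_trim(lines)) & !startsWith(str_trim(lines), "#"))
  if (length(keep_idx) == 0L) {
    return(tibble(protein_id = character(), accession = character(),
                  domain_class = character(), env_start = integer(),
                  env_end = integer(), full_seq_evalue = double(),
                  domain_ievalue = double(), bit_score = double()))
  }
  parse_row <- function(line, lineno) {
    f <- str_split(str_trim(line), "\\s+")[[1]]
    if (length(f) < 21L) {
      abort(sprintf("domain table: line %d has %d fields, expected >= 21",
                    lineno, length(f)))
    }
    nums <- suppressWarnings(as.numeric(f[c(7, 13, 14, 20, 21)]))
    if (anyNA(nums)) {
      abort(sprintf("domain table: non-numeric field on line %d", lineno))
    }
    list(protein_id = f[[1]], accession = f[[5]],
         full_seq_evalue = nums[[1]], domain_ievalue = nums[[2]],
         bit_score = nums[[3]], env_start = as.integer(nums[[4]]),
         env_end = as.integer(nums[[5]]))
  }
  rows <- map2(lines[keep_idx], keep_idx, parse_row)
  out <- tibble(
    protein_id = map_chr(rows, "protein_id"),
    accession = map_chr(rows, "accession"),
    env_start = map_int(rows, "env_start"),
    env_end = map_int(rows, "env_end"),
    full_seq_evalue = map_dbl(rows, "full_seq_evalue"),
    domain_ievalue = map_dbl(rows, "domain_ievalue"),
    bit_score = map_dbl(rows, "bit_score")
  )
  bad <- which(out$env_start < 1L | out$env_end < out$env_start)
  if (length(bad) > 0L) {
    abort(sprintf("domain table: invalid envelope on line %d",
                  keep_idx[bad[[1]]]))
  }
  bad <- which(out$full_seq_evalue <= 0 | out$domain_ievalue <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("domain table: non-positive E-value on line %d",
                  keep_idx[bad[[1]]]))
  }
  out$domain_class <- unname(accession_map[out$accession])
  out$domain_class[is.na(out$domain_class)] <- "OTHER"
  select(out, "protein_id", "accession", "domain_class", "env_start",
         "env_end", "full_seq_evalue", "domain_ievalue", "bit_score")
}

#' Filter domain hits by full-sequence E-value
#'
#' Keeps hits with full-sequence E-value strictly below `e_max` (the mining
#' threshold is E < 1e-4, a strict inequality). Row order is preserved.
#'
#' @param hits Tibble of domain hits as from [read_domain_table()].
#' @param e_max Positive E-value threshold (default `1e-4`).
#' @return The filtered tibble, same columns.
#' @export
filter_domain_hits <- function(hits, e_max = 1e-4) {
  stopifnot(is.numeric(e_max), length(e_max) == 1L)
  if (e_max <= 0) abort("e_max must be > 0")
  filter(hits, .data$full_seq_evalue < e_max)
}

#' Write a domain-hit tibble in the domtblout dialect
#'
#' Counterpart of [read_domain_table()]; used by the synthetic-data
#' generator so that emitted fixtures are valid parser inputs.
#'
#' @param hits Tibble with the columns produced by [read_domain_table()]
#'   (an optional `qlen`/`tlen` are synthesized when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic domain table (domtblout dialect)", con)
  if (nrow(hits) == 0L) return(invisible(path))
  profile_name <- ifelse(hits$domain_class == "OTHER", "Unknown",
                         hits$domain_class)
  lines <- sprintf(
    "%s - %d %s %s %d %.3g %.1f 0.0 1 1 %.3g %.3g %.1f 0.0 1 %d %d %d %d %d 0.90 -",
    hits$protein_id,
    hits$env_end + 10L,                  # stand-in target length
    profile_name, hits$accession,
    hits$env_end - hits$env_start + 1L,  # stand-in profile length
    hits$full_seq_evalue, hits$bit_score,
    hits$domain_ievalue, hits$domain_ievalue, hits$bit_score,
    hits$env_end - hits$env_start + 1L,
    hits$env_start, hits$env_end, hits$env_start, hits$env_end
  )
  writeLines(lines, con)
  invisible(path)
}
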