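#' Resolve a protein's domain architecture from its filtered hits
#'
#' Orders a single protein's domain hits by envelope start and merges
#' same-class hits whose reciprocal overlap exceeds 50% of the shorter
#' envelope (repeated weak hits on one domain must not be double-counted as,
#' say, two RRMs). Merged hits keep the union envelope.
#'
#' @param hits Tibble of domain hits for one protein (columns
#'   `domain_class`, `env_start`, `env_end`; a `protein_id` column, if
#'   present, must be constant).
#' @return A tibble of merged domains ordered by `env_start`, with columns
#'   `domain_class`, `env_start`, `env_end`. The ordered token list is
#'   `$domain_class`.
#' @export
resolve_architecture <- function(hits) {
  empty <- tibble(domain_class = character(), env_start = integer(),
                  env_end = integer())
  if (nrow(hits) == 0L) return(empty)
  if ("protein_id" %in% names(hits) &&
      length(unique(hits$protein_id)) > 1L) {
    abort("resolve_architecture: hits span multiple proteins")
  }
  h <- arrange(hits, .data$env_start, .data$env_end)
  merged <- list()
  for (i in seq_len(nrow(h))) {
    cur <- list(domain_class = h$domain_class[[i]],
                env_start = h$env_start[[i]], env_end = h$env_end[[i]])
    absorbed <- FALSE
    for (j in seq_along(merged)) {
      m <- merged[[j]]
      if (m$domain_class != cur$domain_class) next
      ov <- min(m$env_end, cur$env_end) - max(m$env_start, cur$env_start) + 1L
      shorter <- min(m$env_end - m$env_start, cur$env_end - cur$env_start) + 1L
      if (ov > 0.5 * shorter) {
        merged[[j]]$env_start <- min(m$env_start, cur$env_start)
        merged[[j]]$env_end <- max(m$env_end, cur$env_end)
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) merged[[length(merged) + 1L]] <- cur
  }
  out <- tibble(
    domain_class = map_chr(merged, "domain_class"),
    env_start = as.integer(map_dbl(merged, "env_start")),
    env_end = as.integer(map_dbl(merged, "env_end"))
  )
  arrange(out, .data$env_start, .data$env_end)
}

#' Classify a domain architecture into subfamilies IVa-IVd
#'
#' The RB-GRP subfamilies are defined by domain arrangement: IVa a single
#' RRM, IVb an RRM plus zinc finger(s) (CCHC or RanBP2 type), IVc a
#' cold-shock domain with zinc finger(s), IVd two RRMs. Precedence is
#' CSD-first, then two-or-more RRMs, then RRM + zinc finger, then a lone
#' RRM; anything else is UNCLASSIFIED. A CSD accompanied by a single zinc
#' finger still classifies as IVc (observed arrangements include CSD-C2HC
#' as well as CSD-C2HC-C2HC).
#'
#' @param architecture Character vector of ordered domain-class tokens
#'   (`RRM`, `CSD`, `ZnF_CCHC`, `ZnF_RanBP2`, `OTHER`).
#' @return A single string: `"IVa"`, `"IVb"`, `"IVc"`, `"IVd"` or
#'   `"UNCLASSIFIED"`.
#' @export
#' @examples
#' classify_family(c("RRM", "ZnF_CCHC"))
classify_family <- function(architecture) {
  stopifnot(is.character(architecture))
  n_rrm <- sum(architecture == "RRM")
  n_csd <- sum(architecture == "CSD")
  n_znf <- sum(architecture %in% c("ZnF_CCHC", "ZnF_RanBP2"))
  if (n_csd >= 1L) return("IVc")
  if (n_rrm >= 2L) return("IVd")
  if (n_rrm == 1L && n_znf >= 1L) return("IVb")
  if (n_rrm == 1L) return("IVa")
  "UNCLASSIFIED"
}

#' Hyphen-joined architecture label
#'
#' Collapses an ordered token list into the conventional label used in
#' family tables, e.g. `"RRM-C2HC"` or `"CSD-C2HC-C2HC"`.
#'
#' @param architecture Character vector of ordered domain-class tokens.
#' @return A single string (empty string for an empty architecture).
#' @export
architecture_string <- function(architecture) {
  display <- c(RRM = "RRM", CSD = "CSD", ZnF_CCHC = "C2HC",
               ZnF_RanBP2 = "RanBP2", OTHER = "OTHER")
  paste(display[architecture], collapse = "-")
}

#' Extract domain envelope subsequences with positional suffixes
#'
#' Cuts the merged domain envelopes out of a protein sequence and names the
#' segments by position: a single domain keeps the bare protein id; two
#' domains get suffixes `N` and `C`; three or more get `N`, `M` (numbered
#' `M1`, `M2`, ... when several middles) and `C`.
#'
#' @param protein_id Protein identifier used to build segment names.
#' @param sequence The protein's amino-acid sequence.
#' @param domains Tibble from [resolve_architecture()] (columns
#'   `domain_class`, `env_start`, `env_end`).
#' @return Tibble with `segment_name`, `domain_class`, `env_start`,
#'   `env_end`, `subsequence`.
#' @export
extract_domain_segments <- function(protein_id, sequence, domains) {
  n <- nrow(domains)
  if (n == 0L) {
    return(tibble(segment_name = character(), domain_class = character(),
                  env_start = integer(), env_end = integer(),
                  subsequence = character()))
  }
  if (any(domains$env_start < 1L) || any(domains$env_end > nchar(sequence))) {
    abort(sprintf("extract_domain_segments: envelope outside [1, %d] for %s",
                  nchar(sequence), protein_id))
  }
  suffix <- if (n == 1L) {
    ""
  } else if (n == 2L) {
    c(" N", " C")
  } else {
    mids <- if (n - 2L == 1L) " M" else paste0(" M", seq_len(n - 2L))
    c(" N", mids, " C")
  }
  tibble(
    segment_name = paste0(protein_id, suffix),
    domain_class = domains$domain_class,
    env_start = domains$env_start,
    env_end = domains$env_end,
    subsequence = str_sub(sequence, domains$env_start, domains$env_end)
  )
}
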