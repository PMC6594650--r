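#' Sliding-window glycine-content profile
#'
#' Scans an amino-acid sequence with a window of `window` residues sliding by
#' one and records the maximum glycine fraction over all windows. A sequence
#' is called glycine-rich when that maximum exceeds `threshold` strictly
#' (more than 50% glycine within some 20-residue stretch, i.e. at least 11 G
#' in a 20-residue window at the defaults). Sequences shorter than the window
#' are scored as one window over their own length.
#'
#' @param sequence Character vector of amino-acid sequences (upper case).
#' @param window Window length in residues (default 20).
#' @param threshold Glycine fraction that must be exceeded (default 0.5).
#' @return A tibble with one row per sequence: `window_length`,
#'   `max_window_fraction`, `best_window_start` (1-based start of the first
#'   maximal window), `is_glycine_rich`.
#' @export
#' @examples
#' glycine_profile(strrep("G", 20))
glycine_profile <- function(sequence, window = 20L, threshold = 0.5) {
  stopifnot(is.character(sequence), window >= 1L)
  if (any(!nzchar(sequence))) abort("glycine_profile: empty sequence")
  one <- function(seq) {
    n <- nchar(seq)
    is_g <- as.integer(strsplit(seq, "", fixed = TRUE)[[1]] == "G")
    if (n < window) {
      frac <- sum(is_g) / n
      return(c(frac = frac, start = 1))
    }
    cs <- c(0L, cumsum(is_g))
    counts <- cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
    best <- which.max(counts)
    c(frac = counts[[best]] / window, start = best)
  }
  res <- map(sequence, one)
  tibble(
    window_length = as.integer(window),
    max_window_fraction = map_dbl(res, "frac"),
    best_window_start = as.integer(map_dbl(res, "start")),
    is_glycine_rich = map_dbl(res, "frac") > threshold
  )
}
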