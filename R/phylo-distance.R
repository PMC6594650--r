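#' Pairwise distance between two aligned rows
#'
#' Sites where either row carries a gap `-` or the ambiguity code `X` are
#' excluded (pairwise deletion). The p-distance is the mismatch proportion
#' over the remaining sites; the Poisson correction is `d = -ln(1 - p)`.
#'
#' @param row_a,row_b Equal-length aligned strings.
#' @param correction `"p"` or `"poisson"`.
#' @return A single non-negative distance.
#' @export
#' @examples
#' pairwise_distance("AAAA", "AAAC", "poisson") # -log(0.75)
pairwise_distance <- function(row_a, row_b, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  if (nchar(row_a) != nchar(row_b)) {
    abort("pairwise_distance: rows have unequal lengths")
  }
  a <- strsplit(row_a, "", fixed = TRUE)[[1]]
  b <- strsplit(row_b, "", fixed = TRUE)[[1]]
  use <- !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
  n <- sum(use)
  if (n == 0L) abort("pairwise_distance: no comparable sites after deletion")
  p <- sum(a[use] != b[use]) / n
  if (correction == "p") return(p)
  if (p >= 1) abort("pairwise_distance: p >= 1, Poisson distance infinite")
  -log(1 - p)
}

#' Distance matrix over an alignment
#'
#' Applies [pairwise_distance()] to every pair of rows.
#'
#' @param alignment Tibble with `name`, `row` (as from [read_alignment()]).
#' @param correction `"poisson"` (default) or `"p"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by row
#'   names.
#' @export
alignment_distances <- function(alignment, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  n <- nrow(alignment)
  d <- matrix(0, n, n, dimnames = list(alignment$name, alignment$name))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(alignment$row[[i]],
                                              alignment$row[[j]], correction)
    }
  }
  d
}
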