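#' Read a proteome FASTA into a protein table
#'
#' Headers of the form `>protein_id gene=gene_id` carry the gene locus used
#' for the longest-isoform reduction; when the `gene=` attribute is absent
#' the protein id doubles as the gene id.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Tibble with `protein_id`, `gene_id`, `sequence`, `length`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- names(aa)
  protein_id <- map_chr(str_split(nm, "\\s+"), 1L)
  gene_id <- map_chr(nm, function(x) {
    m <- regmatches(x, regexpr("gene=\\S+", x))
    if (length(m) == 0L) strsplit(x, "\\s+")[[1]][[1]] else sub("^gene=", "", m)
  })
  if (anyDuplicated(protein_id)) {
    abort("read_proteome: duplicate protein ids")
  }
  tibble(protein_id = protein_id, gene_id = gene_id,
         sequence = as.character(aa), length = nchar(as.character(aa)))
}

#' Write a protein table as FASTA
#'
#' @param proteins Tibble with `protein_id`, `gene_id`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                         paste0(proteins$protein_id,
                                                " gene=", proteins$gene_id)))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a multiple alignment FASTA into an alignment table
#'
#' @param path FASTA file of equal-length aligned rows (gaps `-`).
#' @return Tibble with `name`, `row`; all rows equal length.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- as.character(aa)
  if (length(unique(nchar(rows))) > 1L) {
    abort("read_alignment: rows have unequal lengths")
  }
  nm <- map_chr(str_split(names(aa), "\\s+"), 1L)
  if (anyDuplicated(nm)) abort("read_alignment: duplicate row names")
  tibble(name = nm, row = unname(rows))
}
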