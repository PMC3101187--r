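# Equality of datasets up to identifier renaming — the invariant contract
# of the round-trip converters and of the triples mapping.

matrix_signature <- function(m) {
  pos <- match(m$cells$character_ref, m$characters$id)
  row <- m$tus$label[match(m$cells$tu_ref, m$tus$id)]
  cells <- sort(paste(row, pos, m$cells$state, sep = "\r"))
  paste(c(m$datatype, nrow(m$tus), nrow(m$characters), cells),
        collapse = "\n")
}

#' Compare two datasets up to identifier renaming
#'
#' Two datasets are considered equal when they carry the same TU label set,
#' topologically identical trees (canonical Newick, branch lengths
#' included), the same matrices (data type, dimensions, and cell states
#' keyed by row label and column position), and the same annotation
#' (predicate, value) pairs.  Internal identifiers — node, edge, TU,
#' character ids and synthesized `#node<k>` labels — are ignored.
#'
#' @param a,b `cdao_dataset` objects.
#' @return `TRUE` or `FALSE`.
#' @export
dataset_equal <- function(a, b) {
  if (!setequal(a$tus$label, b$tus$label)) return(FALSE)
  if (length(a$trees) != length(b$trees)) return(FALSE)
  ta <- sort(vapply(a$trees, write_newick, ""))
  tb <- sort(vapply(b$trees, write_newick, ""))
  if (!identical(ta, tb)) return(FALSE)
  if (length(a$matrices) != length(b$matrices)) return(FALSE)
  ma <- sort(vapply(a$matrices, matrix_signature, ""))
  mb <- sort(vapply(b$matrices, matrix_signature, ""))
  if (!identical(ma, mb)) return(FALSE)
  aa <- a$annotations[a$annotations$predicate != "ps:nexus_block", ,
                      drop = FALSE]
  ab <- b$annotations[b$annotations$predicate != "ps:nexus_block", ,
                      drop = FALSE]
  setequal(paste(aa$predicate, aa$value, sep = "\r"),
           paste(ab$predicate, ab$value, sep = "\r"))
}
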