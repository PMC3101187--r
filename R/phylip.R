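# PHYLIP character-matrix reader/writer.

#' Parse a PHYLIP character matrix
#'
#' The header line gives `ntax nchar`.  Both sequential and interleaved
#' layouts are supported: the first `ntax` data lines each start a taxon
#' (name then sequence); later lines are continuation blocks appended in
#' taxon order until every row reaches `nchar` states.  Names are
#' whitespace-delimited ("relaxed") by default; `strict_names = TRUE`
#' instead takes the classic fixed 10-character name field.
#'
#' The data type is inferred: DNA when the alphabet is within
#' `{A,C,G,T,U,N,-,?}` (case-insensitive), protein otherwise.
#'
#' @param text PHYLIP file content.
#' @param id Matrix identifier.
#' @param strict_names Use the fixed-width 10-character name convention.
#' @return A `cdao_matrix`.
#' @export
parse_phylip <- function(text, id = "m1", strict_names = FALSE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("phylip: empty input")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("phylip: header must be 'ntax nchar'")
  ntax <- as.integer(hdr[1]); nchar_ <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) < ntax)
    stop("phylip: declared ", ntax, " taxa but found ", length(body), " rows")
  names_ <- character(ntax); seqs <- character(ntax)
  for (i in seq_len(ntax)) {
    ln <- body[i]
    if (strict_names) {
      names_[i] <- trimws(substr(ln, 1, 10))
      seqs[i] <- gsub("\\s", "", substr(ln, 11, nchar(ln)))
    } else {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      names_[i] <- toks[1]
      seqs[i] <- paste(toks[-1], collapse = "")
    }
  }
  extra <- body[-seq_len(ntax)]
  for (j in seq_along(extra)) {           # interleaved continuation blocks
    k <- ((j - 1L) %% ntax) + 1L
    seqs[k] <- paste0(seqs[k], gsub("\\s", "", extra[j]))
  }
  if (any(nchar(seqs) != nchar_))
    stop("phylip: rows have ", paste(unique(nchar(seqs)), collapse = ","),
         " states but header declares nchar=", nchar_)
  alphabet <- unique(strsplit(toupper(paste(seqs, collapse = "")), "")[[1]])
  datatype <- if (all(alphabet %in% c("A", "C", "G", "T", "U", "N", "-", "?")))
    "DNA" else "protein"
  rows <- stats::setNames(as.list(seqs), names_)
  counter <- 0L
  tu_id_for <- function(label) { counter <<- counter + 1L; paste0("tu", counter) }
  build_matrix_from_rows(rows, id, datatype, tu_id_for)
}

#' Serialize a character matrix to (relaxed, sequential) PHYLIP
#'
#' @param m A `cdao_matrix`.
#' @return PHYLIP text; missing cells are written as `?`.
#' @export
write_phylip <- function(m) {
  rows <- vapply(seq_len(nrow(m$tus)), function(i) {
    cc <- m$cells[m$cells$tu_ref == m$tus$id[i], , drop = FALSE]
    st <- cc$state[match(m$characters$id, cc$character_ref)]
    st[is.na(st)] <- "?"
    paste0(gsub("\\s", "_", m$tus$label[i]), " ", paste(st, collapse = ""))
  }, "")
  paste(c(paste(nrow(m$tus), nrow(m$characters)), rows, ""), collapse = "\n")
}
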