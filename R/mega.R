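# MEGA sequence-data reader (the #mega / #Taxon dialect).  Distance-matrix
# MEGA files are rejected: only aligned sequence data maps onto the
# character-matrix model.

#' Parse a MEGA sequence file
#'
#' Accepts the sequence-data dialect: a `#mega` header, optional `Title`,
#' `Format` or `!`-command lines, then one `#TaxonName` header per taxon
#' followed by its sequence lines.  All sequences must have equal length.
#'
#' @param text MEGA file content (must start with `#mega`, any case).
#' @param id Dataset identifier.
#' @return A `cdao_dataset` holding one character matrix.
#' @export
parse_mega <- function(text, id = "ds1") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  if (!length(lines) || !grepl("^#mega", lines[1], ignore.case = TRUE))
    stop("mega: file must begin with #mega")
  rows <- list(); current <- NULL
  for (ln in lines[-1]) {
    if (!nzchar(ln)) next
    if (grepl("^!", ln) || grepl("^(Title|Format|Description)\\b", ln,
                                 ignore.case = TRUE)) {
      if (grepl("distance", ln, ignore.case = TRUE))
        stop("mega: distance-matrix files are not supported, ",
             "only sequence data")
      next
    }
    if (startsWith(ln, "#")) {
      current <- sub("^#", "", ln)
      if (is.null(rows[[current]])) rows[[current]] <- ""
    } else {
      if (is.null(current)) stop("mega: sequence line before any #Taxon header")
      rows[[current]] <- paste0(rows[[current]], gsub("\\s", "", ln))
    }
  }
  if (!length(rows)) stop("mega: no taxa found")
  lens <- vapply(rows, nchar, 0L)
  if (any(lens == 0))
    stop("mega: taxon '", names(rows)[lens == 0][1], "' has no sequence lines")
  if (length(unique(lens)) != 1)
    stop("mega: inconsistent sequence lengths: ",
         paste(unique(lens), collapse = ","))
  alphabet <- unique(strsplit(toupper(paste(unlist(rows), collapse = "")),
                              "")[[1]])
  datatype <- if (all(alphabet %in% c("A", "C", "G", "T", "U", "N", "-", "?")))
    "DNA" else "protein"
  counter <- 0L
  tu_id_for <- function(label) { counter <<- counter + 1L; paste0("tu", counter) }
  m <- build_matrix_from_rows(rows, "m1", datatype, tu_id_for)
  new_dataset(id, tus = m$tus, matrices = list(m))
}
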