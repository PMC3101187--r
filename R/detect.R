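# Format detection and the import front door.

format_tags <- c("nexus", "nexml", "phylip", "mega", "newick",
                 "ntriples", "rdfxml")

#' Detect the format of a phylogenetic data file
#'
#' Rules: `#NEXUS` (case-insensitive) as first token is NEXUS; `#mega` is
#' MEGA; an XML document is classified by its root element (`<nexml>` vs
#' `<RDF>`); a first line of two integers is PHYLIP; text starting with
#' `(` and ending with `;` is Newick; a line shaped like
#' `<s> <p> <o> .` is N-Triples.  Anything else is an explicit error, never
#' a silent guess.
#'
#' @param text Raw file content.
#' @return One of `"nexus"`, `"nexml"`, `"phylip"`, `"mega"`, `"newick"`,
#'   `"ntriples"`, `"rdfxml"`.
#' @export
detect_format <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  trimmed <- trimws(text)
  if (!nzchar(trimmed)) stop("cannot detect format of empty input")
  if (grepl("^#nexus", trimmed, ignore.case = TRUE)) return("nexus")
  if (grepl("^#mega", trimmed, ignore.case = TRUE)) return("mega")
  first_line <- strsplit(trimmed, "\n", fixed = TRUE)[[1]][1]
  if (grepl("^<[^>]+>\\s+<[^>]+>\\s+.*\\.$", trimws(first_line)))
    return("ntriples")
  if (startsWith(trimmed, "<")) {
    root <- tryCatch(xml2::xml_name(xml2::read_xml(text)),
                     error = function(e) NA_character_)
    if (identical(root, "nexml")) return("nexml")
    if (identical(root, "RDF")) return("rdfxml")
    stop("unknown format: XML document with unrecognized root element '",
         root, "'")
  }
  toks <- strsplit(trimws(first_line), "\\s+")[[1]]
  if (length(toks) == 2 && all(grepl("^[0-9]+$", toks))) return("phylip")
  if (startsWith(trimmed, "(") && endsWith(trimmed, ";")) return("newick")
  stop("unknown format: content matches none of ",
       paste(format_tags, collapse = "/"))
}

#' Import a phylogenetic data file as a dataset
#'
#' Front door over the format readers: detects (or accepts) the format and
#' returns a dataset whatever the input kind — a bare tree or matrix is
#' wrapped into a one-element dataset.
#'
#' @param path File path.
#' @param format `"auto"` (default) or one of the supported input formats.
#' @param id Dataset identifier.
#' @param strict_names Passed to [parse_phylip()].
#' @return A `cdao_dataset`.
#' @export
read_phylo_file <- function(path, format = "auto", id = "ds1",
                            strict_names = FALSE) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_phylo_text(text, format, id, strict_names)
}

#' @rdname read_phylo_file
#' @param text Raw file content (alternative to `path`).
#' @export
parse_phylo_text <- function(text, format = "auto", id = "ds1",
                             strict_names = FALSE) {
  if (identical(format, "auto")) format <- detect_format(text)
  format <- match.arg(format, c("nexus", "nexml", "phylip", "mega", "newick"))
  switch(format,
         nexus  = parse_nexus(text, id),
         nexml  = parse_nexml(text, id),
         mega   = parse_mega(text, id),
         phylip = {
           m <- parse_phylip(text, strict_names = strict_names)
           new_dataset(id, tus = m$tus, matrices = list(m))
         },
         newick = as_dataset(parse_newick(text), id))
}
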