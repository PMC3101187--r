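# The PhyloWS-style URI grammar and the query dispatcher.
#
# URIs take the form /phylows/<querytype>/<parameters...>?format=...&limit=
# &offset=...  Taxon labels containing "/" must be percent-encoded; every
# path segment is percent-decoded before matching.

ws_formats <- c(newick = "newick", nexus = "nexus", nexml = "nexml",
                phylip = "phylip", phyloxml = "phyloxml",
                graphml = "graphml", prolog = "prolog",
                rdf = "rdfxml", rdfxml = "rdfxml", ntriples = "ntriples",
                json = "json", text = "text")

new_query_spec <- function(qtype, target_id = NULL, taxa = character(0),
                           measure = NULL, q = NULL, direction = NULL,
                           criteria = NULL, size = NULL, datatype = NULL,
                           field = NULL, value = NULL, format = NULL,
                           limit = NULL, offset = NULL) {
  structure(list(qtype = qtype, target_id = target_id, taxa = taxa,
                 measure = measure, q = q, direction = direction,
                 criteria = criteria, size = size, datatype = datatype,
                 field = field, value = value, format = format,
                 limit = limit, offset = offset),
            class = "query_spec")
}

#' @export
print.query_spec <- function(x, ...) {
  flds <- Filter(function(v) !is.null(v) && length(v), unclass(x))
  cat("<query_spec>", paste(names(flds),
                            vapply(flds, function(v)
                              paste(v, collapse = ","), ""),
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Parse a PhyloWS-style query URI
#'
#' The path must begin with `/phylows/`; the next segment is the query
#' type, followed by type-specific parameters:
#' \describe{
#'   \item{`tree/<id>`, `matrix/<id>`}{fetch one object.}
#'   \item{`list`}{list all tree ids.}
#'   \item{`taxa/<t1>/<t2>/...`}{trees containing all the taxa.}
#'   \item{`msc|nca/<tree>/<t1>/...`}{minimum spanning clade / nearest
#'     common ancestor of taxa in one tree.}
#'   \item{`author|method/<value>`}{metadata search.}
#'   \item{`size/<direction>/<criteria>/<n>`}{size filter with direction
#'     greater/less/equal and criteria node/internal/leaf.}
#'   \item{`property/<diameter|width>/<n>`}{property filter.}
#'   \item{`distance/<ref>/<measure>/<q>`}{trees within distance q.}
#'   \item{`stats/<measure>`}{distribution summary.}
#'   \item{`datatype/<type>[/taxa...]`}{trees built from a data type.}
#' }
#' The query string accepts `format=` (e.g. `rdf` for RDF/XML, `newick`,
#' `nexml`), and `limit=`/`offset=` for paginating listing results.
#'
#' @param uri Path plus optional query string, e.g.
#'   `"/phylows/tree/TB2:Tr3099?format=rdf"`.
#' @return A `query_spec`.
#' @export
parse_phylows_uri <- function(uri) {
  stopifnot(is.character(uri), length(uri) == 1)
  parts <- strsplit(uri, "?", fixed = TRUE)[[1]]
  path <- parts[1]
  if (!grepl("^/phylows/", path))
    stop("phylows: URI path must begin with /phylows/")
  qs <- if (length(parts) > 1) parts[2] else ""
  params <- list()
  if (nzchar(qs)) {
    for (kv in strsplit(qs, "&", fixed = TRUE)[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2) params[[p[1]]] <- utils::URLdecode(p[2])
    }
  }
  segs <- strsplit(sub("^/phylows/", "", path), "/", fixed = TRUE)[[1]]
  segs <- vapply(segs, utils::URLdecode, "", USE.NAMES = FALSE)
  if (!length(segs) || !nzchar(segs[1]))
    stop("phylows: missing query type after /phylows/")
  qtype <- segs[1]; rest <- segs[-1]
  need <- function(n, what) {
    if (length(rest) < n)
      stop("phylows: query type '", qtype, "' requires ", what)
  }
  fmt <- NULL
  if (!is.null(params$format)) {
    if (!params$format %in% names(ws_formats))
      stop("phylows: unknown format '", params$format, "'")
    fmt <- unname(ws_formats[params$format])
  }
  int_param <- function(key) {
    v <- params[[key]]
    if (is.null(v)) return(NULL)
    if (!grepl("^[0-9]+$", v)) stop("phylows: ", key, " must be a numeral")
    as.integer(v)
  }
  limit <- int_param("limit"); offset <- int_param("offset")
  spec <- switch(
    qtype,
    tree = { need(1, "a tree id")
      new_query_spec("tree", target_id = rest[1]) },
    matrix = { need(1, "a matrix id")
      new_query_spec("matrix", target_id = rest[1]) },
    list = new_query_spec("list"),
    taxa = { need(1, "at least one taxon")
      new_query_spec("taxa", taxa = rest) },
    msc = { need(2, "a tree id and at least one taxon")
      new_query_spec("msc", target_id = rest[1], taxa = rest[-1]) },
    nca = { need(2, "a tree id and at least one taxon")
      new_query_spec("nca", target_id = rest[1], taxa = rest[-1]) },
    author = { need(1, "a search string")
      new_query_spec("author", field = "author", value = rest[1]) },
    method = { need(1, "a search string")
      new_query_spec("method", field = "method", value = rest[1]) },
    size = { need(3, "direction/criteria/size")
      if (!rest[1] %in% c("greater", "less", "equal"))
        stop("phylows: size direction must be greater, less, or equal")
      if (!rest[2] %in% c("node", "internal", "leaf"))
        stop("phylows: size criteria must be node, internal, or leaf")
      if (!grepl("^[0-9]+$", rest[3]))
        stop("phylows: size must be a numeral")
      new_query_spec("size", direction = rest[1], criteria = rest[2],
                     size = as.integer(rest[3])) },
    property = { need(2, "a property and a value")
      if (!rest[1] %in% c("diameter", "width"))
        stop("phylows: property must be diameter or width")
      if (!grepl("^[0-9]+$", rest[2]))
        stop("phylows: property value must be a numeral")
      new_query_spec("property", measure = rest[1],
                     q = as.numeric(rest[2])) },
    distance = { need(3, "a reference tree, a measure, and a quantity")
      if (!rest[2] %in% c("rf", "treelength-diff", "nodecount-diff"))
        stop("phylows: unknown distance measure '", rest[2], "'")
      if (is.na(suppressWarnings(as.numeric(rest[3]))))
        stop("phylows: distance quantity must be numeric")
      new_query_spec("distance", target_id = rest[1], measure = rest[2],
                     q = as.numeric(rest[3])) },
    stats = { need(1, "a measure")
      if (!rest[1] %in% c("treelength", "nodecount", "diameter", "width"))
        stop("phylows: unknown statistics measure '", rest[1], "'")
      new_query_spec("stats", measure = rest[1]) },
    datatype = { need(1, "a data type")
      if (!rest[1] %in% c("DNA", "RNA", "protein", "standard", "continuous"))
        stop("phylows: unknown data type '", rest[1], "'")
      new_query_spec("datatype", datatype = rest[1], taxa = rest[-1]) },
    stop("phylows: unknown query type '", qtype, "'")
  )
  spec$format <- fmt
  spec$limit <- limit
  spec$offset <- offset
  spec
}

#' Render a query spec back into its PhyloWS URI
#'
#' Inverse of [parse_phylows_uri()]: `parse_phylows_uri(render_phylows_uri(s))`
#' reproduces `s` for every query type.
#'
#' @param spec A `query_spec`.
#' @return URI string.
#' @export
render_phylows_uri <- function(spec) {
  e <- function(x) vapply(x, utils::URLencode, "", reserved = TRUE,
                          USE.NAMES = FALSE)
  segs <- switch(spec$qtype,
                 tree = c("tree", e(spec$target_id)),
                 matrix = c("matrix", e(spec$target_id)),
                 list = "list",
                 taxa = c("taxa", e(spec$taxa)),
                 msc = c("msc", e(spec$target_id), e(spec$taxa)),
                 nca = c("nca", e(spec$target_id), e(spec$taxa)),
                 author = c("author", e(spec$value)),
                 method = c("method", e(spec$value)),
                 size = c("size", spec$direction, spec$criteria, spec$size),
                 property = c("property", spec$measure,
                              format(spec$q, scientific = FALSE)),
                 distance = c("distance", e(spec$target_id), spec$measure,
                              format(spec$q, scientific = FALSE)),
                 stats = c("stats", spec$measure),
                 datatype = c("datatype", spec$datatype, e(spec$taxa)),
                 stop("unknown query type '", spec$qtype, "'"))
  qs <- c(if (!is.null(spec$format))
    paste0("format=", names(ws_formats)[match(spec$format, ws_formats)][1]),
    if (!is.null(spec$limit)) paste0("limit=", spec$limit),
    if (!is.null(spec$offset)) paste0("offset=", spec$offset))
  paste0("/phylows/", paste(segs, collapse = "/"),
         if (length(qs)) paste0("?", paste(qs, collapse = "&")) else "")
}

paginate <- function(ids, spec) {
  ids <- sort(ids)
  off <- if (is.null(spec$offset)) 0L else spec$offset
  if (off >= length(ids)) return(character(0))
  ids <- ids[(off + 1L):length(ids)]
  if (!is.null(spec$limit)) ids <- utils::head(ids, spec$limit)
  ids
}

#' Execute a parsed query against a store
#'
#' Dispatches to the matching query operation.  Tree-valued results are
#' serialized in the requested format (default nexml); id-list results are
#' newline-delimited ids, sorted lexicographically, with `limit`/`offset`
#' applied after sorting so pagination is deterministic; statistics are
#' returned as JSON.  The store is never mutated and repeated identical
#' calls return identical payloads.
#'
#' @param store A `triple_store`.
#' @param spec A `query_spec` from [parse_phylows_uri()].
#' @return List with `payload` (text), `count` (result count before
#'   pagination), and `format`.
#' @export
execute_query <- function(store, spec) {
  stopifnot(inherits(spec, "query_spec"))
  base <- store$namespaces[["ps"]]
  tree_payload <- function(t) {
    fmt <- if (is.null(spec$format)) "nexml" else spec$format
    if (fmt %in% c("json", "text")) fmt <- "nexml"
    list(payload = export_phylo(t, fmt, base = base), count = 1L,
         format = fmt)
  }
  ids_payload <- function(ids) {
    total <- length(ids)
    list(payload = paste(paginate(ids, spec), collapse = "\n"),
         count = total, format = "text")
  }
  switch(
    spec$qtype,
    tree = tree_payload(store_get_tree(store, spec$target_id)),
    matrix = {
      for (ds_id in store_dataset_ids(store)) {
        ds <- triples_to_dataset(store, ds_id)
        i <- match(spec$target_id, names(ds$matrices))
        if (!is.na(i)) {
          fmt <- if (is.null(spec$format)) "nexml" else spec$format
          m <- ds$matrices[[i]]
          return(list(payload = export_phylo(m, fmt, base = base),
                      count = 1L, format = fmt))
        }
      }
      stop("matrix '", spec$target_id, "' not found in store")
    },
    list = ids_payload(store_tree_ids(store)),
    taxa = ids_payload(trees_containing_taxa(store, spec$taxa)),
    msc = {
      t <- store_get_tree(store, spec$target_id)
      res <- minimum_spanning_clade(t, spec$taxa)
      fmt <- if (is.null(spec$format)) "newick" else spec$format
      if (fmt %in% c("json", "text")) fmt <- "newick"
      list(payload = export_phylo(res$clade, fmt, base = base),
           count = 1L, format = fmt)
    },
    nca = {
      t <- store_get_tree(store, spec$target_id)
      n <- nearest_common_ancestor(t, spec$taxa)
      list(payload = paste0(n, "\t",
                            t$nodes$label[match(n, t$nodes$id)]),
           count = 1L, format = "text")
    },
    author = ids_payload(trees_by_metadata(store, "author", spec$value)),
    method = ids_payload(trees_by_metadata(store, "method", spec$value)),
    size = ids_payload(trees_by_size(store, spec$direction, spec$criteria,
                                     spec$size)),
    property = ids_payload(trees_by_property(store, spec$measure, spec$q)),
    distance = ids_payload(trees_within_distance(store, spec$target_id,
                                                 spec$measure, spec$q)),
    stats = {
      s <- measure_statistics(store, spec$measure)
      list(payload = jsonlite::toJSON(unclass(s), auto_unbox = TRUE,
                                      digits = NA),
           count = s$count, format = "json")
    },
    datatype = ids_payload(trees_by_datatype(store, spec$datatype,
                                             spec$taxa))
  )
}

#' Parse and execute a PhyloWS URI in one step
#'
#' @param store A `triple_store`.
#' @param uri A PhyloWS query URI.
#' @return As [execute_query()].
#' @export
phylows <- function(store, uri) {
  execute_query(store, parse_phylows_uri(uri))
}
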