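# The RDF triple store and the bidirectional dataset <-> triples mapping.
#
# Triples are held as a data frame (subject, predicate, object, otype) with
# set semantics; otype distinguishes IRIs from literals.  The CDAO term
# local-names used in the mapping are pinned in `cdao_vocabulary()` so the
# schema is a single testable table.  Annotation hubs (branch-length
# carriers, matrix cells) get deterministic skolem IRIs derived from their
# owners, keeping the mapping blank-node free and the triple counts exact.

DEFAULT_BASE <- "http://example.org/phylostore/"

default_namespaces <- function(base = DEFAULT_BASE) {
  c(rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    dc   = "http://purl.org/dc/elements/1.1/",
    cdao = "http://purl.obolibrary.org/obo/cdao.owl#",
    ps   = base)
}

#' The CDAO vocabulary table used by the triple mapping
#'
#' Class and property local-names (in the CDAO namespace) plus the
#' store-local terms (`ps:` namespace) used where CDAO has no term: dataset
#' scoping, matrix row/column bookkeeping, and `used_method` /
#' `used_software` metadata.
#'
#' @return Named character vector mapping role to qualified term.
#' @export
cdao_vocabulary <- function() {
  c(node = "cdao:Node", tu = "cdao:TU",
    rooted_tree = "cdao:RootedTree", unrooted_tree = "cdao:UnrootedTree",
    edge = "cdao:Edge", directed_edge = "cdao:DirectedEdge",
    edge_length = "cdao:EdgeLength",
    has_annotation = "cdao:has_Annotation", has_value = "cdao:has_Value",
    belongs_to_tree = "cdao:belongs_to_Tree",
    belongs_to_edge_as_parent = "cdao:belongs_to_Edge_as_Parent",
    belongs_to_edge_as_child = "cdao:belongs_to_Edge_as_Child",
    represents_tu = "cdao:represents_TU",
    matrix = "cdao:CharacterStateDataMatrix", character = "cdao:Character",
    belongs_to_matrix = "cdao:belongs_to_CharacterStateDataMatrix",
    belongs_to_tu = "cdao:belongs_to_TU",
    belongs_to_character = "cdao:belongs_to_Character",
    has_state = "cdao:has_State",
    type = "rdf:type", label = "rdfs:label",
    creator = "dc:creator", used_method = "ps:used_method",
    used_software = "ps:used_software",
    datatype = "ps:datatype", position = "ps:position",
    has_tu = "ps:has_TU")
}

empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), otype = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty triple store
#'
#' @param base Base IRI for store-local entity and term names; the CDAO,
#'   RDF(S) and Dublin Core namespaces are always declared.
#' @return An object of class `triple_store`.
#' @export
triple_store <- function(base = DEFAULT_BASE) {
  structure(list(triples = empty_triples(),
                 namespaces = default_namespaces(base)),
            class = "triple_store")
}

#' @export
print.triple_store <- function(x, ...) {
  cat(sprintf("<triple_store> %d triples, %d datasets\n",
              nrow(x$triples), length(store_dataset_ids(x))))
  invisible(x)
}

expand_term <- function(term, ns) {
  if (grepl("^https?://", term)) return(term)
  m <- regmatches(term, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", term))[[1]]
  if (length(m) != 3) stop("term '", term, "' is not namespaced")
  if (m[2] %in% names(ns)) return(paste0(ns[[m[2]]], m[3]))
  # user-supplied namespace: give it a stable IRI under the store base
  paste0(ns[["ps"]], "ns/", m[2], "#", m[3])
}

compact_term <- function(iri, ns) {
  for (p in names(ns)) {
    if (startsWith(iri, ns[[p]])) {
      local <- substring(iri, nchar(ns[[p]]) + 1L)
      if (p == "ps" && grepl("^ns/([^#]+)#", local))
        return(sub("^ns/([^#]+)#(.*)$", "\\1:\\2", local))
      return(paste0(p, ":", local))
    }
  }
  iri
}

enc <- function(x) vapply(x, utils::URLencode, "", reserved = TRUE,
                          USE.NAMES = FALSE)
dec <- function(x) vapply(x, utils::URLdecode, "", USE.NAMES = FALSE)

dataset_iri <- function(base, ds_id) paste0(base, "data/", enc(ds_id))

add_triples <- function(store, s, p, o, otype = "iri") {
  new <- data.frame(subject = s, predicate = p, object = o,
                    otype = otype, stringsAsFactors = FALSE)
  all <- rbind(store$triples, new)
  key <- paste(all$subject, all$predicate, all$object, all$otype, sep = "\r")
  store$triples <- all[!duplicated(key), , drop = FALSE]
  rownames(store$triples) <- NULL
  store
}

# ---- dataset -> triples -----------------------------------------------------

#' Map a dataset to CDAO triples
#'
#' Applies the package's documented mapping: one type triple per tree; per
#' node a `cdao:Node` type triple and a tree-membership triple; per leaf a
#' `represents_TU` triple plus TU type and label triples; per edge a type
#' triple, a membership triple and the two
#' `belongs_to_Edge_as_Parent`/`..._as_Child` triples; per measured branch
#' length a skolem annotation hub with `EdgeLength` type and `has_Value`;
#' matrices per cell.  A rooted tree with `V` nodes, `E` edges, `L` leaves
#' and `B` measured branch lengths thus yields `1 + 2V + 3L + 4E + 3B`
#' tree-derived triples.  Output is deterministic for a given dataset.
#'
#' @param ds A `cdao_dataset`.
#' @param base Base IRI for entity names.
#' @return Triple data frame (columns `subject`, `predicate`, `object`,
#'   `otype`), the `triples` component of a [triple_store()].
#' @export
dataset_to_triples <- function(ds, base = DEFAULT_BASE) {
  validate_dataset(ds)
  ns <- default_namespaces(base)
  voc <- cdao_vocabulary()
  q <- function(role) expand_term(voc[[role]], ns)
  dsi <- dataset_iri(base, ds$id)
  S <- character(0); P <- character(0); O <- character(0); OT <- character(0)
  emit <- function(s, p, o, ot = "iri") {
    n <- max(length(s), length(o))
    if (!n) return(invisible())
    S <<- c(S, rep_len(s, n)); P <<- c(P, rep_len(p, n))
    O <<- c(O, rep_len(o, n)); OT <<- c(OT, rep_len(ot, n))
  }
  tu_iri <- function(id) paste0(dsi, "/tu/", enc(id))
  tu_lab <- stats::setNames(ds$tus$label, ds$tus$id)

  for (t in ds$trees) {
    ti <- paste0(dsi, "/tree/", enc(t$id))
    ni <- function(id) paste0(ti, "/node/", enc(id))
    emit(ti, q("type"), q(if (isTRUE(t$rooted)) "rooted_tree" else "unrooted_tree"))
    emit(ni(t$nodes$id), q("type"), q("node"))
    emit(ni(t$nodes$id), q("belongs_to_tree"), ti)
    # internal labels that are not synthesized placeholders are kept
    internal <- is.na(t$nodes$tu_ref)
    named <- internal & !grepl("^#node[0-9]+$", t$nodes$label)
    if (any(named))
      emit(ni(t$nodes$id[named]), q("label"), t$nodes$label[named], "literal")
    leaf <- t$nodes[!internal, , drop = FALSE]
    emit(ni(leaf$id), q("represents_tu"), tu_iri(leaf$tu_ref))
    emit(tu_iri(leaf$tu_ref), q("type"), q("tu"))
    emit(tu_iri(leaf$tu_ref), q("label"),
         unname(tu_lab[leaf$tu_ref]), "literal")
    if (nrow(t$edges)) {
      ei <- paste0(ti, "/edge/", enc(t$edges$id))
      emit(ei, q("type"),
           q(if (isTRUE(t$rooted)) "directed_edge" else "edge"))
      emit(ei, q("belongs_to_tree"), ti)
      emit(ni(t$edges$parent), q("belongs_to_edge_as_parent"), ei)
      emit(ni(t$edges$child), q("belongs_to_edge_as_child"), ei)
      has_len <- !is.na(t$edges$length)
      if (any(has_len)) {
        ai <- paste0(ei[has_len], "/length")
        emit(ei[has_len], q("has_annotation"), ai)
        emit(ai, q("type"), q("edge_length"))
        emit(ai, q("has_value"),
             format(t$edges$length[has_len], digits = 15,
                    scientific = FALSE), "literal")
      }
    }
  }

  for (m in ds$matrices) {
    mi <- paste0(dsi, "/matrix/", enc(m$id))
    emit(mi, q("type"), q("matrix"))
    emit(mi, q("datatype"), m$datatype, "literal")
    emit(mi, q("has_tu"), tu_iri(m$tus$id))
    emit(tu_iri(m$tus$id), q("type"), q("tu"))
    emit(tu_iri(m$tus$id), q("label"), unname(tu_lab[m$tus$id]), "literal")
    ci <- function(id) paste0(mi, "/char/", enc(id))
    emit(ci(m$characters$id), q("type"), q("character"))
    emit(ci(m$characters$id), q("belongs_to_matrix"), mi)
    emit(ci(m$characters$id), q("position"),
         as.character(seq_len(nrow(m$characters))), "literal")
    if (nrow(m$cells)) {
      celli <- paste0(mi, "/cell/", enc(m$cells$tu_ref), "_",
                      enc(m$cells$character_ref))
      emit(celli, q("belongs_to_tu"), tu_iri(m$cells$tu_ref))
      emit(celli, q("belongs_to_character"), ci(m$cells$character_ref))
      emit(celli, q("has_state"), m$cells$state, "literal")
    }
  }

  for (i in seq_len(nrow(ds$annotations))) {
    a <- ds$annotations[i, ]
    subj <- annotation_subject_iri(ds, a$subject, base)
    emit(subj, expand_term(a$predicate, ns), a$value, "literal")
  }

  out <- data.frame(subject = S, predicate = P, object = O, otype = OT,
                    stringsAsFactors = FALSE)
  key <- paste(out$subject, out$predicate, out$object, out$otype, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

annotation_subject_iri <- function(ds, subject, base) {
  dsi <- dataset_iri(base, ds$id)
  if (identical(subject, ds$id)) return(dsi)
  if (subject %in% names(ds$trees)) return(paste0(dsi, "/tree/", enc(subject)))
  if (subject %in% names(ds$matrices))
    return(paste0(dsi, "/matrix/", enc(subject)))
  if (subject %in% ds$tus$id) return(paste0(dsi, "/tu/", enc(subject)))
  dsi
}

#' Add a dataset's triples to a store
#'
#' @param store A `triple_store`.
#' @param ds A `cdao_dataset`.
#' @return The updated store.
#' @export
store_add_dataset <- function(store, ds) {
  tr <- dataset_to_triples(ds, base = store$namespaces[["ps"]])
  add_triples(store, tr$subject, tr$predicate, tr$object, tr$otype)
}

#' Dataset identifiers present in a store
#'
#' @param store A `triple_store`.
#' @return Character vector of dataset ids.
#' @export
store_dataset_ids <- function(store) {
  pre <- paste0(store$namespaces[["ps"]], "data/")
  subj <- store$triples$subject[startsWith(store$triples$subject, pre)]
  ids <- unique(sub("/.*$", "", substring(subj, nchar(pre) + 1L)))
  sort(dec(ids))
}

# ---- triples -> dataset -----------------------------------------------------

natural_sort <- function(x) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", x)))
  x[order(is.na(num), num, x)]
}

#' Reconstruct a dataset from its triples
#'
#' Inverse of [dataset_to_triples()]: for a store holding a complete image
#' of the dataset, `triples_to_dataset(store, id)` returns a dataset equal
#' to the original up to identifier normalization (node/edge/TU ids are
#' regenerated; synthesized internal labels are renumbered).  Incomplete
#' graphs — an edge endpoint without a `cdao:Node` type triple, a dangling
#' reference — raise an "incomplete graph" error naming the offending
#' subject.
#'
#' @param store A `triple_store`.
#' @param dataset_id Dataset identifier (as listed by [store_dataset_ids()]).
#' @return A `cdao_dataset`.
#' @export
triples_to_dataset <- function(store, dataset_id) {
  ns <- store$namespaces
  base <- ns[["ps"]]
  voc <- cdao_vocabulary()
  q <- function(role) expand_term(voc[[role]], ns)
  dsi <- dataset_iri(base, dataset_id)
  pre <- paste0(dsi, "/")
  tr <- store$triples
  scoped <- tr[startsWith(tr$subject, pre) | tr$subject == dsi, , drop = FALSE]
  if (!nrow(scoped)) stop("dataset '", dataset_id, "' not found in store")
  obj_of <- function(s, p) scoped$object[scoped$subject == s &
                                           scoped$predicate == p]
  typed <- function(type_iri)
    scoped$subject[scoped$predicate == q("type") & scoped$object == type_iri]
  tail_id <- function(iri) dec(sub(".*/", "", iri))

  tus_seen <- typed(q("tu"))
  tu_id <- tail_id(tus_seen)
  tu_label <- vapply(tus_seen, function(s) {
    l <- obj_of(s, q("label"))
    if (!length(l)) stop("incomplete graph: TU ", s, " has no label")
    l[1]
  }, "")
  ord <- order(match(tu_id, natural_sort(tu_id)))
  tus <- data.frame(id = tu_id[ord], label = unname(tu_label[ord]),
                    stringsAsFactors = FALSE)
  tu_of_iri <- stats::setNames(tu_id, tus_seen)

  trees <- list()
  tree_iris <- c(typed(q("rooted_tree")), typed(q("unrooted_tree")))
  for (ti in natural_sort(tree_iris)) {
    rooted <- ti %in% typed(q("rooted_tree"))
    node_iris <- scoped$subject[scoped$predicate == q("belongs_to_tree") &
                                  scoped$object == ti &
                                  scoped$subject %in% typed(q("node"))]
    edge_iris <- scoped$subject[scoped$predicate == q("belongs_to_tree") &
                                  scoped$object == ti &
                                  !scoped$subject %in% node_iris]
    etype <- q(if (rooted) "directed_edge" else "edge")
    for (e in edge_iris)
      if (!e %in% typed(etype))
        stop("incomplete graph: edge ", e, " lacks its type triple")
    ends <- function(e, role) {
      n <- scoped$subject[scoped$predicate == q(role) & scoped$object == e]
      if (length(n) != 1)
        stop("incomplete graph: edge ", e, " lacks a ",
             sub("belongs_to_edge_as_", "", role), " node")
      if (!n %in% typed(q("node")))
        stop("incomplete graph: node ", n, " lacks its cdao:Node type triple")
      n
    }
    edge_iris <- natural_sort(edge_iris)
    parents <- vapply(edge_iris, ends, "", role = "belongs_to_edge_as_parent")
    children <- vapply(edge_iris, ends, "", role = "belongs_to_edge_as_child")
    lengths <- vapply(edge_iris, function(e) {
      a <- obj_of(e, q("has_annotation"))
      a <- a[a %in% typed(q("edge_length"))]
      if (!length(a)) return(NA_real_)
      as.numeric(obj_of(a[1], q("has_value"))[1])
    }, 0)
    node_iris <- natural_sort(node_iris)
    nid <- tail_id(node_iris)
    tu_ref <- vapply(node_iris, function(n) {
      t <- obj_of(n, q("represents_tu"))
      if (!length(t)) return(NA_character_)
      if (!t[1] %in% tus_seen)
        stop("incomplete graph: node ", n, " represents unknown TU ", t[1])
      unname(tu_of_iri[t[1]])
    }, "")
    label <- vapply(node_iris, function(n) {
      l <- obj_of(n, q("label"))
      if (length(l)) l[1] else NA_character_
    }, "")
    label[!is.na(tu_ref)] <- tus$label[match(tu_ref[!is.na(tu_ref)], tus$id)]
    k <- cumsum(is.na(label))
    label[is.na(label)] <- paste0("#node", k[is.na(label)])
    nodes <- data.frame(id = nid, label = label, tu_ref = tu_ref,
                        stringsAsFactors = FALSE)
    edf <- data.frame(id = tail_id(edge_iris),
                      parent = nid[match(parents, node_iris)],
                      child = nid[match(children, node_iris)],
                      length = unname(lengths), stringsAsFactors = FALSE)
    root <- if (rooted) setdiff(nid, edf$child) else NA_character_
    if (rooted && length(root) != 1)
      stop("incomplete graph: tree ", ti, " has no unique root")
    t <- structure(list(id = tail_id(ti), nodes = nodes, edges = edf,
                        rooted = rooted, root = root),
                   class = "cdao_tree")
    validate_tree(t)
    trees[[length(trees) + 1L]] <- t
  }

  matrices <- list()
  for (mi in natural_sort(typed(q("matrix")))) {
    datatype <- obj_of(mi, q("datatype"))
    if (!length(datatype))
      stop("incomplete graph: matrix ", mi, " has no datatype")
    row_iris <- obj_of(mi, q("has_tu"))
    row_ids <- natural_sort(unname(tu_of_iri[row_iris]))
    char_iris <- scoped$subject[scoped$predicate == q("belongs_to_matrix") &
                                  scoped$object == mi]
    pos <- vapply(char_iris, function(c)
      as.integer(obj_of(c, q("position"))[1]), 0L)
    char_iris <- char_iris[order(pos)]
    cid <- tail_id(char_iris)
    cell_subj <- scoped$subject[scoped$predicate == q("belongs_to_character") &
                                  scoped$object %in% char_iris]
    cells <- do.call(rbind, lapply(cell_subj, function(cs) {
      tu <- obj_of(cs, q("belongs_to_tu"))
      ch <- obj_of(cs, q("belongs_to_character"))
      st <- obj_of(cs, q("has_state"))
      if (!length(tu) || !length(st))
        stop("incomplete graph: cell ", cs, " is missing its TU or state")
      data.frame(tu_ref = unname(tu_of_iri[tu[1]]),
                 character_ref = tail_id(ch[1]), state = st[1],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cells))
      cells <- data.frame(tu_ref = character(), character_ref = character(),
                          state = character(), stringsAsFactors = FALSE)
    matrices[[length(matrices) + 1L]] <- new_character_matrix(
      tail_id(mi),
      tus = data.frame(id = row_ids,
                       label = tus$label[match(row_ids, tus$id)],
                       stringsAsFactors = FALSE),
      characters = data.frame(id = cid, label = cid,
                              stringsAsFactors = FALSE),
      cells = cells, datatype = datatype[1])
  }

  # any literal triple whose predicate is outside the mapping vocabulary is
  # an annotation
  voc_iris <- vapply(cdao_vocabulary(), expand_term, "", ns = ns)
  extra <- scoped[!scoped$predicate %in% voc_iris & scoped$otype == "literal",
                  , drop = FALSE]
  ann <- data.frame(subject = character(), predicate = character(),
                    value = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(extra))) {
    subj <- extra$subject[i]
    sid <- if (subj == dsi) dataset_id else tail_id(subj)
    ann <- rbind(ann, data.frame(subject = sid,
                                 predicate = compact_term(extra$predicate[i], ns),
                                 value = extra$object[i],
                                 stringsAsFactors = FALSE))
  }
  new_dataset(dataset_id, tus = tus, trees = trees, matrices = matrices,
              annotations = ann)
}

# ---- pattern matching -------------------------------------------------------

#' Match triples against an (s, p, o) pattern
#'
#' `NULL` (or `"?"`) in a position is a wildcard; qualified names
#' (`rdf:type`, `cdao:Node`) are expanded through the store's namespace
#' table.
#'
#' @param store A `triple_store`.
#' @param s,p,o Pattern positions: IRI, qualified name, literal, or wildcard.
#' @return Data frame of matching triples.
#' @export
match_triples <- function(store, s = NULL, p = NULL, o = NULL) {
  tr <- store$triples
  fix <- function(x) if (is.null(x) || identical(x, "?")) NULL
  else expand_term_or_literal(x, store$namespaces)
  s <- fix(s); p <- fix(p); o <- fix(o)
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(s)) keep <- keep & tr$subject == s
  if (!is.null(p)) keep <- keep & tr$predicate == p
  if (!is.null(o)) keep <- keep & tr$object == o
  out <- tr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

expand_term_or_literal <- function(x, ns) {
  if (grepl("^https?://", x)) return(x)
  if (grepl("^[A-Za-z][A-Za-z0-9_.-]*:", x)) {
    pfx <- sub(":.*$", "", x)
    if (pfx %in% names(ns)) return(expand_term(x, ns))
  }
  x   # treated as a literal value
}

#' Conjunctive basic-graph-pattern matching
#'
#' Matches a list of `(s, p, o)` patterns sharing `?variables` and returns
#' the consistent variable bindings — the pattern-match contract standing
#' behind the searching class of domain queries.
#'
#' @param store A `triple_store`.
#' @param patterns List of length-3 character vectors; positions starting
#'   with `?` are variables, everything else is matched as in
#'   [match_triples()].
#' @return Data frame with one column per variable (without the `?`), one
#'   row per consistent binding.
#' @export
match_bgp <- function(store, patterns) {
  bindings <- NULL
  for (pat in patterns) {
    stopifnot(length(pat) == 3)
    is_var <- startsWith(pat, "?")
    cand <- match_triples(store,
                          s = if (is_var[1]) NULL else pat[1],
                          p = if (is_var[2]) NULL else pat[2],
                          o = if (is_var[3]) NULL else pat[3])
    cols <- c("subject", "predicate", "object")[is_var]
    vars <- sub("^\\?", "", pat[is_var])
    tab <- cand[, cols, drop = FALSE]
    names(tab) <- vars
    # a variable repeated inside one pattern must bind consistently
    if (anyDuplicated(vars)) {
      keep <- Reduce(`&`, lapply(which(duplicated(vars)), function(i)
        tab[[i]] == tab[[match(vars[i], vars)]]))
      tab <- tab[keep, !duplicated(vars), drop = FALSE]
    }
    tab <- unique(tab)
    bindings <- if (is.null(bindings)) tab
    else if (length(intersect(names(bindings), names(tab))))
      merge(bindings, tab, by = intersect(names(bindings), names(tab)))
    else merge(bindings, tab, by = NULL)   # cartesian, rare
    if (!nrow(bindings)) break
  }
  unique(bindings)
}

#' Annotate an entity in the store
#'
#' Adds one (subject, predicate, literal) triple; the predicate must be a
#' namespaced term (CDAO, Dublin Core, or a user-supplied prefix, which is
#' skolemized under the store base).  Set semantics make repeated identical
#' annotations no-ops.
#'
#' @param store A `triple_store`.
#' @param subject Entity IRI, or a dataset id known to the store.
#' @param predicate Namespaced term, e.g. `"dc:creator"`.
#' @param value Literal value.
#' @return The updated store.
#' @export
annotate_store <- function(store, subject, predicate, value) {
  if (!grepl(":", predicate, fixed = TRUE))
    stop("annotation predicate '", predicate,
         "' must be a namespaced term (e.g. dc:creator)")
  pred <- expand_term(predicate, store$namespaces)
  if (!grepl("^https?://", subject)) {
    if (subject %in% store_dataset_ids(store))
      subject <- dataset_iri(store$namespaces[["ps"]], subject)
    else subject <- paste0(store$namespaces[["ps"]], "entity/", enc(subject))
  }
  add_triples(store, subject, pred, value, "literal")
}

# ---- N-Triples persistence --------------------------------------------------

nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

nt_unescape <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Persist a store as canonical N-Triples
#'
#' Lines are sorted, so identical stores serialize bit-identically.
#'
#' @param store A `triple_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_store <- function(store, path) {
  tr <- store$triples
  lines <- if (!nrow(tr)) character(0) else {
    obj <- ifelse(tr$otype == "iri", paste0("<", tr$object, ">"),
                  paste0("\"", nt_escape(tr$object), "\""))
    paste0("<", tr$subject, "> <", tr$predicate, "> ", obj, " .")
  }
  writeLines(sort(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Load a store from an N-Triples file
#'
#' @param path N-Triples file path.
#' @param base Store base IRI (namespace table of the result).
#' @return A `triple_store`; malformed lines are reported with their line
#'   number.
#' @export
load_store <- function(path, base = DEFAULT_BASE) {
  lines <- readLines(path, warn = FALSE)
  store <- triple_store(base)
  pat <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+",
                "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"",
                "(?:@[A-Za-z-]+|\\^\\^<[^>]*>)?)\\s*\\.\\s*$")
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  S <- character(0); P <- character(0); O <- character(0); OT <- character(0)
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    m <- regmatches(lines[i], regexec(pat, lines[i], perl = TRUE))[[1]]
    if (!length(m))
      stop("malformed N-Triples at line ", i, ": ", trimws(lines[i]))
    S <- c(S, m[2]); P <- c(P, m[3])
    if (nzchar(m[4])) { O <- c(O, m[4]); OT <- c(OT, "iri") }
    else { O <- c(O, nt_unescape(m[5])); OT <- c(OT, "literal") }
  }
  add_triples(store, S, P, O, OT)
}
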