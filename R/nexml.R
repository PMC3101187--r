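# nexml reading and writing, built on xml2.  Elements are matched by local
# name so schema-version namespace drift does not break parsing.  The cell
# dialect written here is <row otu=...><cell char=... state=.../></row> with
# literal state symbols; <seq> text rows and <state>-table indirection are
# accepted on input.

nx_find <- function(node, name) {
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
}

nx_children <- function(node, name) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_name(kids) == name]
}

#' Parse a nexml document into a dataset
#'
#' `<otus>/<otu>` elements become TUs; `<trees>/<tree>` elements (sequences
#' of `<node>` and `<edge>` elements, with `otu` attributes linking leaves)
#' become trees; `<characters>` blocks become character matrices; `<meta>`
#' elements on the document root become annotations.
#'
#' @param text nexml XML text (root element `<nexml>`).
#' @param id Dataset identifier.
#' @return A `cdao_dataset`.
#' @export
parse_nexml <- function(text, id = "ds1") {
  doc <- xml2::read_xml(text)
  if (xml2::xml_name(doc) != "nexml") stop("nexml: root element must be <nexml>")

  tus <- new_tu(character(), character())
  otu_map <- character(0)   # document otu id -> internal tu id
  for (otus in nx_children(doc, "otus")) {
    for (otu in nx_children(otus, "otu")) {
      oid <- xml2::xml_attr(otu, "id")
      lab <- xml2::xml_attr(otu, "label")
      if (is.na(lab) || !nzchar(lab)) lab <- oid
      tid <- paste0("tu", nrow(tus) + 1L)
      tus <- rbind(tus, data.frame(id = tid, label = lab,
                                   stringsAsFactors = FALSE))
      otu_map[oid] <- tid
    }
  }

  trees <- list()
  for (trs in nx_children(doc, "trees")) {
    for (tr in nx_children(trs, "tree")) {
      tid <- xml2::xml_attr(tr, "id")
      nodes_xml <- nx_children(tr, "node")
      nid <- xml2::xml_attr(nodes_xml, "id")
      nlab <- xml2::xml_attr(nodes_xml, "label")
      notu <- xml2::xml_attr(nodes_xml, "otu")
      if (length(notu)) {
        bad <- setdiff(notu[!is.na(notu)], names(otu_map))
        if (length(bad))
          stop("nexml: node references undeclared otu '", bad[1], "'")
      }
      edges_xml <- nx_children(tr, "edge")
      esrc <- xml2::xml_attr(edges_xml, "source")
      etgt <- xml2::xml_attr(edges_xml, "target")
      elen <- suppressWarnings(as.numeric(xml2::xml_attr(edges_xml, "length")))
      bad <- setdiff(c(esrc, etgt), nid)
      if (length(bad))
        stop("nexml: edge references undeclared node '", bad[1], "'")
      tu_ref <- unname(otu_map[notu])
      label <- ifelse(!is.na(tu_ref), tus$label[match(tu_ref, tus$id)],
                      ifelse(!is.na(nlab) & nzchar(nlab), nlab, NA))
      k <- cumsum(is.na(label))
      label[is.na(label)] <- paste0("#node", k[is.na(label)])
      nodes <- data.frame(id = nid, label = label, tu_ref = tu_ref,
                          stringsAsFactors = FALSE)
      edf <- data.frame(id = paste0("e", seq_along(esrc)),
                        parent = esrc, child = etgt, length = elen,
                        stringsAsFactors = FALSE)
      root <- setdiff(nid, etgt)
      if (length(root) != 1)
        stop("nexml: tree ", tid, " does not have a unique root")
      t <- structure(list(id = if (is.na(tid)) paste0("t", length(trees) + 1L)
                          else tid,
                          nodes = nodes, edges = edf,
                          rooted = TRUE, root = root),
                     class = "cdao_tree")
      validate_tree(t)
      trees[[length(trees) + 1L]] <- t
    }
  }

  matrices <- list()
  for (chs in nx_children(doc, "characters")) {
    mid <- xml2::xml_attr(chs, "id")
    if (is.na(mid)) mid <- paste0("m", length(matrices) + 1L)
    cls <- xml2::xml_attr(chs, "type")
    if (is.na(cls)) cls <- xml2::xml_attr(chs, "xsi:type")
    datatype <- if (is.na(cls)) "standard"
    else if (grepl("Dna", cls)) "DNA" else if (grepl("Rna", cls)) "RNA"
    else if (grepl("Protein", cls)) "protein"
    else if (grepl("Continuous", cls)) "continuous" else "standard"
    # state tables (id -> symbol), optional
    state_sym <- character(0)
    for (st in nx_find(chs, "state")) {
      sid <- xml2::xml_attr(st, "id"); sym <- xml2::xml_attr(st, "symbol")
      if (!is.na(sid) && !is.na(sym)) state_sym[sid] <- sym
    }
    fmt <- nx_children(chs, "format")
    char_ids <- character(0)
    if (length(fmt)) {
      ch_xml <- nx_children(fmt[[1]], "char")
      char_ids <- xml2::xml_attr(ch_xml, "id")
    }
    mtx <- nx_children(chs, "matrix")
    row_tus <- character(0); cells <- list()
    if (length(mtx)) for (row in nx_children(mtx[[1]], "row")) {
      oid <- xml2::xml_attr(row, "otu")
      if (!oid %in% names(otu_map))
        stop("nexml: row references undeclared otu '", oid, "'")
      tu <- otu_map[[oid]]
      row_tus <- c(row_tus, tu)
      cell_xml <- nx_children(row, "cell")
      if (length(cell_xml)) {
        cref <- xml2::xml_attr(cell_xml, "char")
        stat <- xml2::xml_attr(cell_xml, "state")
        stat <- ifelse(stat %in% names(state_sym), state_sym[stat], stat)
        cells[[length(cells) + 1L]] <-
          data.frame(tu_ref = tu, character_ref = cref, state = stat,
                     stringsAsFactors = FALSE)
        if (!length(char_ids)) char_ids <- unique(cref)
      } else {
        sq <- nx_children(row, "seq")
        if (length(sq)) {
          st <- strsplit(gsub("\\s", "", xml2::xml_text(sq[[1]])), "")[[1]]
          if (!length(char_ids)) char_ids <- paste0(mid, "c", seq_along(st))
          if (length(st) != length(char_ids))
            stop("nexml: <seq> length differs from declared characters")
          cells[[length(cells) + 1L]] <-
            data.frame(tu_ref = tu, character_ref = char_ids, state = st,
                       stringsAsFactors = FALSE)
        }
      }
    }
    clab <- sub(paste0("^", mid), "", char_ids)
    matrices[[length(matrices) + 1L]] <- new_character_matrix(
      mid,
      tus = data.frame(id = row_tus,
                       label = tus$label[match(row_tus, tus$id)],
                       stringsAsFactors = FALSE),
      characters = data.frame(id = char_ids,
                              label = ifelse(nzchar(clab), clab, char_ids),
                              stringsAsFactors = FALSE),
      cells = if (length(cells)) do.call(rbind, cells) else
        data.frame(tu_ref = character(), character_ref = character(),
                   state = character(), stringsAsFactors = FALSE),
      datatype = datatype)
  }

  ann <- data.frame(subject = character(), predicate = character(),
                    value = character(), stringsAsFactors = FALSE)
  for (meta in nx_children(doc, "meta")) {
    prop <- xml2::xml_attr(meta, "property")
    val <- xml2::xml_attr(meta, "content")
    if (!is.na(prop) && !is.na(val))
      ann <- rbind(ann, data.frame(subject = id, predicate = prop,
                                   value = val, stringsAsFactors = FALSE))
  }
  new_dataset(id, tus = tus, trees = trees, matrices = matrices,
              annotations = ann)
}

#' Serialize a dataset to nexml
#'
#' Writes `<otus>`, one `<characters>` block per matrix (cell encoding with
#' literal state symbols) and `<trees>` with explicit `<node>`/`<edge>`
#' elements; dataset annotations become `<meta>` elements on the root.
#'
#' @param ds A `cdao_dataset`.
#' @return nexml XML text.
#' @export
write_nexml <- function(ds) {
  doc <- xml2::xml_new_root("nexml", version = "0.9",
                            xmlns = "http://www.nexml.org/2009")
  for (i in seq_len(nrow(ds$annotations))) {
    a <- ds$annotations[i, ]
    if (a$predicate == "ps:nexus_block") next
    xml2::xml_add_child(doc, "meta", property = a$predicate,
                        content = a$value, datatype = "xsd:string")
  }
  otus <- xml2::xml_add_child(doc, "otus", id = "otus1")
  for (i in seq_len(nrow(ds$tus)))
    xml2::xml_add_child(otus, "otu", id = ds$tus$id[i],
                        label = ds$tus$label[i])
  for (m in ds$matrices) {
    cls <- switch(m$datatype, DNA = "nex:DnaCells", RNA = "nex:RnaCells",
                  protein = "nex:ProteinCells",
                  continuous = "nex:ContinuousCells", "nex:StandardCells")
    chs <- xml2::xml_add_child(doc, "characters", id = m$id, otus = "otus1",
                               type = cls)
    fmt <- xml2::xml_add_child(chs, "format")
    for (i in seq_len(nrow(m$characters)))
      xml2::xml_add_child(fmt, "char", id = m$characters$id[i],
                          label = m$characters$label[i])
    mtx <- xml2::xml_add_child(chs, "matrix")
    for (i in seq_len(nrow(m$tus))) {
      row <- xml2::xml_add_child(mtx, "row",
                                 id = paste0(m$id, "r", i),
                                 otu = m$tus$id[i])
      cc <- m$cells[m$cells$tu_ref == m$tus$id[i], , drop = FALSE]
      cc <- cc[order(match(cc$character_ref, m$characters$id)), , drop = FALSE]
      for (j in seq_len(nrow(cc)))
        xml2::xml_add_child(row, "cell", char = cc$character_ref[j],
                            state = cc$state[j])
    }
  }
  if (length(ds$trees)) {
    trs <- xml2::xml_add_child(doc, "trees", id = "trees1", otus = "otus1")
    for (t in ds$trees) {
      tr <- xml2::xml_add_child(trs, "tree", id = t$id,
                                type = "nex:FloatTree")
      for (i in seq_len(nrow(t$nodes))) {
        nd <- t$nodes[i, ]
        args <- list(tr, "node", id = nd$id, label = nd$label)
        if (!is.na(nd$tu_ref)) args$otu <- nd$tu_ref
        if (identical(nd$id, t$root)) args$root <- "true"
        do.call(xml2::xml_add_child, args)
      }
      for (i in seq_len(nrow(t$edges))) {
        e <- t$edges[i, ]
        args <- list(tr, "edge", id = e$id, source = e$parent,
                     target = e$child)
        if (!is.na(e$length))
          args$length <- format(e$length, digits = 15, scientific = FALSE)
        do.call(xml2::xml_add_child, args)
      }
    }
  }
  as.character(doc)
}
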