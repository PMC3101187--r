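# NEXUS reading and writing.
#
# Dialect: square-bracket comments are stripped anywhere; commands are
# case-insensitive; TAXA, CHARACTERS/DATA and TREES blocks are interpreted;
# other blocks are preserved verbatim as dataset annotations (predicate
# ps:nexus_block) so no user content is silently dropped.

strip_nexus_comments <- function(text) {
  gsub("\\[[^][]*\\]", "", text)
}

# split into top-level commands (";"-terminated), honoring quoted labels
nexus_commands <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- character(0); buf <- character(0); inq <- FALSE
  for (ch in chars) {
    if (ch == "'") inq <- !inq
    if (ch == ";" && !inq) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else buf <- c(buf, ch)
  }
  trimws(out[nzchar(trimws(out))])
}

nexus_tokens <- function(cmd) {
  m <- gregexpr("'(?:[^']|'')*'|[^\\s=]+|=", cmd, perl = TRUE)[[1]]
  toks <- regmatches(cmd, list(m))[[1]]
  vapply(toks, function(t) {
    if (startsWith(t, "'")) gsub("''", "'", substr(t, 2, nchar(t) - 1)) else t
  }, "", USE.NAMES = FALSE)
}

nexus_keyval <- function(toks) {
  # "DATATYPE = DNA MISSING = ?" -> named vector
  out <- character(0)
  i <- 1L
  while (i <= length(toks)) {
    if (i + 2 <= length(toks) && toks[i + 1] == "=") {
      out[toupper(toks[i])] <- toks[i + 2]; i <- i + 3L
    } else i <- i + 1L
  }
  out
}

#' Parse a NEXUS file into a dataset
#'
#' Interprets the TAXA block (TAXLABELS) as TUs, CHARACTERS/DATA blocks
#' (FORMAT DATATYPE/MISSING/GAP, MATRIX rows; interleaved rows for the same
#' taxon are concatenated) as character matrices, and the TREES block
#' (optional TRANSLATE table, `TREE name = <newick>`) as trees whose leaf
#' labels are resolved through the translate table.  Unrecognized blocks are
#' kept as annotations.
#'
#' @param text NEXUS file content (must start with `#NEXUS`).
#' @param id Dataset identifier.
#' @return A `cdao_dataset`.
#' @export
parse_nexus <- function(text, id = "ds1") {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE))
    stop("nexus: file must begin with #NEXUS")
  body <- strip_nexus_comments(sub("^\\s*#NEXUS", "", text, ignore.case = TRUE))
  cmds <- nexus_commands(body)

  tus <- new_tu(character(), character())
  trees <- list(); matrices <- list()
  ann <- data.frame(subject = character(), predicate = character(),
                    value = character(), stringsAsFactors = FALSE)
  tu_id_for <- function(label) {
    i <- match(label, tus$label)
    if (is.na(i)) {
      tus <<- rbind(tus, data.frame(id = paste0("tu", nrow(tus) + 1L),
                                    label = label, stringsAsFactors = FALSE))
      i <- nrow(tus)
    }
    tus$id[i]
  }

  i <- 1L; n_tree <- 0L; n_mat <- 0L
  while (i <= length(cmds)) {
    toks <- nexus_tokens(cmds[i])
    if (toupper(toks[1]) != "BEGIN") { i <- i + 1L; next }
    block <- toupper(toks[2])
    j <- i + 1L
    block_cmds <- character(0)
    while (j <= length(cmds)) {
      t2 <- nexus_tokens(cmds[j])
      if (toupper(t2[1]) %in% c("END", "ENDBLOCK")) break
      block_cmds <- c(block_cmds, cmds[j])
      j <- j + 1L
    }
    if (block == "TAXA") {
      for (bc in block_cmds) {
        bt <- nexus_tokens(bc)
        if (toupper(bt[1]) == "TAXLABELS")
          for (lab in bt[-1]) tu_id_for(lab)
      }
    } else if (block %in% c("CHARACTERS", "DATA")) {
      n_mat <- n_mat + 1L
      matrices[[length(matrices) + 1L]] <-
        parse_nexus_matrix(block_cmds, paste0("m", n_mat), tu_id_for)
    } else if (block == "TREES") {
      translate <- character(0)
      for (bc in block_cmds) {
        bt <- nexus_tokens(bc)
        kw <- toupper(bt[1])
        if (kw == "TRANSLATE") {
          pairs <- bt[-1]
          pairs <- pairs[pairs != ","]
          # entries may carry trailing commas when quoting kept them attached
          pairs <- sub(",$", "", pairs)
          keys <- pairs[seq(1, length(pairs), by = 2)]
          vals <- pairs[seq(2, length(pairs), by = 2)]
          translate <- stats::setNames(vals, keys)
        } else if (kw %in% c("TREE", "UTREE")) {
          n_tree <- n_tree + 1L
          name <- bt[2]
          nwk <- sub("^[^=]*=", "", bc)
          nwk <- sub("^\\s*(\\[[^]]*\\])?\\s*", "", nwk)  # [&R]/[&U] flag
          tr <- parse_newick(paste0(trimws(nwk), ";"),
                             id = if (nzchar(name)) name else paste0("t", n_tree))
          if (length(translate)) {
            leaf_ids <- tree_leaf_ids(tr)
            for (k in seq_len(nrow(tr$nodes))) {
              if (!tr$nodes$id[k] %in% leaf_ids) next
              lbl <- tr$nodes$label[k]
              if (lbl %in% names(translate)) {
                tr$nodes$label[k] <- translate[[lbl]]
              } else if (grepl("^[0-9]+$", lbl)) {
                stop("nexus: tree leaf '", lbl,
                     "' not found in TRANSLATE table")
              }
            }
          }
          tr$nodes$tu_ref[!is.na(tr$nodes$tu_ref)] <-
            vapply(tr$nodes$label[!is.na(tr$nodes$tu_ref)], tu_id_for, "")
          trees[[length(trees) + 1L]] <- tr
        }
      }
    } else {
      ann <- rbind(ann, data.frame(
        subject = id, predicate = "ps:nexus_block",
        value = paste(c(cmds[i], block_cmds, "END"), collapse = ";\n"),
        stringsAsFactors = FALSE))
    }
    i <- j + 1L
  }
  # register any matrix taxa met only in matrices
  new_dataset(id, tus = tus, trees = trees, matrices = matrices,
              annotations = ann)
}

parse_nexus_matrix <- function(block_cmds, mid, tu_id_for) {
  datatype <- "standard"; ntax <- NA_integer_; nchar_ <- NA_integer_
  rows <- list(); order_seen <- character(0)
  for (bc in block_cmds) {
    bt <- nexus_tokens(bc)
    kw <- toupper(bt[1])
    if (kw == "DIMENSIONS") {
      kv <- nexus_keyval(bt[-1])
      if ("NTAX" %in% names(kv)) ntax <- as.integer(kv[["NTAX"]])
      if ("NCHAR" %in% names(kv)) nchar_ <- as.integer(kv[["NCHAR"]])
    } else if (kw == "FORMAT") {
      kv <- nexus_keyval(bt[-1])
      if ("DATATYPE" %in% names(kv)) {
        dt <- toupper(kv[["DATATYPE"]])
        datatype <- switch(dt, DNA = "DNA", RNA = "RNA",
                           PROTEIN = "protein", CONTINUOUS = "continuous",
                           "standard")
      }
    } else if (kw == "MATRIX") {
      # line-oriented: each line is "taxon states..."; repeated taxa
      # (interleaved layout) have their fragments concatenated
      body <- sub("(?i)^\\s*MATRIX", "", bc, perl = TRUE)
      for (ln in strsplit(body, "\n", fixed = TRUE)[[1]]) {
        lt <- nexus_tokens(ln)
        if (!length(lt)) next
        taxon <- lt[1]
        states <- paste(lt[-1], collapse = "")
        rows[[taxon]] <- paste0(if (is.null(rows[[taxon]])) "" else rows[[taxon]],
                                states)
        if (!taxon %in% order_seen) order_seen <- c(order_seen, taxon)
      }
    }
  }
  if (!is.na(ntax) && length(rows) != ntax)
    stop("nexus: NTAX=", ntax, " but matrix has ", length(rows), " rows")
  lens <- vapply(rows, nchar, 0L)
  if (!is.na(nchar_) && any(lens != nchar_))
    stop("nexus: NCHAR=", nchar_, " but row lengths are ",
         paste(unique(lens), collapse = ","))
  build_matrix_from_rows(rows[order_seen], mid, datatype, tu_id_for)
}

# shared by the NEXUS/PHYLIP/MEGA readers: named character rows -> matrix
build_matrix_from_rows <- function(rows, mid, datatype, tu_id_for) {
  labs <- names(rows)
  tu_ids <- vapply(labs, tu_id_for, "")
  ncol_ <- unique(vapply(rows, nchar, 0L))
  if (length(ncol_) != 1)
    stop("matrix rows have inconsistent lengths: ",
         paste(ncol_, collapse = ","))
  chars <- data.frame(id = paste0(mid, "c", seq_len(ncol_)),
                      label = paste0("c", seq_len(ncol_)),
                      stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_along(labs), function(i) {
    st <- strsplit(rows[[i]], "", fixed = TRUE)[[1]]
    data.frame(tu_ref = unname(tu_ids[i]), character_ref = chars$id,
               state = st, stringsAsFactors = FALSE)
  }))
  new_character_matrix(mid,
                       tus = data.frame(id = unname(tu_ids), label = labs,
                                        stringsAsFactors = FALSE),
                       characters = chars, cells = cells, datatype = datatype)
}

nexus_quote <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.#-]", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Serialize a dataset to NEXUS
#'
#' Regenerates TAXA, CHARACTERS and TREES blocks; preserved opaque blocks
#' (annotation predicate `ps:nexus_block`) are replayed verbatim.
#'
#' @param ds A `cdao_dataset`.
#' @return NEXUS text.
#' @export
write_nexus <- function(ds) {
  out <- c("#NEXUS", "")
  if (nrow(ds$tus)) {
    out <- c(out, "BEGIN TAXA;",
             paste0("  DIMENSIONS NTAX=", nrow(ds$tus), ";"),
             paste0("  TAXLABELS ",
                    paste(nexus_quote(ds$tus$label), collapse = " "), ";"),
             "END;", "")
  }
  for (m in ds$matrices) {
    dt <- switch(m$datatype, DNA = "DNA", RNA = "RNA", protein = "PROTEIN",
                 continuous = "CONTINUOUS", "STANDARD")
    rows <- vapply(seq_len(nrow(m$tus)), function(i) {
      cc <- m$cells[m$cells$tu_ref == m$tus$id[i], , drop = FALSE]
      st <- cc$state[match(m$characters$id, cc$character_ref)]
      st[is.na(st)] <- "?"
      paste0("    ", nexus_quote(m$tus$label[i]), " ",
             paste(st, collapse = ""))
    }, "")
    out <- c(out, "BEGIN CHARACTERS;",
             paste0("  DIMENSIONS NTAX=", nrow(m$tus),
                    " NCHAR=", nrow(m$characters), ";"),
             paste0("  FORMAT DATATYPE=", dt, " MISSING=? GAP=-;"),
             "  MATRIX", rows, "  ;", "END;", "")
  }
  if (length(ds$trees)) {
    out <- c(out, "BEGIN TREES;",
             vapply(ds$trees, function(t)
               paste0("  TREE ", nexus_quote(t$id), " = ",
                      write_newick(t)), ""),
             "END;", "")
  }
  blocks <- ds$annotations[ds$annotations$predicate == "ps:nexus_block", ]
  if (nrow(blocks)) out <- c(out, paste0(blocks$value, ";"), "")
  paste(out, collapse = "\n")
}
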