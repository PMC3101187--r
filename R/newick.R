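# Newick reading and writing.
#
# The reader is a recursive-descent parser over an explicit token stream so
# that malformed input (unbalanced parentheses, trailing garbage, empty
# strings) is rejected with a precise message and quoted labels ('...', with
# '' as the escaped quote) survive round trips; unlabeled internal nodes get
# synthesized "#node<k>" labels in parse order.

newick_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- list(); i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", ",", ":", ";")) {
      toks[[length(toks) + 1L]] <- list(type = ch)
      i <- i + 1L
    } else if (ch == "'") {
      lab <- character(0); i <- i + 1L
      repeat {
        if (i > n) stop("newick: unterminated quoted label")
        if (chars[i] == "'") {
          if (i < n && chars[i + 1L] == "'") { lab <- c(lab, "'"); i <- i + 2L }
          else { i <- i + 1L; break }
        } else { lab <- c(lab, chars[i]); i <- i + 1L }
      }
      toks[[length(toks) + 1L]] <- list(type = "label",
                                        value = paste(lab, collapse = ""))
    } else {
      j <- i
      while (j <= n && !chars[j] %in% c("(", ")", ",", ":", ";", "'") &&
             !grepl("^\\s$", chars[j])) j <- j + 1L
      toks[[length(toks) + 1L]] <-
        list(type = "label", value = paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  toks
}

#' Parse a Newick tree string
#'
#' Reads one `;`-terminated Newick tree into a rooted tree object.  Branch
#' lengths (`:0.5`) and quoted labels (`'Ilex anomala'`) are supported;
#' unlabeled internal nodes receive labels `#node1`, `#node2`, ... in parse
#' order.
#'
#' @param text Newick string, e.g. `"((A:1,B:2):0.5,C:1);"`.
#' @param id Tree identifier for the result.
#' @return A `cdao_tree` (see [build_tree()]).
#' @examples
#' parse_newick("((A,B),C);")
#' @export
parse_newick <- function(text, id = "t1") {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) stop("newick: empty string")
  toks <- newick_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else "eof"
  take <- function(type) {
    if (peek() != type)
      stop("newick: expected '", type, "' but found '", peek(), "'")
    tok <- toks[[pos]]; pos <<- pos + 1L; tok
  }
  edges <- list()
  auto_k <- 0L
  used <- new.env(parent = emptyenv())
  uniq <- function(lab) {      # duplicate labels get positional suffixes
    key <- paste0("k", lab)
    cnt <- if (is.null(used[[key]])) 0L else used[[key]]
    used[[key]] <- cnt + 1L
    if (cnt == 0L) lab else paste0(lab, "#", cnt + 1L)
  }
  parse_clade <- function() {
    if (peek() == "(") {
      take("(")
      kids <- list(parse_clade())
      while (peek() == ",") { take(","); kids[[length(kids) + 1L]] <- parse_clade() }
      take(")")
      lab <- if (peek() == "label") take("label")$value else {
        auto_k <<- auto_k + 1L
        paste0("#node", auto_k)
      }
      lab <- uniq(lab)
      for (k in kids)
        edges[[length(edges) + 1L]] <<- list(lab, k$label, k$length)
      len <- NA_real_
      if (peek() == ":") { take(":"); len <- as.numeric(take("label")$value) }
      list(label = lab, length = len)
    } else {
      lab <- uniq(take("label")$value)
      len <- NA_real_
      if (peek() == ":") { take(":"); len <- as.numeric(take("label")$value) }
      list(label = lab, length = len)
    }
  }
  top <- parse_clade()
  take(";")
  if (peek() != "eof") stop("newick: trailing garbage after ';'")
  if (!length(edges)) {   # single-leaf tree "A;"
    nodes <- data.frame(id = "n1", label = top$label, tu_ref = "tu1",
                        stringsAsFactors = FALSE)
    return(structure(list(id = id, nodes = nodes,
                          edges = data.frame(id = character(),
                                             parent = character(),
                                             child = character(),
                                             length = numeric(),
                                             stringsAsFactors = FALSE),
                          rooted = TRUE, root = "n1"),
                     class = "cdao_tree"))
  }
  build_tree(edges, rooted = TRUE, id = id)
}

newick_quote <- function(lab) {
  ifelse(grepl("[][ ():;,']", lab),
         paste0("'", gsub("'", "''", lab), "'"),
         lab)
}

#' Serialize a tree to Newick
#'
#' Children are ordered by the smallest leaf label in their subtree, so the
#' output is a canonical form: two topologically identical trees serialize to
#' the same string and round trips are byte-stable.  Labels containing
#' spaces or Newick metacharacters are single-quoted; absent branch lengths
#' are omitted.  Synthesized `#node<k>` internal labels are not written.
#'
#' @param tree A `cdao_tree`.
#' @param include_internal_labels Write non-synthesized internal labels.
#' @return A single Newick string terminated by `";"`.
#' @export
write_newick <- function(tree, include_internal_labels = TRUE) {
  km <- tree_children_map(tree)
  lab <- stats::setNames(tree$nodes$label, tree$nodes$id)
  len <- stats::setNames(tree$edges$length, tree$edges$child)
  anchor <- setdiff(tree$nodes$id, tree$edges$child)
  min_leaf <- function(v) {
    kids <- km[[v]]
    if (!length(kids)) return(lab[[v]])
    min(vapply(kids, min_leaf, ""))
  }
  fmt_len <- function(v) {
    l <- len[v]
    if (is.na(l)) "" else paste0(":", format(l, digits = 15, scientific = FALSE))
  }
  rec <- function(v) {
    kids <- km[[v]]
    if (!length(kids)) return(paste0(newick_quote(lab[[v]]), fmt_len(v)))
    kids <- kids[order(vapply(kids, min_leaf, ""))]
    inner <- paste(vapply(kids, rec, ""), collapse = ",")
    il <- lab[[v]]
    il <- if (include_internal_labels && !grepl("^#node[0-9]+$", il))
      newick_quote(il) else ""
    paste0("(", inner, ")", il, fmt_len(v))
  }
  paste0(rec(anchor), ";")
}
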