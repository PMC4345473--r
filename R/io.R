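#' @title Versioned JSON serialization for argument graphs
#'
#' @description
#' Arguments are saved as versioned JSON documents (`format:
#' "gsn-argument"`, `version: 1`). The serialization is *canonical*: nodes
#' sorted by uid, edges sorted by (source, target, kind), object keys
#' sorted, 2-space indentation, UTF-8, trailing newline. Equal graphs
#' therefore always produce byte-identical files. Because node and edge
#' records are sorted, each edge carries an `ordinal` field recording the
#' child's insertion position among its siblings of the same edge kind, so
#' the canonical form does not destroy child order.
#'
#' @name gsn-io
NULL

GSN_FORMAT_TAG <- "gsn-argument"
GSN_FORMAT_VERSION <- 1L

#' Serialize an argument graph to canonical JSON
#'
#' @param g A well-formed `gsn_graph`.
#' @param path Optional file path; when given the JSON is also written
#'   there (UTF-8, trailing newline).
#' @param meta Named list/character of document metadata (e.g. `title`,
#'   `authors`, `purpose`); values must be single strings.
#' @return The canonical JSON text, invisibly when `path` is given.
#' @export
gsn_save <- function(g, path = NULL, meta = list()) {
  stopifnot(inherits(g, "gsn_graph"))
  stop_unless_wellformed(g)
  meta <- as.list(meta)
  if (length(meta) && (is.null(names(meta)) || any(!nzchar(names(meta))))) {
    abort_invalid("meta must be a named list of strings")
  }

  # per-parent, per-edge-kind insertion ordinals
  ordinals <- integer(length(g$edges))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    key <- paste0(e$kind, "\r", e$source)
    k <- (if (is.null(seen[[key]])) 0L else seen[[key]]) + 1L
    seen[[key]] <- k
    ordinals[i] <- k
  }

  node_recs <- lapply(g$nodes, function(n) {
    list(collapsed = jsonlite::unbox(n$collapsed),
         kind = jsonlite::unbox(n$kind),
         label = jsonlite::unbox(n$label),
         links = as.character(n$links),
         statement = jsonlite::unbox(n$statement),
         status = jsonlite::unbox(n$status),
         uid = jsonlite::unbox(n$uid))
  })
  node_recs <- node_recs[order(names(g$nodes), method = "radix")]
  names(node_recs) <- NULL

  edge_recs <- lapply(seq_along(g$edges), function(i) {
    e <- g$edges[[i]]
    list(kind = jsonlite::unbox(e$kind),
         ordinal = jsonlite::unbox(ordinals[i]),
         source = jsonlite::unbox(e$source),
         target = jsonlite::unbox(e$target))
  })
  if (length(edge_recs)) {
    key <- vapply(g$edges, function(e)
      paste(e$source, e$target, e$kind, sep = "\r"), character(1))
    edge_recs <- edge_recs[order(key, method = "radix")]
  }

  meta_sorted <- lapply(meta, function(v) jsonlite::unbox(as.character(v)))
  if (length(meta_sorted)) {
    meta_sorted <- meta_sorted[order(names(meta_sorted), method = "radix")]
  } else {
    meta_sorted <- stats::setNames(list(), character())
  }

  doc <- list(
    edges = edge_recs,
    format = jsonlite::unbox(GSN_FORMAT_TAG),
    meta = meta_sorted,
    nodes = node_recs,
    root = jsonlite::unbox(g$root),
    version = jsonlite::unbox(GSN_FORMAT_VERSION)
  )
  txt <- paste0(jsonlite::toJSON(doc, pretty = 2, digits = NA), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(txt)), con)
    return(invisible(txt))
  }
  txt
}

#' Load an argument graph from JSON
#'
#' Hard structural failures raise a `gsn_format_error`: a wrong format tag
#' or version, an unknown node/edge kind, a duplicated uid, or an edge
#' naming a missing uid. Everything else -- including soft rule violations
#' -- is reported via the returned issue list, so a successfully loaded
#' graph is always structurally usable.
#'
#' @param x Path to a JSON file, or the JSON text itself.
#' @return A list with elements `graph` (a `gsn_graph`) and `issues` (the
#'   [gsn_validate()] report).
#' @export
gsn_load <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{\n]", x)) {
    if (!file.exists(x)) abort_not_found(sprintf("file '%s' does not exist", x))
    readChar(x, file.info(x)$size, useBytes = TRUE)
  } else {
    paste(x, collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    abort_format(paste0("not valid JSON: ",
                                        conditionMessage(e))))
  if (!identical(doc$format, GSN_FORMAT_TAG)) {
    abort_format("missing or wrong format tag; expected \"gsn-argument\"")
  }
  if (!identical(as.integer(doc$version %||% -1L), GSN_FORMAT_VERSION)) {
    abort_format(sprintf("unsupported format version: %s",
                         doc$version %||% "<missing>"))
  }
  if (is.null(doc$nodes) || length(doc$nodes) == 0) {
    abort_format("document contains no nodes")
  }

  uids <- vapply(doc$nodes, function(n) as.character(n$uid %||% ""),
                 character(1))
  if (any(!nzchar(uids))) abort_format("a node record is missing its uid")
  dup <- unique(uids[duplicated(uids)])
  if (length(dup)) {
    abort_format(sprintf("DUPLICATE_UID: duplicated uid(s): %s",
                         paste(dup, collapse = ", ")))
  }

  nodes <- list()
  for (rec in doc$nodes) {
    kind <- as.character(rec$kind %||% "")
    if (!kind %in% GSN_NODE_KINDS) {
      abort_format(sprintf("unknown node kind '%s' (uid '%s')", kind,
                           rec$uid))
    }
    status <- as.character(rec$status %||% "developed")
    if (!status %in% c("developed", "undeveloped")) {
      abort_format(sprintf("unknown status '%s' (uid '%s')", status, rec$uid))
    }
    nodes[[as.character(rec$uid)]] <- new_gsn_node(
      uid = as.character(rec$uid), kind = kind,
      statement = as.character(rec$statement %||% ""),
      links = vapply(rec$links %||% list(), as.character, character(1)),
      status = status,
      collapsed = isTRUE(rec$collapsed),
      label = as.character(rec$label %||% "")
    )
  }

  edges <- list()
  for (rec in doc$edges %||% list()) {
    kind <- as.character(rec$kind %||% "")
    if (!kind %in% GSN_EDGE_KINDS) {
      abort_format(sprintf("unknown edge kind '%s'", kind))
    }
    src <- as.character(rec$source %||% "")
    tgt <- as.character(rec$target %||% "")
    if (!src %in% uids || !tgt %in% uids) {
      abort_format(sprintf("DANGLING_EDGE: edge %s -> %s references a missing uid",
                           src, tgt))
    }
    edges[[length(edges) + 1L]] <-
      list(source = src, target = tgt, kind = kind,
           ordinal = as.integer(rec$ordinal %||% length(edges) + 1L))
  }

  # restore insertion order: sort per (source, kind) by ordinal; the global
  # sequence groups parents in uid order, which is immaterial -- only the
  # per-parent child order has semantics
  if (length(edges)) {
    key <- vapply(edges, function(e)
      sprintf("%s\r%s\r%09d", e$source, e$kind, e$ordinal), character(1))
    edges <- edges[order(key, method = "radix")]
    edges <- lapply(edges, function(e) e[c("source", "target", "kind")])
  }

  root <- as.character(doc$root %||% "")
  if (!root %in% uids) {
    abort_format(sprintf("declared root '%s' is not among the nodes", root))
  }

  counter <- suppressWarnings(
    max(1L, as.integer(sub("^n", "", grep("^n[0-9]+$", uids, value = TRUE))))
  )
  g <- structure(
    list(nodes = nodes, edges = edges, root = root, counter = counter),
    class = "gsn_graph"
  )
  list(graph = g, issues = gsn_validate(g))
}

dot_quote <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

#' Export an argument graph as Graphviz DOT text
#'
#' Node shapes follow the notation: goal = box, strategy = parallelogram,
#' context = rounded box, assumption/justification = ellipse (with an
#' `[A]`/`[J]` tag appended to the text), evidence = circle. `supported_by`
#' edges carry a filled (`normal`) arrowhead, `in_context_of` edges an
#' open (`empty`) arrowhead. The output is deterministic: nodes are sorted
#' by uid, edges by (source, target, kind).
#'
#' @param g A well-formed `gsn_graph`.
#' @return DOT text (single string).
#' @export
gsn_export_dot <- function(g) {
  stop_unless_wellformed(g)
  shape_attr <- function(n) {
    switch(n$kind,
      goal = "shape=box",
      strategy = "shape=parallelogram",
      context = "shape=box, style=rounded",
      assumption = "shape=ellipse",
      justification = "shape=ellipse",
      evidence = "shape=circle")
  }
  lines <- c("digraph argument {", "  rankdir=TB;",
             "  node [fontname=\"Helvetica\"];")
  for (uid in sort(names(g$nodes), method = "radix")) {
    n <- g$nodes[[uid]]
    text <- n$statement
    if (n$kind == "assumption") text <- paste0(text, " [A]")
    if (n$kind == "justification") text <- paste0(text, " [J]")
    if (nzchar(n$label)) text <- paste0(n$label, "\\n", text)
    lines <- c(lines, sprintf("  %s [label=%s, %s];",
                              dot_quote(uid), dot_quote(text), shape_attr(n)))
  }
  ekey <- vapply(g$edges, function(e)
    paste(e$source, e$target, e$kind, sep = "\r"), character(1))
  for (e in g$edges[order(ekey, method = "radix")]) {
    arrow <- if (e$kind == "supported_by") "normal" else "empty"
    lines <- c(lines, sprintf("  %s -> %s [arrowhead=%s];",
                              dot_quote(e$source), dot_quote(e$target), arrow))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}
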