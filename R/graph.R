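#' @title Typed argument graphs in goal structuring notation
#'
#' @description
#' An argument graph is a rooted tree of typed nodes expressing a
#' fitness-for-purpose argument: a top-level *goal* (claim) is decomposed via
#' *strategy* nodes into sub-goals, which are ultimately substantiated by
#' *evidence* nodes, with *context*, *assumption* and *justification* nodes
#' scoping claims and strategies. Two edge kinds connect nodes:
#' `supported_by` (drawn with a solid arrowhead) carries the argumentative
#' decomposition, and `in_context_of` (open arrowhead) attaches the
#' context-family nodes. Goals whose substantiation is not yet possible --
#' typically because the biological data do not exist -- are marked
#' `undeveloped` and drawn with an open diamond.
#'
#' @details
#' Graphs are ordinary R lists of class `gsn_graph` with fields `nodes`
#' (named list, one entry per uid), `edges` (list of
#' `list(source, target, kind)` in insertion order) and `root` (the uid of
#' the top-level goal). Child order is insertion order and is preserved by
#' labelling, serialization and layout. All mutators return the updated
#' graph; [gsn_add_child()] additionally records the uid of the node it
#' created, retrievable with [gsn_last_uid()].
#'
#' @name gsn_graph-class
NULL

GSN_NODE_KINDS <- c("goal", "strategy", "context", "assumption",
                    "justification", "evidence")
GSN_EDGE_KINDS <- c("supported_by", "in_context_of")
GSN_CONTEXT_FAMILY <- c("context", "assumption", "justification")

new_gsn_node <- function(uid, kind, statement, links = character(),
                         status = "developed", collapsed = FALSE,
                         label = "") {
  list(uid = uid, kind = kind, statement = statement,
       links = as.character(links), status = status,
       collapsed = isTRUE(collapsed), label = label)
}

#' Create a new argument graph with a single top-level claim
#'
#' The first step in constructing an argument is to state the top-level
#' claim the argument seeks to establish. The returned graph holds one
#' developed goal node, which is the root.
#'
#' @param root_statement Non-empty text of the top-level claim.
#' @param uid Optional uid for the root node; autogenerated when `NULL`.
#' @return A `gsn_graph` with a single goal node.
#' @examples
#' g <- gsn_graph("the simulation is an adequate representation of the biology")
#' gsn_metrics(g)$n_goal
#' @export
gsn_graph <- function(root_statement, uid = NULL) {
  if (!is.character(root_statement) || length(root_statement) != 1 ||
      is.na(root_statement) || !nzchar(trimws(root_statement))) {
    abort_invalid("root_statement must be a single non-empty string")
  }
  uid <- uid %||% "n1"
  g <- structure(
    list(nodes = list(), edges = list(), root = uid, counter = 1L),
    class = "gsn_graph"
  )
  g$nodes[[uid]] <- new_gsn_node(uid, "goal", root_statement)
  g
}

next_uid <- function(g) {
  repeat {
    g$counter <- g$counter + 1L
    uid <- paste0("n", g$counter)
    if (is.null(g$nodes[[uid]])) {
      return(list(graph = g, uid = uid))
    }
  }
}

node_kind <- function(g, uid) g$nodes[[uid]]$kind

# child uids of `uid`, in edge-insertion order, optionally filtered by
# edge kind
children_of <- function(g, uid, kind = NULL) {
  out <- character()
  for (e in g$edges) {
    if (identical(e$source, uid) && (is.null(kind) || e$kind == kind)) {
      out <- c(out, e$target)
    }
  }
  out
}

parent_of <- function(g, uid) {
  for (e in g$edges) if (identical(e$target, uid)) return(e$source)
  NULL
}

# Legality of a (parent kind, child kind) pairing under the notation rules.
# Returns the inferred edge kind, or NULL when the pairing is illegal.
infer_edge_kind <- function(parent_kind, child_kind) {
  if (child_kind %in% GSN_CONTEXT_FAMILY) {
    if (parent_kind %in% c("goal", "strategy")) return("in_context_of")
    return(NULL)
  }
  if (!parent_kind %in% c("goal", "strategy")) return(NULL)
  if (parent_kind == "strategy" && child_kind == "strategy") return(NULL)
  if (!child_kind %in% c("goal", "strategy", "evidence")) return(NULL)
  "supported_by"
}

#' Add a child node to an argument graph
#'
#' Creates a node of the requested kind under `parent` and infers the edge
#' kind from the child kind: `in_context_of` for context, assumption and
#' justification nodes, `supported_by` otherwise. Children keep their
#' insertion order, which drives labelling and layout.
#'
#' Legal pairings: goals and strategies may carry context-family
#' attachments; goals decompose into strategies, sub-goals or evidence;
#' strategies decompose into goals (and, flagged with a validation warning,
#' directly into evidence). Evidence nodes are leaves and accept no
#' children.
#'
#' @param g A `gsn_graph`.
#' @param parent uid of the parent node.
#' @param kind One of `"goal"`, `"strategy"`, `"context"`, `"assumption"`,
#'   `"justification"`, `"evidence"`.
#' @param statement Free statement text for the new node.
#' @param links Character vector of URIs pointing at supporting material
#'   (publications, analyses); mainly used on evidence nodes.
#' @param uid Optional explicit uid; autogenerated (`"n<k>"`) when `NULL`.
#' @return The updated graph. The new node's uid is available via
#'   [gsn_last_uid()].
#' @examples
#' g <- gsn_graph("top-level claim")
#' g <- gsn_add_child(g, gsn_root(g), "strategy", "argue over sub-systems")
#' s <- gsn_last_uid(g)
#' g <- gsn_add_child(g, s, "goal", "sub-system A is adequately represented")
#' @export
gsn_add_child <- function(g, parent, kind, statement, links = character(),
                          uid = NULL) {
  stopifnot(inherits(g, "gsn_graph"))
  kind <- match.arg(kind, GSN_NODE_KINDS)
  if (is.null(g$nodes[[parent]])) {
    abort_not_found(sprintf("parent node '%s' does not exist", parent))
  }
  if (!is.character(statement) || length(statement) != 1 || is.na(statement) ||
      !nzchar(trimws(statement))) {
    abort_invalid("statement must be a single non-empty string")
  }
  edge_kind <- infer_edge_kind(node_kind(g, parent), kind)
  if (is.null(edge_kind)) {
    abort_typing(sprintf("a %s node cannot have a %s child",
                         node_kind(g, parent), kind))
  }
  if (is.null(uid)) {
    gen <- next_uid(g)
    g <- gen$graph
    uid <- gen$uid
  } else if (!is.null(g$nodes[[uid]])) {
    abort_invalid(sprintf("uid '%s' already exists", uid))
  }
  g$nodes[[uid]] <- new_gsn_node(uid, kind, statement, links)
  g$edges[[length(g$edges) + 1L]] <-
    list(source = parent, target = uid, kind = edge_kind)
  attr(g, "last_uid") <- uid
  g
}

#' uid of the most recently added node
#' @param g A `gsn_graph`.
#' @return The uid recorded by the last [gsn_add_child()] call, or `NULL`.
#' @export
gsn_last_uid <- function(g) attr(g, "last_uid")

#' uid of the root goal
#' @param g A `gsn_graph`.
#' @return The root uid.
#' @export
gsn_root <- function(g) g$root

#' Mark a goal as developed or undeveloped
#'
#' An *undeveloped* goal records a recognized gap: a claim that cannot
#' currently be substantiated, typically for lack of quantitative
#' biological data. It is drawn with an open diamond. Only goals without
#' `supported_by` children may be marked undeveloped; every other node is
#' permanently `developed`.
#'
#' @param g A `gsn_graph`.
#' @param uid uid of a goal node.
#' @param status `"developed"` or `"undeveloped"`.
#' @return The updated graph.
#' @export
gsn_set_status <- function(g, uid, status) {
  stopifnot(inherits(g, "gsn_graph"))
  status <- match.arg(status, c("developed", "undeveloped"))
  if (is.null(g$nodes[[uid]])) {
    abort_not_found(sprintf("node '%s' does not exist", uid))
  }
  if (status == "undeveloped") {
    if (node_kind(g, uid) != "goal") {
      abort_typing("only goal nodes can be marked undeveloped")
    }
    if (length(children_of(g, uid, "supported_by")) > 0) {
      abort_typing("a goal with supporting children cannot be undeveloped")
    }
  }
  g$nodes[[uid]]$status <- status
  g
}

#' Collapse or expand a subtree for rendering
#'
#' A collapsed node hides its descendants in diagrams and is drawn with a
#' filled diamond; the graph structure itself is unchanged. Only nodes with
#' at least one `supported_by` child can be collapsed.
#'
#' @param g A `gsn_graph`.
#' @param uid uid of the node to collapse or expand.
#' @param collapsed `TRUE` to collapse, `FALSE` to expand.
#' @return The updated graph.
#' @export
gsn_collapse <- function(g, uid, collapsed = TRUE) {
  stopifnot(inherits(g, "gsn_graph"), is.logical(collapsed),
            length(collapsed) == 1)
  if (is.null(g$nodes[[uid]])) {
    abort_not_found(sprintf("node '%s' does not exist", uid))
  }
  if (length(children_of(g, uid, "supported_by")) == 0) {
    abort_invalid("only nodes with supporting children can be collapsed")
  }
  g$nodes[[uid]]$collapsed <- isTRUE(collapsed)
  g
}

issue_row <- function(code, severity, uids, message) {
  data.frame(code = code, severity = severity,
             uids = paste(uids, collapse = ","),
             message = message, stringsAsFactors = FALSE)
}

#' Validate the well-formedness of an argument graph
#'
#' Checks the notation rules and returns all violations; nothing is raised.
#' A graph is well-formed when no issue of severity `"error"` is reported.
#' Graphs built exclusively through the construction API
#' ([gsn_graph()], [gsn_add_child()], [gsn_set_status()], [gsn_collapse()])
#' always validate cleanly; the checks exist for documents decoded from
#' files or assembled by other means.
#'
#' Rule codes: `NO_ROOT`, `MULTIPLE_ROOTS`, `ROOT_NOT_GOAL` (exactly one
#' parentless node, a goal), `CYCLE`, `UNREACHABLE`, `BAD_EDGE_TYPING`
#' (edge endpoints must respect the notation's kind rules; a strategy
#' supported directly by evidence is tolerated but flagged as a warning),
#' `EVIDENCE_NOT_LEAF`, `UNDEVELOPED_NOT_GOAL`, `UNDEVELOPED_WITH_CHILDREN`,
#' `DANGLING_EDGE`, `DUPLICATE_UID`.
#'
#' @param g A `gsn_graph` (possibly malformed).
#' @return A data frame of class `gsn_issues` with columns `code`,
#'   `severity`, `uids` (comma-separated) and `message`; zero rows when the
#'   graph is fully clean.
#' @export
gsn_validate <- function(g) {
  stopifnot(inherits(g, "gsn_graph"))
  issues <- list()
  push <- function(x) issues[[length(issues) + 1L]] <<- x

  uids <- names(g$nodes)
  kinds <- vapply(g$nodes, function(n) n$kind, character(1))
  names(kinds) <- uids

  dup <- unique(uids[duplicated(uids)])
  if (length(dup)) {
    push(issue_row("DUPLICATE_UID", "error", dup,
                   sprintf("duplicated uid(s): %s",
                           paste(dup, collapse = ", "))))
  }

  # split edges into dangling (an endpoint not in the node set) and clean;
  # dangling edges are excluded from the structural checks below
  clean <- list()
  for (e in g$edges) {
    if (!(e$source %in% uids) || !(e$target %in% uids)) {
      push(issue_row("DANGLING_EDGE", "error",
                     c(e$source, e$target),
                     sprintf("edge %s -> %s references a missing uid",
                             e$source, e$target)))
    } else {
      clean[[length(clean) + 1L]] <- e
    }
  }

  u_uids <- unique(uids)
  targets <- vapply(clean, function(e) e$target, character(1))
  sources <- vapply(clean, function(e) e$source, character(1))
  parentless <- setdiff(u_uids, targets)

  if (length(u_uids) > 0) {
    if (length(parentless) == 0) {
      push(issue_row("NO_ROOT", "error", character(),
                     "every node has a parent; no root exists"))
    } else if (length(parentless) > 1) {
      push(issue_row("MULTIPLE_ROOTS", "error", parentless,
                     sprintf("%d parentless nodes found",
                             length(parentless))))
    } else if (kinds[[parentless]] != "goal") {
      push(issue_row("ROOT_NOT_GOAL", "error", parentless,
                     sprintf("root node '%s' is a %s, not a goal",
                             parentless, kinds[[parentless]])))
    }
  }

  # multiple parents break the tree structure
  multi <- unique(targets[duplicated(targets)])
  for (uid in multi) {
    push(issue_row("BAD_EDGE_TYPING", "error", uid,
                   sprintf("node '%s' has more than one parent", uid)))
  }

  # cycle detection: iteratively strip nodes without incoming clean edges;
  # whatever survives lies on or below a cycle
  if (length(clean)) {
    alive <- u_uids
    esrc <- sources
    etgt <- targets
    repeat {
      rootsish <- setdiff(alive, etgt)
      if (length(rootsish) == 0) break
      keep <- !(esrc %in% rootsish)
      esrc <- esrc[keep]
      etgt <- etgt[keep]
      alive <- setdiff(alive, rootsish)
    }
    if (length(alive)) {
      cyc <- sort(intersect(alive, unique(etgt)))
      push(issue_row("CYCLE", "error", cyc,
                     sprintf("cycle detected involving: %s",
                             paste(cyc, collapse = ", "))))
    }
  }

  # reachability from the parentless node(s); meaningless when none exist
  if (length(parentless) >= 1) {
    seen <- parentless
    frontier <- parentless
    while (length(frontier)) {
      nxt <- setdiff(targets[sources %in% frontier], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    unreach <- sort(setdiff(u_uids, seen))
    if (length(unreach)) {
      push(issue_row("UNREACHABLE", "error", unreach,
                     sprintf("node(s) not reachable from the root: %s",
                             paste(unreach, collapse = ", "))))
    }
  }

  for (e in clean) {
    ks <- kinds[[e$source]]
    kt <- kinds[[e$target]]
    if (ks == "evidence") {
      push(issue_row("EVIDENCE_NOT_LEAF", "error", c(e$source, e$target),
                     sprintf("evidence node '%s' has an outgoing edge",
                             e$source)))
      next
    }
    if (e$kind == "supported_by") {
      if (!ks %in% c("goal", "strategy")) {
        push(issue_row("BAD_EDGE_TYPING", "error", c(e$source, e$target),
                       sprintf("supported_by edge from a %s node", ks)))
      } else if (!kt %in% c("goal", "strategy", "evidence")) {
        push(issue_row("BAD_EDGE_TYPING", "error", c(e$source, e$target),
                       sprintf("supported_by edge into a %s node", kt)))
      } else if (ks == "strategy" && kt == "strategy") {
        push(issue_row("BAD_EDGE_TYPING", "error", c(e$source, e$target),
                       "a strategy cannot be supported by a strategy"))
      } else if (ks == "strategy" && kt == "evidence") {
        push(issue_row("BAD_EDGE_TYPING", "warning", c(e$source, e$target),
                       "evidence directly under a strategy; prefer an intermediate goal"))
      }
    } else if (e$kind == "in_context_of") {
      if (!ks %in% c("goal", "strategy")) {
        push(issue_row("BAD_EDGE_TYPING", "error", c(e$source, e$target),
                       sprintf("in_context_of edge from a %s node", ks)))
      }
      if (!kt %in% GSN_CONTEXT_FAMILY) {
        push(issue_row("BAD_EDGE_TYPING", "error", c(e$source, e$target),
                       sprintf("in_context_of edge into a %s node", kt)))
      }
    } else {
      push(issue_row("BAD_EDGE_TYPING", "error", c(e$source, e$target),
                     sprintf("unknown edge kind '%s'", e$kind)))
    }
  }

  for (uid in u_uids) {
    n <- g$nodes[[uid]]
    if (identical(n$status, "undeveloped")) {
      if (n$kind != "goal") {
        push(issue_row("UNDEVELOPED_NOT_GOAL", "error", uid,
                       sprintf("%s node '%s' marked undeveloped", n$kind, uid)))
      } else if (uid %in% sources[vapply(clean, function(e) e$kind,
                                         character(1)) == "supported_by"]) {
        push(issue_row("UNDEVELOPED_WITH_CHILDREN", "error", uid,
                       sprintf("undeveloped goal '%s' has supporting children",
                               uid)))
      }
    }
  }

  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(), severity = character(),
               uids = character(), message = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("gsn_issues", "data.frame")
  out
}

#' Is a graph well-formed?
#'
#' @param g A `gsn_graph`.
#' @return `TRUE` when [gsn_validate()] reports no error-severity issue.
#' @export
gsn_is_wellformed <- function(g) {
  iss <- gsn_validate(g)
  !any(iss$severity == "error")
}

stop_unless_wellformed <- function(g) {
  iss <- gsn_validate(g)
  if (any(iss$severity == "error")) abort_validation(iss)
  invisible(iss)
}

#' Assign hierarchical dotted labels to all nodes
#'
#' The root goal is labelled `"1"`; the k-th `supported_by` child (in
#' insertion order) of a node labelled `L` gets `"L.k"`, so a strategy
#' under goal `1.1.3` becomes `1.1.3.1`. Context-family attachments get a
#' per-parent suffix label: `L-C1`, `L-A1`, `L-J1` for context, assumption
#' and justification respectively. Labels are written onto the nodes;
#' re-running is idempotent.
#'
#' @param g A well-formed `gsn_graph`.
#' @return The graph with every node's `label` field set.
#' @export
gsn_assign_labels <- function(g) {
  stopifnot(inherits(g, "gsn_graph"))
  stop_unless_wellformed(g)
  assign_rec <- function(g, uid, label) {
    g$nodes[[uid]]$label <- label
    sup <- children_of(g, uid, "supported_by")
    for (k in seq_along(sup)) {
      g <- assign_rec(g, sup[k], paste0(label, ".", k))
    }
    ctx <- children_of(g, uid, "in_context_of")
    counters <- c(context = 0L, assumption = 0L, justification = 0L)
    tag <- c(context = "C", assumption = "A", justification = "J")
    for (cu in ctx) {
      kind <- node_kind(g, cu)
      counters[kind] <- counters[kind] + 1L
      g$nodes[[cu]]$label <- paste0(label, "-", tag[kind], counters[kind])
    }
    g
  }
  assign_rec(g, g$root, "1")
}

#' Mapping from uid to dotted label
#'
#' @param g A `gsn_graph`, usually after [gsn_assign_labels()].
#' @return Named character vector: names are uids, values labels.
#' @export
gsn_labels <- function(g) {
  vapply(g$nodes, function(n) n$label, character(1))
}

#' Resolve a dotted label to a uid
#'
#' @param g A labelled `gsn_graph`.
#' @param label A dotted label such as `"1.1.3"` or `"1.1-C1"`.
#' @return The uid carrying that label.
#' @export
gsn_find_label <- function(g, label) {
  lab <- gsn_labels(g)
  hit <- names(lab)[lab == label]
  if (length(hit) == 0) {
    abort_not_found(sprintf("no node carries label '%s'", label))
  }
  hit[[1]]
}

# order labels hierarchically: compare dotted integer components
label_order <- function(labels) {
  keys <- lapply(strsplit(labels, "[.-]"), function(parts) {
    suppressWarnings(ifelse(is.na(as.numeric(parts)), 1e6, as.numeric(parts)))
  })
  maxlen <- max(vapply(keys, length, integer(1)), 0L)
  mat <- t(vapply(keys, function(k) c(k, rep(-1, maxlen - length(k))),
                  numeric(maxlen)))
  do.call(order, as.data.frame(mat))
}

#' List undeveloped claims
#'
#' @param g A well-formed `gsn_graph`.
#' @return uids of the goals with status `"undeveloped"`, sorted by dotted
#'   label.
#' @export
gsn_undeveloped <- function(g) {
  stop_unless_wellformed(g)
  g <- gsn_assign_labels(g)
  und <- Filter(function(n) n$kind == "goal" && n$status == "undeveloped",
                g$nodes)
  if (length(und) == 0) return(character())
  uids <- vapply(und, function(n) n$uid, character(1))
  labs <- vapply(und, function(n) n$label, character(1))
  unname(uids[label_order(labs)])
}

#' Argument completeness metrics
#'
#' Summarizes an argument for review: node counts per kind, the depth of
#' the support tree, how many goals are *terminal* (no goal or strategy
#' among their supporting children -- the places where the argument must
#' bottom out in evidence), how many of those are substantiated by at
#' least one evidence node, and the resulting evidence coverage.
#'
#' @param g A well-formed `gsn_graph`.
#' @return A list of class `gsn_metrics`: `n_goal`, `n_strategy`,
#'   `n_context`, `n_assumption`, `n_justification`, `n_evidence`,
#'   `max_depth` (root = 1), `n_undeveloped`, `n_terminal_goals`,
#'   `n_substantiated_terminal_goals`, `coverage` in `[0, 1]` (0 when no
#'   terminal goal exists).
#' @export
gsn_metrics <- function(g) {
  stop_unless_wellformed(g)
  kinds <- vapply(g$nodes, function(n) n$kind, character(1))
  counts <- vapply(GSN_NODE_KINDS, function(k) sum(kinds == k), integer(1))

  depth_rec <- function(uid, d) {
    kids <- children_of(g, uid, "supported_by")
    if (length(kids) == 0) return(d)
    max(vapply(kids, depth_rec, numeric(1), d = d + 1))
  }
  max_depth <- depth_rec(g$root, 1)

  terminal <- substant <- 0L
  for (uid in names(g$nodes)) {
    if (kinds[[uid]] != "goal") next
    kid_kinds <- vapply(children_of(g, uid, "supported_by"),
                        function(u) node_kind(g, u), character(1))
    if (!any(kid_kinds %in% c("goal", "strategy"))) {
      terminal <- terminal + 1L
      if (any(kid_kinds == "evidence")) substant <- substant + 1L
    }
  }
  und <- sum(vapply(g$nodes, function(n)
    n$kind == "goal" && n$status == "undeveloped", logical(1)))

  structure(list(
    n_goal = counts[["goal"]], n_strategy = counts[["strategy"]],
    n_context = counts[["context"]], n_assumption = counts[["assumption"]],
    n_justification = counts[["justification"]],
    n_evidence = counts[["evidence"]],
    max_depth = max_depth, n_undeveloped = und,
    n_terminal_goals = terminal,
    n_substantiated_terminal_goals = substant,
    coverage = if (terminal > 0) substant / terminal else 0
  ), class = "gsn_metrics")
}

#' @export
print.gsn_metrics <- function(x, ...) {
  cat("argument metrics\n")
  cat(sprintf("  nodes: %d goal, %d strategy, %d context, %d assumption, %d justification, %d evidence\n",
              x$n_goal, x$n_strategy, x$n_context, x$n_assumption,
              x$n_justification, x$n_evidence))
  cat(sprintf("  max support depth: %d\n", x$max_depth))
  cat(sprintf("  undeveloped claims: %d\n", x$n_undeveloped))
  cat(sprintf("  terminal goals: %d (substantiated: %d, coverage %.2f)\n",
              x$n_terminal_goals, x$n_substantiated_terminal_goals,
              x$coverage))
  invisible(x)
}

#' @export
print.gsn_graph <- function(x, ...) {
  kinds <- vapply(x$nodes, function(n) n$kind, character(1))
  cat(sprintf("<gsn_graph> %d nodes (%d goals), %d edges\n",
              length(x$nodes), sum(kinds == "goal"), length(x$edges)))
  root <- x$nodes[[x$root]]
  if (!is.null(root)) {
    cat(sprintf("  root: %s%s\n",
                if (nzchar(root$label)) paste0("[", root$label, "] ") else "",
                root$statement))
  }
  invisible(x)
}

#' @export
print.gsn_issues <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("no validation issues\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("%s %s [%s]: %s\n", toupper(x$severity[i]), x$code[i],
                  x$uids[i], x$message[i]))
    }
  }
  invisible(x)
}
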