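# Builders shared across test files.

WORDS <- c("cell", "aggregation", "behaviour", "velocity", "displacement",
           "chemokine", "adhesion", "environment", "simulation", "adequate",
           "representative", "observed", "published", "data", "abstraction")

rand_stmt <- function() paste(sample(WORDS, sample(3:8, 1), replace = TRUE),
                              collapse = " ")

# Random well-formed argument tree built exclusively through the
# construction API; exercises every node kind, undeveloped marks and
# collapsing. Never attaches evidence directly under a strategy, so the
# result validates with zero issues.
random_graph <- function(n_extra = sample(3:14, 1)) {
  g <- gsn_graph(rand_stmt())
  for (i in seq_len(n_extra)) {
    uids <- names(g$nodes)
    repeat {
      parent <- sample(uids, 1)
      pk <- g$nodes[[parent]]$kind
      kind <- if (pk == "goal") {
        sample(c("strategy", "goal", "evidence", "context", "assumption",
                 "justification"), 1,
               prob = c(0.25, 0.2, 0.25, 0.1, 0.1, 0.1))
      } else if (pk == "strategy") {
        sample(c("goal", "context", "assumption", "justification"), 1,
               prob = c(0.7, 0.1, 0.1, 0.1))
      } else {
        NA_character_
      }
      if (!is.na(kind)) break
    }
    g <- gsn_add_child(g, parent, kind, rand_stmt())
  }
  # mark some childless goals undeveloped
  for (uid in names(g$nodes)) {
    n <- g$nodes[[uid]]
    if (n$kind == "goal" && uid != gsn_root(g) &&
        length(gsnarg:::children_of(g, uid, "supported_by")) == 0 &&
        stats::runif(1) < 0.2) {
      g <- gsn_set_status(g, uid, "undeveloped")
    }
  }
  # collapse an occasional internal node
  for (uid in names(g$nodes)) {
    if (length(gsnarg:::children_of(g, uid, "supported_by")) > 0 &&
        stats::runif(1) < 0.1) {
      g <- gsn_collapse(g, uid, TRUE)
    }
  }
  g
}

# Deterministic base graph for single-rule mutation tests:
#   n1 goal (root) -> n2 goal -> n3 strategy -> n4 goal -> n5 evidence
#   n6 context attached to n1
mutation_base <- function() {
  g <- gsn_graph("top-level claim", uid = "n1")
  g <- gsn_add_child(g, "n1", "goal", "sub-claim", uid = "n2")
  g <- gsn_add_child(g, "n2", "strategy", "argue over evidence", uid = "n3")
  g <- gsn_add_child(g, "n3", "goal", "terminal claim", uid = "n4")
  g <- gsn_add_child(g, "n4", "evidence", "statistical result", uid = "n5")
  g <- gsn_add_child(g, "n1", "context", "scope of the claim", uid = "n6")
  g
}

raw_node <- function(uid, kind, status = "developed") {
  list(uid = uid, kind = kind, statement = paste(kind, uid),
       links = character(), status = status, collapsed = FALSE, label = "")
}

raw_edge <- function(source, target, kind = "supported_by") {
  list(source = source, target = target, kind = kind)
}

# Named list of single-rule mutations. Each entry: fun mutating the base
# graph, the violated code, and whether the violation is structurally
# isolable (TRUE -> validate must report exactly that code).
rule_mutations <- function() {
  list(
    ROOT_NOT_GOAL = list(isolated = TRUE, fun = function(g) {
      g$nodes$n1$kind <- "strategy"; g
    }),
    MULTIPLE_ROOTS = list(isolated = TRUE, fun = function(g) {
      g$nodes$n7 <- raw_node("n7", "goal"); g
    }),
    NO_ROOT = list(isolated = FALSE, fun = function(g) {
      g$edges <- c(g$edges, list(raw_edge("n4", "n1"))); g
    }),
    CYCLE = list(isolated = FALSE, fun = function(g) {
      g$nodes$n7 <- raw_node("n7", "goal")
      g$nodes$n8 <- raw_node("n8", "goal")
      g$edges <- c(g$edges, list(raw_edge("n7", "n8"), raw_edge("n8", "n7")))
      g
    }),
    UNREACHABLE = list(isolated = FALSE, fun = function(g) {
      g$nodes$n7 <- raw_node("n7", "goal")
      g$nodes$n8 <- raw_node("n8", "goal")
      g$edges <- c(g$edges, list(raw_edge("n7", "n8"), raw_edge("n8", "n7")))
      g
    }),
    BAD_EDGE_TYPING = list(isolated = TRUE, fun = function(g) {
      for (i in seq_along(g$edges)) {
        if (g$edges[[i]]$target == "n6") g$edges[[i]]$kind <- "supported_by"
      }
      g
    }),
    EVIDENCE_NOT_LEAF = list(isolated = TRUE, fun = function(g) {
      g$nodes$n7 <- raw_node("n7", "goal")
      g$edges <- c(g$edges, list(raw_edge("n5", "n7")))
      g
    }),
    UNDEVELOPED_NOT_GOAL = list(isolated = TRUE, fun = function(g) {
      g$nodes$n3$status <- "undeveloped"; g
    }),
    UNDEVELOPED_WITH_CHILDREN = list(isolated = TRUE, fun = function(g) {
      g$nodes$n2$status <- "undeveloped"; g
    }),
    DANGLING_EDGE = list(isolated = TRUE, fun = function(g) {
      g$edges <- c(g$edges, list(raw_edge("n4", "ghost"))); g
    }),
    DUPLICATE_UID = list(isolated = TRUE, fun = function(g) {
      dup <- raw_node("n6", "context")
      g$nodes <- c(g$nodes, stats::setNames(list(dup), "n6"))
      g
    })
  )
}

# geometry helpers for layout tests
boxes_overlap <- function(b) {
  n <- nrow(b)
  if (n < 2) return(0L)
  ov <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (b$x[i] < b$x[j] + b$width[j] && b$x[j] < b$x[i] + b$width[i] &&
          b$y[i] < b$y[j] + b$height[j] && b$y[j] < b$y[i] + b$height[i]) {
        ov <- ov + 1L
      }
    }
  }
  ov
}

parent_above_violations <- function(g, lay) {
  b <- lay$boxes
  rownames(b) <- b$uid
  bad <- 0L
  for (e in g$edges) {
    if (e$kind != "supported_by") next
    if (!(e$source %in% b$uid) || !(e$target %in% b$uid)) next
    if (b[e$source, "y"] + b[e$source, "height"] > b[e$target, "y"]) {
      bad <- bad + 1L
    }
  }
  bad
}

# tracks with a built-in near/far velocity separation around a centre
separated_tracks <- function(centre = c(0, 0), n_near = 8, n_far = 8,
                             seed = 42) {
  near <- synthesize_tracks(n_near, start_region = c(-30, -30, 30, 30),
                            drift = c(3, 0), step_sd = 0.2, n_steps = 12,
                            seed = seed)
  far <- synthesize_tracks(n_far, start_region = c(120, 120, 200, 200),
                           drift = c(0.3, 0), step_sd = 0.2, n_steps = 12,
                           seed = seed + 1)
  far$track_id <- sub("^t", "f", far$track_id)
  rbind(near, far)
}

brute_force_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
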