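test_that("graph creation yields a single developed goal root", {
  g <- gsn_graph("our model is an adequate representation of the biology")
  expect_s3_class(g, "gsn_graph")
  expect_length(g$nodes, 1)
  root <- g$nodes[[gsn_root(g)]]
  expect_equal(root$kind, "goal")
  expect_equal(root$status, "developed")
  expect_equal(gsn_metrics(g)$max_depth, 1)

  expect_error(gsn_graph(""), class = "gsn_invalid_error")
  expect_error(gsn_graph("   "), class = "gsn_invalid_error")
})

test_that("add_child infers the edge kind from the child kind", {
  g <- gsn_graph("claim")
  root <- gsn_root(g)
  g <- gsn_add_child(g, root, "strategy", "argue over sub-systems")
  expect_equal(g$edges[[1]]$kind, "supported_by")
  g <- gsn_add_child(g, root, "context", "scope")
  expect_equal(g$edges[[2]]$kind, "in_context_of")
  g <- gsn_add_child(g, root, "assumption", "assumed")
  g <- gsn_add_child(g, root, "justification", "justified")
  expect_true(all(vapply(g$edges[3:4], `[[`, "", "kind") == "in_context_of"))

  g <- gsn_add_child(g, root, "evidence", "a result")
  ev <- gsn_last_uid(g)
  expect_error(gsn_add_child(g, ev, "goal", "child of evidence"),
               class = "gsn_typing_error")
  expect_error(gsn_add_child(g, "nope", "goal", "x"),
               class = "gsn_not_found_error")
  expect_error(gsn_add_child(g, root, "goal", ""),
               class = "gsn_invalid_error")
})

test_that("strategies cannot parent strategies or context-family under evidence", {
  g <- gsn_graph("claim")
  g <- gsn_add_child(g, gsn_root(g), "strategy", "s")
  s <- gsn_last_uid(g)
  expect_error(gsn_add_child(g, s, "strategy", "s2"),
               class = "gsn_typing_error")
  g <- gsn_add_child(g, s, "goal", "sub")
  g <- gsn_add_child(g, gsn_last_uid(g), "evidence", "ev")
  expect_error(gsn_add_child(g, gsn_last_uid(g), "context", "ctx"),
               class = "gsn_typing_error")
})

test_that("undeveloped status is restricted to childless goals", {
  g <- gsn_graph("claim")
  g <- gsn_add_child(g, gsn_root(g), "strategy", "s")
  s <- gsn_last_uid(g)
  g <- gsn_add_child(g, s, "goal", "leaf claim")
  leaf <- gsn_last_uid(g)

  g2 <- gsn_set_status(g, leaf, "undeveloped")
  expect_equal(g2$nodes[[leaf]]$status, "undeveloped")
  expect_error(gsn_set_status(g, s, "undeveloped"),
               class = "gsn_typing_error")
  expect_error(gsn_set_status(g, gsn_root(g), "undeveloped"),
               class = "gsn_typing_error")
  # context attachments do not block the undeveloped mark
  g3 <- gsn_add_child(g, leaf, "assumption", "assumed in place of data")
  expect_no_error(gsn_set_status(g3, leaf, "undeveloped"))
})

test_that("collapse is restricted to supported nodes and is an involution", {
  g <- gsn_graph("claim")
  g <- gsn_add_child(g, gsn_root(g), "strategy", "s")
  s <- gsn_last_uid(g)
  g <- gsn_add_child(g, s, "goal", "sub")
  leaf <- gsn_last_uid(g)

  g2 <- gsn_collapse(g, s, TRUE)
  expect_true(g2$nodes[[s]]$collapsed)
  g3 <- gsn_collapse(g2, s, FALSE)
  expect_identical(unclass(g3)[c("nodes", "edges", "root")],
                   unclass(g)[c("nodes", "edges", "root")])
  expect_error(gsn_collapse(g, leaf, TRUE), class = "gsn_invalid_error")
})

test_that("labels follow the hierarchical dotted numbering", {
  g <- gsn_graph("top")
  g <- gsn_add_child(g, gsn_root(g), "strategy", "argue over four areas")
  s <- gsn_last_uid(g)
  for (i in 1:4) g <- gsn_add_child(g, s, "goal", paste("area", i))
  g <- gsn_assign_labels(g)
  labs <- unname(sort(gsn_labels(g)))
  expect_setequal(labs, c("1", "1.1", "1.1.1", "1.1.2", "1.1.3", "1.1.4"))

  # a strategy under the goal labelled 1.1.3 becomes 1.1.3.1
  uid_113 <- gsn_find_label(g, "1.1.3")
  g <- gsn_add_child(g, uid_113, "strategy", "compare against observation")
  g <- gsn_assign_labels(g)
  expect_equal(unname(gsn_labels(g)[gsn_last_uid(g)]), "1.1.3.1")

  # context-family suffix labels, counted per parent and kind
  g <- gsn_add_child(g, uid_113, "context", "ctx one")
  g <- gsn_add_child(g, uid_113, "context", "ctx two")
  g <- gsn_add_child(g, uid_113, "assumption", "an assumption")
  g <- gsn_assign_labels(g)
  kid_labs <- unname(gsn_labels(g)[gsnarg:::children_of(g, uid_113,
                                                        "in_context_of")])
  expect_equal(kid_labs, c("1.1.3-C1", "1.1.3-C2", "1.1.3-A1"))

  expect_equal(unname(gsn_labels(gsn_assign_labels(gsn_graph("solo")))), "1")
})

test_that("labelling is idempotent, unique and prefix-consistent", {
  set.seed(101)
  for (rep in 1:25) {
    g <- gsn_assign_labels(random_graph())
    g2 <- gsn_assign_labels(g)
    expect_identical(gsn_labels(g), gsn_labels(g2))
    labs <- gsn_labels(g)
    expect_false(any(duplicated(labs)))
    for (e in g$edges) {
      if (e$kind == "supported_by") {
        expect_true(startsWith(labs[[e$target]],
                               paste0(labs[[e$source]], ".")))
      }
    }
  }
})

test_that("undeveloped_claims returns childless goals in label order", {
  g <- gsn_graph("solo")
  expect_identical(gsn_undeveloped(g), character())

  g <- gsn_set_status(g, gsn_root(g), "undeveloped")
  expect_identical(gsn_undeveloped(g), gsn_root(g))

  set.seed(77)
  for (rep in 1:10) {
    g <- random_graph()
    und <- gsn_undeveloped(g)
    for (uid in und) {
      expect_equal(g$nodes[[uid]]$kind, "goal")
      expect_length(gsnarg:::children_of(g, uid, "supported_by"), 0)
    }
    g <- gsn_assign_labels(g)
    labs <- gsn_labels(g)[und]
    expect_identical(labs, labs[gsnarg:::label_order(labs)])
  }
})

test_that("metrics count kinds, depth, terminal goals and coverage", {
  g <- gsn_graph("solo")
  m <- gsn_metrics(g)
  expect_equal(m$n_terminal_goals, 1)
  expect_equal(m$n_substantiated_terminal_goals, 0)
  expect_equal(m$coverage, 0)

  g2 <- gsn_add_child(g, gsn_root(g), "evidence", "direct result")
  m2 <- gsn_metrics(g2)
  expect_equal(m2$coverage, 1)
  expect_equal(m2$max_depth, 2)

  set.seed(5)
  for (rep in 1:10) {
    g <- random_graph()
    m <- gsn_metrics(g)
    total <- m$n_goal + m$n_strategy + m$n_context + m$n_assumption +
      m$n_justification + m$n_evidence
    expect_equal(total, length(g$nodes))
    expect_lte(m$n_substantiated_terminal_goals, m$n_terminal_goals)
    expect_gte(m$coverage, 0)
    expect_lte(m$coverage, 1)
  }
})

test_that("coverage never decreases when evidence substantiates a terminal goal", {
  set.seed(9)
  for (rep in 1:10) {
    g <- random_graph()
    m <- gsn_metrics(g)
    goals <- Filter(function(uid) {
      n <- g$nodes[[uid]]
      kk <- vapply(gsnarg:::children_of(g, uid, "supported_by"),
                   function(u) g$nodes[[u]]$kind, character(1))
      n$kind == "goal" && !any(kk %in% c("goal", "strategy")) &&
        n$status == "developed"
    }, names(g$nodes))
    if (length(goals) == 0) next
    g2 <- gsn_add_child(g, goals[[1]], "evidence", "new result")
    expect_gte(gsn_metrics(g2)$coverage, m$coverage)
  }
})

test_that("graphs built through the construction API always validate cleanly", {
  set.seed(31)
  for (rep in 1:50) {
    iss <- gsn_validate(random_graph())
    expect_equal(nrow(iss), 0)
  }
})

test_that("each notation rule is detected when violated in isolation", {
  muts <- rule_mutations()
  for (code in names(muts)) {
    g <- muts[[code]]$fun(mutation_base())
    iss <- gsn_validate(g)
    expect_true(code %in% iss$code, label = paste("reports", code))
    if (muts[[code]]$isolated) {
      expect_identical(unique(iss$code), code,
                       label = paste("isolates", code))
    }
  }
})

test_that("a strategy supported directly by evidence is flagged as a warning", {
  g <- gsn_graph("claim")
  g <- gsn_add_child(g, gsn_root(g), "strategy", "s")
  g <- gsn_add_child(g, gsn_last_uid(g), "evidence", "ev")
  iss <- gsn_validate(g)
  expect_equal(iss$code, "BAD_EDGE_TYPING")
  expect_equal(iss$severity, "warning")
  expect_true(gsn_is_wellformed(g))
})
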