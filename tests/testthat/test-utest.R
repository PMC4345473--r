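test_that("the U statistic counts pairwise wins with ties at one half", {
  expect_equal(mann_whitney_u(c(3, 4, 5), c(1, 2, 6))$u_statistic, 6)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$u_statistic, 0)
  expect_equal(mann_whitney_u(5, 5)$u_statistic, 0.5)
  expect_error(mann_whitney_u(numeric(), 1), class = "gsn_invalid_error")
  expect_error(mann_whitney_u(1, numeric()), class = "gsn_invalid_error")
})

test_that("U matches the brute-force pairwise count on random tied samples", {
  set.seed(61)
  for (rep in 1:200) {
    n1 <- sample(1:8, 1)
    n2 <- sample(1:8, 1)
    x <- sample(0:5, n1, replace = TRUE) + sample(c(0, 0.5), n1, TRUE)
    y <- sample(0:5, n2, replace = TRUE) + sample(c(0, 0.5), n2, TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$u_statistic, brute_force_u(x, y))
    expect_gte(res$u_statistic, 0)
    expect_lte(res$u_statistic, n1 * n2)
    # U1 + U2 = n1 * n2
    expect_equal(res$u_statistic + mann_whitney_u(y, x)$u_statistic, n1 * n2)
    expect_gte(res$p_two_sided, 0)
    expect_lte(res$p_two_sided, 1)
  }
})

test_that("exact p for complete separation at n1 = n2 = 3 is 2/20", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$method, "exact")
  expect_equal(res$p_two_sided, 0.1)
  # independent check: count extreme assignments over all choose(6, 3)
  pooled <- c(1, 2, 3, 4, 5, 6)
  combs <- utils::combn(6, 3)
  us <- apply(combs, 2, function(idx)
    brute_force_u(pooled[idx], pooled[-idx]))
  expect_equal(mean(abs(us - 4.5) >= abs(0 - 4.5)), 0.1)
})

test_that("exact p agrees with wilcox.test when there are no ties", {
  set.seed(71)
  for (rep in 1:50) {
    n1 <- sample(2:7, 1)
    n2 <- sample(2:7, 1)
    vals <- sample(1:100, n1 + n2)           # distinct -> no ties
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    res <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(res$u_statistic, unname(ref$statistic))
    expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(81)
  x <- sample(0:9, 30, replace = TRUE)
  y <- sample(2:11, 25, replace = TRUE)
  res <- mann_whitney_u(x, y)
  expect_equal(res$method, "normal_approximation")
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(res$u_statistic, unname(ref$statistic))
  expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-10)

  # degenerate: everything tied
  expect_equal(mann_whitney_u(rep(1, 20), rep(1, 20))$p_two_sided, 1)
})

test_that("U is invariant under strictly monotone transforms", {
  set.seed(91)
  for (rep in 1:25) {
    x <- stats::rnorm(6)
    y <- stats::rnorm(7)
    u0 <- mann_whitney_u(x, y)$u_statistic
    expect_equal(mann_whitney_u(exp(x), exp(y))$u_statistic, u0)
    expect_equal(mann_whitney_u(x^3, y^3)$u_statistic, u0)
  }
})

test_that("compare_groups splits tracks and compares the chosen response", {
  tracks <- separated_tracks()
  res <- compare_groups(tracks, centre = c(0, 0), threshold_um = 50,
                        response = "velocity")
  # constructed complete separation: every near track faster than every far
  expect_equal(res$u_statistic, res$n1 * res$n2)
  expect_lt(res$p_two_sided, 0.05)
  expect_equal(res$n1, 8)

  # relabelling track ids changes nothing
  relabelled <- tracks
  relabelled$track_id <- paste0("z_", relabelled$track_id)
  res2 <- compare_groups(relabelled, centre = c(0, 0), threshold_um = 50,
                         response = "velocity")
  expect_equal(res2$u_statistic, res$u_statistic)
  expect_equal(res2$p_two_sided, res$p_two_sided)

  # an empty side is an error naming that side
  near_only <- synthesize_tracks(4, start_region = c(-5, -5, 5, 5),
                                 step_sd = 1, n_steps = 5, seed = 3)
  expect_error(compare_groups(near_only, centre = c(0, 0)), "far",
               class = "gsn_invalid_error")
  far_only <- synthesize_tracks(4, start_region = c(500, 500, 600, 600),
                                step_sd = 1, n_steps = 5, seed = 3)
  expect_error(compare_groups(far_only, centre = c(0, 0)), "near",
               class = "gsn_invalid_error")
})

test_that("identical near and far samples give p = 1 under the exact method", {
  # two tracks with identical geometry on each side of the threshold
  mk <- function(id, x0) data.frame(track_id = id, t_min = 0:4,
                                    x_um = x0 + c(0, 1, 3, 4, 6), y_um = 0)
  tracks <- rbind(mk("a", 0), mk("b", 10), mk("c", 100), mk("d", 110))
  res <- compare_groups(tracks, centre = c(0, 0), threshold_um = 50,
                        response = "velocity")
  expect_equal(res$method, "exact")
  expect_equal(res$p_two_sided, 1)
})

test_that("attach_evidence composes the statement and verdict", {
  g <- gsn_graph("behaviour is representative")
  res <- structure(list(u_statistic = 12, n1 = 6, n2 = 5,
                        p_two_sided = 0.4, method = "exact"),
                   class = "mwu_test")
  g2 <- attach_evidence(g, gsn_root(g), res, "velocity near vs far",
                        link = "https://example.org/analysis")
  ev <- g2$nodes[[gsn_last_uid(g2)]]
  expect_equal(ev$kind, "evidence")
  expect_match(ev$statement, "no significant difference at alpha = 0.05")
  expect_match(ev$statement, "U = 12")
  expect_equal(ev$links, "https://example.org/analysis")
  expect_equal(nrow(gsn_validate(g2)), 0)

  res$p_two_sided <- 0.01
  g3 <- attach_evidence(g, gsn_root(g), res, "velocity near vs far")
  expect_match(g3$nodes[[gsn_last_uid(g3)]]$statement,
               "significant difference at alpha = 0.05")

  g4 <- gsn_add_child(g, gsn_root(g), "context", "scope")
  expect_error(attach_evidence(g4, gsn_last_uid(g4), res, "x"),
               class = "gsn_typing_error")
})
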