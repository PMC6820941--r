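test_that("a consistent triangle keeps every edge", {
  g <- mk_graph(data.frame(
    v_i = c("a", "b", "a"), v_j = c("b", "c", "c"),
    otype = "FF", gap = c(10, 10, 1020), weight = c(5, 5, 5)))
  sol <- solve_orientation(g)
  expect_true(all(sol$eta))
  expect_equal(dplyr::n_distinct(sol$orientation$o), 1)
})

test_that("the lightest inconsistent edge of a triangle is dropped", {
  g <- mk_graph(data.frame(
    v_i = c("a", "b", "a"), v_j = c("b", "c", "c"),
    otype = c("FF", "FF", "FR"), gap = 0, weight = c(10, 10, 3)))
  sol <- solve_orientation(g)
  expect_equal(sol$objective, 20)
  expect_equal(sol$objective, brute_force_orientation_objective(g))
  dropped <- g$edges[!sol$eta, ]
  expect_equal(dropped$otype, "FR")
})

test_that("a single edge of any type is always satisfiable", {
  for (ot in c("FF", "RR", "FR", "RF")) {
    g <- mk_graph(data.frame(v_i = "a", v_j = "b", otype = ot,
                             gap = 100, weight = 7))
    sol <- solve_orientation(g)
    expect_true(all(sol$eta))
    o <- stats::setNames(sol$orientation$o, sol$orientation$contig_id)
    if (ot %in% c("FR", "RF")) {
      expect_true(o[["a"]] != o[["b"]])
    } else {
      expect_true(o[["a"]] == o[["b"]])
    }
  }
})

test_that("the orientation solver matches exhaustive search", {
  for (seed in 1:25) {
    g <- random_orientation_graph(n_max = 9, m_max = 12, seed = 1000 + seed)
    sol <- solve_orientation(g)
    expect_equal(sol$objective, brute_force_orientation_objective(g))
    # every kept edge satisfies its constraint under the solved o
    o <- stats::setNames(sol$orientation$o, sol$orientation$contig_id)
    kept <- sol$graph$edges
    same <- o[kept$v_i] == o[kept$v_j]
    opp <- kept$otype %in% c("FR", "RF")
    expect_true(all(ifelse(opp, !same, same)))
  }
})

test_that("positions on a consistent chain are exact cumulative sums", {
  set.seed(42)
  g <- chain_graph(c("a", "b", "c"), lens = c(1000, 2000, 1500),
                   gaps = c(100, 250))
  sol <- solve_orientation(g)
  pos <- solve_positions(sol$graph, sol$orientation)
  p <- stats::setNames(pos$positions$p, pos$positions$contig_id)
  lens <- c(a = 1000, b = 2000, c = 1500)
  gaps <- c(ab = 100, bc = 250)
  if (p[["a"]] < p[["c"]]) {
    # forward layout: cumulative len + gap sums from a
    expect_equal(unname(p[c("a", "b", "c")]),
                 c(0, lens[["a"]] + gaps[["ab"]],
                   lens[["a"]] + gaps[["ab"]] + lens[["b"]] + gaps[["bc"]]))
  } else {
    # mirrored layout (the anchored orientation was 0): cumulative sums of
    # the reversed chain
    expect_equal(unname(p[c("c", "b", "a")]),
                 c(0, lens[["c"]] + gaps[["bc"]],
                   lens[["c"]] + gaps[["bc"]] + lens[["b"]] + gaps[["ab"]]))
  }
  expect_true(all(pos$phi == 1))
  expect_equal(nrow(pos$graph$edges), 2)
})

test_that("a transitive edge contradicting the chain is removed", {
  set.seed(43)
  ch <- chain_graph(c("a", "b", "c"), lens = c(1000, 2000, 1500),
                    gaps = c(100, 250))
  bad <- tibble::tibble(v_i = "a", v_j = "c", otype = "FF",
                        gap = 2350 + 5000,  # implied position off by 5000
                        weight = 10, n_support = 1L,
                        support = list(tibble::tibble(read_id = "x",
                                                      gap = 0, weight = 10)))
  g <- longscaf:::new_scaffold_graph(ch$vertices,
                                     dplyr::bind_rows(ch$edges, bad))
  sol <- solve_orientation(g)
  expect_true(all(sol$eta))  # orientations alone cannot see the problem
  pos <- solve_positions(sol$graph, sol$orientation,
                         scaffold_params(delta = 1000))
  removed <- dplyr::anti_join(g$edges, pos$graph$edges,
                              by = c("v_i", "v_j", "otype"))
  expect_equal(nrow(removed), 1)
  expect_equal(removed$weight, 10)
  # chain edges keep zero residual
  expect_true(all(abs(pos$residual[seq_len(2)]) < 1e-6))
})

test_that("a single-edge component has phi 1 and zero deviation", {
  g <- mk_graph(data.frame(v_i = "a", v_j = "b", otype = "RF",
                           gap = 77, weight = 3))
  sol <- solve_orientation(g)
  pos <- solve_positions(sol$graph, sol$orientation)
  expect_equal(pos$phi, 1)
  expect_equal(pos$residual, 0)
})

test_that("per-end conflicts keep the heaviest edge", {
  # both edges engage the 3' end of a
  g <- mk_graph(data.frame(
    v_i = c("a", "a"), v_j = c("b", "c"), otype = "FF",
    gap = 10, weight = c(800, 300)))
  out <- prune_end_conflicts(g)
  expect_equal(nrow(out$edges), 1)
  expect_equal(out$edges$v_j, "b")

  # a clean chain is untouched: the two edges engage different ends of b
  chain <- mk_graph(data.frame(
    v_i = c("a", "b"), v_j = c("b", "c"), otype = "FF",
    gap = 10, weight = c(5, 6)))
  expect_equal(nrow(prune_end_conflicts(chain)$edges), 2)
})

test_that("residual cycles break at their minimum-weight edge", {
  g <- mk_graph(data.frame(
    v_i = c("a", "b", "a"), v_j = c("b", "c", "c"),
    otype = c("FF", "FF", "RR"),  # c->a forward = a RR c canonical
    gap = c(-100, -100, -100), weight = c(5, 4, 3)),
    lens = c(a = 100, b = 100, c = 100))
  out <- prune_end_conflicts(g)
  expect_equal(nrow(out$edges), 2)
  expect_false(any(out$edges$weight == 3))
  expect_true(graph_is_simple_paths(out))
})

test_that("contradiction-free graphs lose no edges end to end", {
  set.seed(7)
  ids <- sprintf("v%d", 1:6)
  g <- chain_graph(ids, lens = rep(1500, 6), gaps = rep(120, 5))
  res <- remove_contradictions(g)
  expect_equal(unname(res$removed), c(0L, 0L, 0L))
  expect_equal(nrow(res$graph$edges), 5)
})

test_that("cleaning always leaves per-end degree <= 1 and no cycles", {
  for (seed in 1:40) {
    g <- random_orientation_graph(n_max = 8, m_max = 14, seed = 500 + seed)
    res <- remove_contradictions(g)
    expect_true(graph_is_simple_paths(res$graph))
  }
})
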