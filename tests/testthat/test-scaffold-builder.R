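test_that("an edgeless graph yields one singleton scaffold per vertex", {
  g <- longscaf:::new_scaffold_graph(
    tibble::tibble(contig_id = c("a", "b", "c"), length = 1000L),
    longscaf:::empty_edges())
  drafts <- extract_simple_paths(g)
  expect_length(drafts, 3)
  expect_true(all(vapply(drafts, nrow, integer(1)) == 1))
  expect_true(all(vapply(drafts, function(p) p$orientation, integer(1)) == 1))
})

test_that("a four-vertex chain becomes one scaffold with edge gaps", {
  set.seed(1)
  g <- chain_graph(c("a", "b", "c", "d"), lens = rep(1000, 4),
                   gaps = c(10, 20, 30))
  drafts <- extract_simple_paths(g)
  expect_length(drafts, 1)
  p <- drafts[[1]]
  expect_equal(p$contig_id, c("a", "b", "c", "d"))
  expect_equal(p$orientation, rep(1L, 4))
  expect_equal(p$gap_after, c(10, 20, 30, 0))
})

test_that("mixed orientations propagate along opposite-strand edges", {
  # a forward, b reverse: a 3' to b 3' = FR
  g <- mk_graph(data.frame(v_i = "a", v_j = "b", otype = "FR",
                           gap = 50, weight = 5))
  drafts <- extract_simple_paths(g)
  p <- drafts[[1]]
  expect_equal(p$contig_id, c("a", "b"))
  expect_equal(p$orientation, c(1L, 0L))
})

test_that("an all-reverse solution is emitted flipped", {
  # RR edge: with the first vertex forced forward the pair reads (b, a)
  g <- mk_graph(data.frame(v_i = "a", v_j = "b", otype = "RR",
                           gap = 40, weight = 5))
  drafts <- extract_simple_paths(g)
  p <- drafts[[1]]
  expect_equal(p$orientation[1], 1L)
  expect_equal(p$contig_id, c("b", "a"))
  expect_equal(p$gap_after, c(40, 0))
})

test_that("the best-supported ambiguous path is inserted with its gaps", {
  draft <- list(scaffold_parts(c("U1", "U2"), c(1L, 1L), c(700, 0)))
  classes <- mk_classes(c("U1", "U2", "amb_a", "amb_b"),
                        c("unique", "unique", "ambiguous", "ambiguous"))
  ls <- dplyr::bind_rows(
    mk_ls("r1", c("U1", "amb_a", "U2"), gaps = c(100L, 80L),
          aln_len = c(900L, 500L, 800L)),
    mk_ls("r2", c("U1", "amb_a", "U2"), gaps = c(102L, 78L),
          aln_len = c(950L, 550L, 850L)),
    mk_ls("r3", c("U1", "amb_a", "U2"), gaps = c(98L, 82L),
          aln_len = c(990L, 400L, 650L)),
    mk_ls("r4", c("U1", "amb_b", "U2"), gaps = c(10L, 20L),
          aln_len = c(999L, 999L, 999L))
  )
  out <- insert_ambiguous(draft, ls, classes)[[1]]
  expect_equal(out$contig_id, c("U1", "amb_a", "U2"))
  # gaps come from r2, the maximal-weight supporting local scaffold
  expect_equal(out$gap_after, c(102, 78, 0))
})

test_that("junctions without intervening candidates stay as gaps", {
  draft <- list(scaffold_parts(c("U1", "U2"), c(1L, 1L), c(700, 0)))
  classes <- mk_classes(c("U1", "U2"), c("unique", "unique"))
  ls <- mk_ls("r1", c("U1", "U2"), gaps = 700L)
  out <- insert_ambiguous(draft, ls, classes)[[1]]
  expect_equal(out$contig_id, c("U1", "U2"))
  expect_equal(out$gap_after, c(700, 0))
})

test_that("insertion respects the layout direction of reversed reads", {
  # the draft places U1+ then U2+; the read saw U2- amb- U1-
  draft <- list(scaffold_parts(c("U1", "U2"), c(1L, 1L), c(700, 0)))
  classes <- mk_classes(c("U1", "U2", "amb"),
                        c("unique", "unique", "ambiguous"))
  ls <- mk_ls("r1", c("U2", "amb", "U1"), orient = c(0L, 0L, 0L),
              gaps = c(60L, 40L))
  out <- insert_ambiguous(draft, ls, classes)[[1]]
  expect_equal(out$contig_id, c("U1", "amb", "U2"))
  expect_equal(out$orientation, c(1L, 1L, 1L))
  expect_equal(out$gap_after, c(40, 60, 0))
})

test_that("support ties break toward the larger run alignment span", {
  draft <- list(scaffold_parts(c("U1", "U2"), c(1L, 1L), c(700, 0)))
  classes <- mk_classes(c("U1", "U2", "amb_a", "amb_b"),
                        c("unique", "unique", "ambiguous", "ambiguous"))
  ls <- dplyr::bind_rows(
    mk_ls("r1", c("U1", "amb_a", "U2"), gaps = c(1L, 2L),
          aln_len = c(300L, 300L, 300L)),
    mk_ls("r2", c("U1", "amb_b", "U2"), gaps = c(3L, 4L),
          aln_len = c(900L, 900L, 900L))
  )
  out <- insert_ambiguous(draft, ls, classes)[[1]]
  expect_equal(out$contig_id[2], "amb_b")
})

test_that("scaffold heads extend along terminal-contig evidence", {
  scaffolds <- list(scaffold_parts(c("U1", "U2"), c(1L, 1L), c(500, 0)))
  classes <- mk_classes(c("U1", "U2", "amb"),
                        c("unique", "unique", "ambiguous"))
  ls <- dplyr::bind_rows(
    mk_ls("r1", c("amb", "U1"), gaps = 120L, aln_len = c(700L, 900L)),
    mk_ls("r2", c("amb", "U1"), gaps = 118L, aln_len = c(710L, 910L)),
    mk_ls("r3", c("U1", "U2"), gaps = 500L)
  )
  out <- extend_ends(scaffolds, ls, classes)
  expect_equal(out[[1]]$contig_id, c("amb", "U1", "U2"))
  expect_equal(out[[1]]$gap_after[1], 119)

  # a candidate already inside the scaffold is never re-added
  ls2 <- dplyr::bind_rows(
    mk_ls("r1", c("U2", "U1"), gaps = 5L),
    mk_ls("r3", c("U1", "U2"), gaps = 500L)
  )
  out2 <- extend_ends(scaffolds, ls2, classes)
  expect_equal(out2[[1]]$contig_id, c("U1", "U2"))
})

test_that("terminal contigs without companions leave scaffolds unchanged", {
  scaffolds <- list(scaffold_parts(c("U1", "U2"), c(1L, 1L), c(500, 0)))
  classes <- mk_classes(c("U1", "U2"), c("unique", "unique"))
  ls <- mk_ls("r1", c("U1", "U2"), gaps = 500L)
  out <- extend_ends(scaffolds, ls, classes)
  expect_equal(out[[1]], scaffolds[[1]])
})

test_that("scaffolds merge on shared terminal runs", {
  a <- scaffold_parts(c("x", "y", "u", "v"), c(1L, 1L, 1L, 0L),
                      c(10, 20, 30, 0))
  b <- scaffold_parts(c("u", "v", "z"), c(1L, 0L, 1L), c(32, 40, 0))
  out <- merge_scaffolds(list(a, b), t = 2)
  expect_length(out, 1)
  expect_equal(out[[1]]$contig_id, c("x", "y", "u", "v", "z"))
  expect_equal(out[[1]]$gap_after, c(10, 20, 31, 40, 0))

  # no shared run of length t: identity
  out2 <- merge_scaffolds(list(a, scaffold_parts("q", 1L, 0)), t = 2)
  expect_length(out2, 2)
})

test_that("merging also tries the reverse-complemented partner", {
  a <- scaffold_parts(c("x", "u", "v"), c(1L, 1L, 1L), c(10, 30, 0))
  # b reversed equals (u, v, z): stored as (z', v', u')
  b <- scaffold_parts(c("z", "v", "u"), c(0L, 0L, 0L), c(40, 30, 0))
  out <- merge_scaffolds(list(a, b), t = 2)
  expect_length(out, 1)
  expect_equal(out[[1]]$contig_id, c("x", "u", "v", "z"))
  expect_equal(out[[1]]$orientation, c(1L, 1L, 1L, 1L))
})

test_that("merging terminates and only ever reduces the scaffold count", {
  a <- scaffold_parts(c("a", "b"), c(1L, 1L), c(10, 0))
  b <- scaffold_parts(c("b", "c"), c(1L, 1L), c(20, 0))
  c_ <- scaffold_parts(c("c", "d"), c(1L, 1L), c(30, 0))
  out <- merge_scaffolds(list(a, b, c_), t = 1)
  expect_length(out, 1)
  expect_equal(out[[1]]$contig_id, c("a", "b", "c", "d"))
})
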