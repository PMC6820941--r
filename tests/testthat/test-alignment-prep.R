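test_that("length filter applies strict inequalities to reads and contigs", {
  p <- scaffold_params(L_r = 500, L_c = 200)
  alns <- dplyr::bind_rows(
    mk_aln("r1", "c1", 10, 400, 10, 400, read_len = 500, contig_len = 900),
    mk_aln("r2", "c2", 10, 150, 10, 150, read_len = 900, contig_len = 200),
    mk_aln("r3", "c3", 10, 400, 10, 400, read_len = 900, contig_len = 900)
  )
  kept <- filter_alignments_by_length(alns, p)
  expect_equal(kept$read_id, "r3")
  expect_equal(nrow(filter_alignments_by_length(kept, p)), 1)
})

test_that("revision extends both axes to the nearer end by equal amounts", {
  # worked case: LEN(lr)=5000, LEN(c)=2000, (sr,er,sc,ec)=(200,1200,300,1300)
  a <- revise_alignments(mk_aln(sr = 200, er = 1200, sc = 300, ec = 1300,
                                read_len = 5000, contig_len = 2000))
  expect_equal(c(a$sr_p, a$er_p, a$sc_p, a$ec_p), c(0, 1899, 100, 1999))
  expect_equal(a$aln_len, 1000L)

  # sr == sc: both starts revise to zero
  b <- revise_alignments(mk_aln(sr = 150, er = 900, sc = 150, ec = 900,
                                read_len = 3000, contig_len = 1000))
  expect_equal(c(b$sr_p, b$sc_p), c(0, 0))

  # alignment already touching position 0 and the read's last position is a
  # fixed point
  c_ <- revise_alignments(mk_aln(sr = 0, er = 2999, sc = 0, ec = 999,
                                 read_len = 3000, contig_len = 1000))
  expect_equal(c(c_$sr_p, c_$er_p, c_$sc_p, c_$ec_p), c(0, 2999, 0, 999))
})

test_that("revision invariants hold and revision is idempotent", {
  raw <- random_raw_alignments(400, seed = 11)
  rev <- revise_alignments(raw)
  expect_true(all(rev$sr_p <= rev$sr))
  expect_true(all(rev$sc_p <= rev$sc))
  expect_true(all(rev$er_p >= rev$er))
  expect_true(all(rev$ec_p >= rev$ec))
  expect_true(all(pmin(rev$sr_p, rev$sc_p) == 0))
  expect_true(all(rev$er_p == rev$read_len - 1 |
                    rev$ec_p == rev$contig_len - 1))
  expect_true(all((rev$sr - rev$sr_p) == (rev$sc - rev$sc_p)))
  expect_true(all((rev$er_p - rev$er) == (rev$ec_p - rev$ec)))

  again <- revise_alignments(
    dplyr::mutate(rev, sr = sr_p, er = er_p, sc = sc_p, ec = ec_p))
  expect_equal(again$sr_p, rev$sr_p)
  expect_equal(again$er_p, rev$er_p)
  expect_equal(again$sc_p, rev$sc_p)
  expect_equal(again$ec_p, rev$ec_p)
})

test_that("reliability needs MAPQ, span, and bounded revision displacement", {
  p <- scaffold_params()
  interior <- revise_alignments(
    mk_aln(sr = 1000, er = 1500, sc = 0, ec = 500, mapq = 60,
           read_len = 5000, contig_len = 501))
  expect_true(is_reliable(interior, p))

  # MAPQ equal to the threshold is not enough (strictly greater required)
  at_sm <- dplyr::mutate(interior, mapq = 20L)
  expect_false(is_reliable(at_sm, p))

  # a contig-end alignment needing a 200 bp extension exceeds alpha = 150
  shifted <- revise_alignments(
    mk_aln(sr = 200, er = 700, sc = 0, ec = 500, mapq = 60,
           read_len = 5000, contig_len = 501))
  expect_equal(shifted$sr - shifted$sr_p, 0)
  shifted2 <- revise_alignments(
    mk_aln(sr = 200, er = 700, sc = 200, ec = 900, mapq = 60,
           read_len = 5000, contig_len = 901))
  expect_equal(shifted2$sr - shifted2$sr_p, 200)
  expect_false(is_reliable(shifted2, p))

  # monotone in mapq; antitone in displacement via a looser alpha
  expect_true(is_reliable(shifted2, scaffold_params(alpha = 300)))
  expect_false(is_reliable(dplyr::mutate(interior, mapq = 0L), p))
})

test_that("short spans on either axis are unreliable", {
  p <- scaffold_params()
  short_read_axis <- revise_alignments(
    mk_aln(sr = 1000, er = 1100, sc = 100, ec = 300, mapq = 60,
           read_len = 5000, contig_len = 2000))
  expect_false(is_reliable(short_read_axis, p))
  short_contig_axis <- revise_alignments(
    mk_aln(sr = 1000, er = 1300, sc = 100, ec = 200, mapq = 60,
           read_len = 5000, contig_len = 2000))
  expect_false(is_reliable(short_contig_axis, p))
})

test_that("containment flags near-complete coverage in longer contigs", {
  p <- scaffold_params()
  # query contig fully inside a longer one
  full <- mk_aln("small", "big", 0, 999, 200, 1199,
                 read_len = 1000, contig_len = 5000)
  expect_equal(drop_contained_contigs(full, p), "small")

  # 99% coverage with the default 0.95 fraction
  partial <- mk_aln("small", "big", 0, 989, 200, 1189,
                    read_len = 1000, contig_len = 5000)
  expect_equal(drop_contained_contigs(partial, p), "small")

  # 90% coverage is below the fraction
  low <- mk_aln("small", "big", 0, 899, 200, 1099,
                read_len = 1000, contig_len = 5000)
  expect_equal(drop_contained_contigs(low, p), character())

  # equal-length contigs never contain one another
  eq <- mk_aln("small", "big", 0, 999, 0, 999,
               read_len = 1000, contig_len = 1000)
  expect_equal(drop_contained_contigs(eq, p), character())

  expect_message(out <- drop_contained_contigs(NULL, p), "skipped")
  expect_equal(out, character())
})

test_that("reliable_alignments chains the filters", {
  p <- scaffold_params()
  alns <- dplyr::bind_rows(
    mk_aln("r1", "keep", 1000, 1500, 0, 500, mapq = 60,
           read_len = 5000, contig_len = 501),
    mk_aln("r1", "lowq", 2000, 2500, 0, 500, mapq = 5,
           read_len = 5000, contig_len = 501),
    mk_aln("r1", "dropme", 3000, 3500, 0, 500, mapq = 60,
           read_len = 5000, contig_len = 501)
  )
  out <- reliable_alignments(alns, p, drop_contigs = "dropme")
  expect_equal(out$contig_id, "keep")
})
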