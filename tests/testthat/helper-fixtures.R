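# Builders for in-code fixtures shared across the test files.

mk_aln <- function(read_id = "r1", contig_id = "c1",
                   sr, er, sc, ec, strand = 1L, mapq = 60L,
                   read_len, contig_len) {
  tibble::tibble(read_id = read_id, contig_id = contig_id,
                 sr = as.integer(sr), er = as.integer(er),
                 sc = as.integer(sc), ec = as.integer(ec),
                 strand = as.integer(strand), mapq = as.integer(mapq),
                 read_len = as.integer(read_len),
                 contig_len = as.integer(contig_len))
}

# One local scaffold as the build_local_scaffolds() output shape.
mk_ls <- function(read_id, ids, orient = rep(1L, length(ids)),
                  gaps = rep(0L, length(ids) - 1),
                  aln_len = rep(500L, length(ids)),
                  contig_len = rep(2000L, length(ids))) {
  m <- length(ids)
  tibble::tibble(
    read_id = read_id, rank = seq_len(m), contig_id = ids,
    orientation = as.integer(orient),
    gap_to_next = as.integer(c(gaps, 0L)[seq_len(m)]),
    aln_len = as.integer(aln_len),
    contig_len = as.integer(contig_len)
  )
}

mk_classes <- function(ids, labels, lens = rep(2000L, length(ids))) {
  tibble::tibble(
    contig_id = ids, length = as.integer(lens), label = labels,
    reason = ifelse(labels == "unique", "default_unique", "multi_neighbour"),
    n5 = 0L, n3 = 0L, middle_count = 0L
  )
}

mk_graph <- function(edges, lens = NULL) {
  # edges: data frame with v_i, v_j, otype, gap, weight
  verts <- sort(unique(c(edges$v_i, edges$v_j)))
  if (is.null(lens)) lens <- stats::setNames(rep(1000L, length(verts)), verts)
  e <- tibble::tibble(
    v_i = edges$v_i, v_j = edges$v_j, otype = edges$otype,
    gap = as.numeric(edges$gap), weight = as.numeric(edges$weight),
    n_support = 1L,
    support = lapply(seq_len(nrow(edges)), function(i) {
      tibble::tibble(read_id = "x", gap = edges$gap[i],
                     weight = edges$weight[i])
    })
  )
  longscaf:::new_scaffold_graph(
    tibble::tibble(contig_id = verts, length = unname(lens[verts])), e)
}

random_raw_alignments <- function(n, seed) {
  set.seed(seed)
  read_len <- sample(500:20000, n, replace = TRUE)
  contig_len <- sample(300:10000, n, replace = TRUE)
  sr <- integer(n); er <- integer(n); sc <- integer(n); ec <- integer(n)
  for (i in seq_len(n)) {
    span <- sample.int(min(read_len[i], contig_len[i]) - 1L, 1L)
    sr[i] <- sample.int(read_len[i] - span, 1L) - 1L
    er[i] <- sr[i] + span
    sc[i] <- sample.int(contig_len[i] - span, 1L) - 1L
    ec[i] <- sc[i] + span
  }
  mk_aln(read_id = sprintf("r%05d", seq_len(n)),
         contig_id = sprintf("c%05d", seq_len(n)),
         sr = sr, er = er, sc = sc, ec = ec,
         strand = sample(c(0L, 1L), n, replace = TRUE),
         mapq = sample(0:60, n, replace = TRUE),
         read_len = read_len, contig_len = contig_len)
}

random_orientation_graph <- function(n_max = 12, m_max = 16, seed) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  verts <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(verts, 2))
  m <- sample.int(min(m_max, nrow(pairs)), 1)
  sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
  mk_graph(data.frame(
    v_i = sel[, 1], v_j = sel[, 2],
    otype = sample(c("FF", "RR", "FR", "RF"), m, replace = TRUE),
    gap = sample(-200:2000, m, replace = TRUE),
    weight = sample(1:1000, m)
  ))
}

# Independent oracle: exhaustive search over all vertex orientation
# assignments for the maximum total weight of satisfiable edges.
brute_force_orientation_objective <- function(graph) {
  verts <- graph$vertices$contig_id
  n <- length(verts)
  edges <- graph$edges
  opp <- edges$otype %in% c("FR", "RF")
  iu <- match(edges$v_i, verts)
  iv <- match(edges$v_j, verts)
  assign_mat <- as.matrix(expand.grid(rep(list(0:1), n)))
  best <- 0
  for (r in seq_len(nrow(assign_mat))) {
    o <- assign_mat[r, ]
    same <- o[iu] == o[iv]
    sat <- ifelse(opp, !same, same)
    best <- max(best, sum(edges$weight[sat]))
  }
  best
}

# A contradiction-free chain graph with exact gaps: FF edges left to right.
chain_graph <- function(ids, lens, gaps) {
  k <- length(ids)
  mk_graph(
    data.frame(v_i = ids[-k], v_j = ids[-1], otype = "FF",
               gap = gaps, weight = sample(500:1000, k - 1, replace = TRUE)),
    lens = stats::setNames(lens, ids)
  )
}

# Per-end degree and acyclicity check used by the structural tests.
graph_is_simple_paths <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) == 0) return(TRUE)
  ends <- c(paste(edges$v_i, longscaf:::edge_end_i(edges$otype)),
            paste(edges$v_j, longscaf:::edge_end_j(edges$otype)))
  if (any(table(ends) > 1)) return(FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("v_i", "v_j")],
                                     directed = FALSE)
  igraph::girth(g)$girth == 0 || is.infinite(igraph::girth(g)$girth)
}
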