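scaffold_parts <- function(contig_id, orientation, gap_after) {
  tibble::tibble(contig_id = contig_id,
                 orientation = as.integer(orientation),
                 gap_after = as.numeric(gap_after))
}

# Reverse-complement view of a scaffold parts tibble: same physical object.
flip_scaffold <- function(parts) {
  m <- nrow(parts)
  scaffold_parts(
    rev(parts$contig_id),
    1L - rev(parts$orientation),
    if (m > 1) c(rev(parts$gap_after[-m]), 0) else 0
  )
}

# Order (u first?) implied by one edge row under given orientation of v_i.
edge_i_first <- function(otype, o_i) {
  (otype %in% c("FF", "FR") & o_i == 1L) |
    (otype %in% c("RR", "RF") & o_i == 0L)
}

# Propagate an orientation for `nxt` from `cur` across one edge row.
propagate_orientation <- function(edge, cur, o_cur) {
  if (is_opposite_type(edge$otype)) 1L - o_cur else o_cur
}

#' Extract draft scaffolds from a cleaned scaffold graph
#'
#' Every maximal simple path of the graph becomes one draft scaffold;
#' isolated vertices become singleton scaffolds. Orientations are propagated
#' along each path from its (lexicographically smaller) starting endpoint
#' and the whole path is flipped when that leaves the first contig
#' reverse-oriented; junction gaps are the edge gap estimates.
#'
#' @param graph A `scaffold_graph` containing only simple paths (see
#'   [remove_contradictions()]).
#' @return A list of scaffold parts tibbles (`contig_id`, `orientation`,
#'   `gap_after`), ordered deterministically.
#' @export
extract_simple_paths <- function(graph) {
  edges <- graph$edges
  verts <- sort(graph$vertices$contig_id)
  deg <- stats::setNames(rep(0L, length(verts)), verts)
  inc <- stats::setNames(vector("list", length(verts)), verts)
  for (k in seq_len(nrow(edges))) {
    for (v in c(edges$v_i[k], edges$v_j[k])) {
      deg[v] <- deg[v] + 1L
      inc[[v]] <- c(inc[[v]], k)
    }
  }
  stopifnot(all(deg <= 2L))
  out <- list()
  visited <- stats::setNames(rep(FALSE, length(verts)), verts)
  starts <- verts[order(deg[verts] != 0L, verts)]  # singletons first
  for (s in c(verts[deg == 0L], sort(verts[deg == 1L]), verts)) {
    if (visited[s]) next
    if (deg[s] == 0L) {
      visited[s] <- TRUE
      out[[length(out) + 1]] <- scaffold_parts(s, 1L, 0)
      next
    }
    # walk the path (or, defensively, a cycle entered at s)
    seq_v <- s
    seq_o <- 1L
    seq_g <- numeric(0)
    used_edges <- integer(0)
    cur <- s
    visited[s] <- TRUE
    repeat {
      nxt_k <- setdiff(inc[[cur]], used_edges)
      if (length(nxt_k) == 0) break
      k <- nxt_k[1]
      e <- edges[k, ]
      nxt <- if (e$v_i == cur) e$v_j else e$v_i
      if (visited[nxt]) break
      used_edges <- c(used_edges, k)
      seq_o <- c(seq_o,
                 propagate_orientation(e, cur,
                                       seq_o[length(seq_o)]))
      seq_g <- c(seq_g, e$gap)
      seq_v <- c(seq_v, nxt)
      visited[nxt] <- TRUE
      cur <- nxt
    }
    # fix the layout direction: the first edge must place seq_v[1] first
    if (length(seq_v) > 1) {
      e1 <- edges[used_edges[1], ]
      o_vi <- if (e1$v_i == seq_v[1]) seq_o[1] else seq_o[2]
      first_id <- if (edge_i_first(e1$otype, o_vi)) e1$v_i else e1$v_j
      if (first_id != seq_v[1]) seq_o <- 1L - seq_o
    }
    parts <- scaffold_parts(seq_v, seq_o, c(seq_g, 0))
    if (parts$orientation[1] == 0L) {
      flipped <- flip_scaffold(parts)
      if (flipped$orientation[1] == 1L) parts <- flipped
    }
    out[[length(out) + 1]] <- parts
  }
  out
}

# All (read, view) occurrences where `a` then `b` appear with the required
# orientations and only ambiguous contigs in between. Returns a list of
# tibbles of the run rows (a .. b inclusive, view direction == pair
# direction).
pair_support_runs <- function(ls_views, a, oa, b, ob, amb_ids) {
  runs <- list()
  for (df in ls_views) {
    ia <- which(df$contig_id == a & df$orientation == oa)
    ib <- which(df$contig_id == b & df$orientation == ob)
    for (i in ia) {
      j <- ib[ib > i]
      if (length(j) == 0) next
      j <- j[1]
      between <- df[seq(i + 1, length.out = j - i - 1), ]
      if (all(between$contig_id %in% amb_ids)) {
        runs[[length(runs) + 1]] <- df[i:j, ]
      }
    }
  }
  runs
}

split_ls_views <- function(ls) {
  both <- dplyr::bind_rows(
    dplyr::mutate(ls, view = "f"),
    dplyr::mutate(reverse_local_scaffolds(ls), view = "r")
  ) |>
    dplyr::arrange(.data$read_id, .data$view, .data$rank)
  split(both, paste(both$read_id, both$view))
}

#' Insert ambiguous contigs between adjacent scaffold contigs
#'
#' For every junction of a draft scaffold, the local scaffolds containing
#' both flanking unique contigs (in either read direction, orientations
#' matching the layout) are scanned. Each distinct ordered, oriented run of
#' intervening ambiguous contigs is a candidate path; the candidate
#' supported by the most local scaffolds wins (ties: larger run weight, the
#' minimum alignment span over the run, then lexicographic) and is inserted
#' with the gap values of its maximum-weight supporting local scaffold.
#' Junctions with no candidate are left as plain gaps. An ambiguous contig
#' may be inserted at several junctions.
#'
#' @param drafts List of scaffold parts tibbles (see
#'   [extract_simple_paths()]).
#' @param ls Local-scaffold tibble (the full set, ambiguous and short
#'   contigs included).
#' @param classes Classification tibble.
#' @return The list of scaffold parts tibbles with insertions applied.
#' @export
insert_ambiguous <- function(drafts, ls, classes) {
  amb_ids <- classes$contig_id[classes$label == "ambiguous"]
  if (length(amb_ids) == 0 || nrow(ls) == 0) return(drafts)
  views <- split_ls_views(ls)
  lapply(drafts, function(parts) {
    m <- nrow(parts)
    if (m < 2) return(parts)
    pieces <- list()
    for (k in seq_len(m - 1)) {
      a <- parts$contig_id[k]; oa <- parts$orientation[k]
      b <- parts$contig_id[k + 1]; ob <- parts$orientation[k + 1]
      runs <- pair_support_runs(views, a, oa, b, ob, amb_ids)
      runs <- Filter(function(r) nrow(r) > 2, runs)
      head_part <- parts[k, ]
      if (length(runs) > 0) {
        key <- vapply(runs, function(r) {
          mid <- r[-c(1, nrow(r)), ]
          paste(paste0(mid$contig_id, ":", mid$orientation), collapse = ",")
        }, character(1))
        wt <- vapply(runs, function(r) min(r$aln_len), numeric(1))
        tallies <- tibble::tibble(key = key, wt = wt) |>
          dplyr::group_by(.data$key) |>
          dplyr::summarise(n = dplyr::n(), w = max(.data$wt),
                           .groups = "drop") |>
          dplyr::arrange(dplyr::desc(.data$n), dplyr::desc(.data$w),
                         .data$key)
        win <- tallies$key[1]
        cand <- runs[key == win]
        best <- cand[[which.max(vapply(cand, function(r) min(r$aln_len),
                                       numeric(1)))]]
        mid <- best[-c(1, nrow(best)), ]
        head_part$gap_after <- best$gap_to_next[1]
        pieces[[length(pieces) + 1]] <- head_part
        pieces[[length(pieces) + 1]] <-
          scaffold_parts(mid$contig_id, mid$orientation, mid$gap_to_next)
      } else {
        pieces[[length(pieces) + 1]] <- head_part
      }
    }
    pieces[[length(pieces) + 1]] <- parts[m, ]
    dplyr::bind_rows(pieces)
  })
}

# Build a small scaffold graph from a subset of local scaffolds over all
# contigs they mention (no uniqueness projection), clean it, and return its
# draft paths.
mini_scaffold_paths <- function(sub_ls, params) {
  verts <- sub_ls |>
    dplyr::distinct(.data$contig_id, length = .data$contig_len)
  edges <- aggregate_edge_observations(pair_observations(sub_ls))
  g <- new_scaffold_graph(verts, edges)
  cleaned <- remove_contradictions(g, params)
  extract_simple_paths(cleaned$graph)
}

extend_one_end <- function(parts, ls_by_contig, params, placed_elsewhere,
                           head_end) {
  view <- if (head_end) parts else flip_scaffold(parts)
  h <- view$contig_id[1]; oh <- view$orientation[1]
  sub_ls <- ls_by_contig[[h]]
  if (is.null(sub_ls)) return(parts)
  paths <- mini_scaffold_paths(sub_ls, params)
  hit <- Filter(function(p) h %in% p$contig_id, paths)
  if (length(hit) == 0) return(parts)
  p <- hit[[1]]
  k <- which(p$contig_id == h)[1]
  if (p$orientation[k] != oh) {
    p <- flip_scaffold(p)
    k <- which(p$contig_id == h)[1]
  }
  if (k == 1) return(parts)
  before <- p[seq_len(k - 1), ]
  in_scaffold <- parts$contig_id
  allowed <- !(before$contig_id %in% in_scaffold) &
    !(before$contig_id %in% placed_elsewhere)
  # maximal run adjacent to the terminal contig
  run_from <- k
  for (i in rev(seq_len(k - 1))) {
    if (allowed[i]) run_from <- i else break
  }
  if (run_from == k) return(parts)
  ext <- p[seq(run_from, k - 1), ]
  new_view <- dplyr::bind_rows(
    scaffold_parts(ext$contig_id, ext$orientation, ext$gap_after),
    view
  )
  if (head_end) new_view else flip_scaffold(new_view)
}

#' Extend scaffold ends from terminal-contig evidence
#'
#' For each scaffold end, a small scaffold graph is rebuilt from only the
#' local scaffolds containing the terminal contig (same gap and weight
#' aggregation, same contradiction removal) and, when a simple path extends
#' from that contig away from the scaffold body, its not-yet-placed contigs
#' are attached with their gaps. Unique contigs placed in any scaffold and
#' contigs already inside the scaffold are never re-added. Runs to fixpoint
#' over all scaffolds and both ends, capped at `max_passes`.
#'
#' @param scaffolds List of scaffold parts tibbles.
#' @param ls Local-scaffold tibble (full set).
#' @param classes Classification tibble.
#' @param params A [scaffold_params()] object.
#' @param max_passes Pass cap guaranteeing termination. Default 10.
#' @return The extended list of scaffold parts tibbles.
#' @export
extend_ends <- function(scaffolds, ls, classes, params = scaffold_params(),
                        max_passes = 10) {
  if (nrow(ls) == 0) return(scaffolds)
  unique_ids <- unique_contig_ids(classes)
  reads_of <- ls |>
    dplyr::distinct(.data$contig_id, .data$read_id)
  ls_by_contig <- lapply(
    split(reads_of$read_id, reads_of$contig_id),
    function(rids) dplyr::filter(ls, .data$read_id %in% rids)
  )
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (i in seq_along(scaffolds)) {
      placed_elsewhere <- unlist(lapply(scaffolds[-i],
                                        function(p) p$contig_id))
      placed_elsewhere <- intersect(placed_elsewhere, unique_ids)
      for (head_end in c(TRUE, FALSE)) {
        new_parts <- extend_one_end(scaffolds[[i]], ls_by_contig, params,
                                    placed_elsewhere, head_end)
        if (nrow(new_parts) != nrow(scaffolds[[i]])) {
          scaffolds[[i]] <- new_parts
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  scaffolds
}

# TRUE when A's last t parts equal B's first t parts exactly.
tail_head_match <- function(a, b, t) {
  na <- nrow(a); nb <- nrow(b)
  if (na < t || nb < t) return(FALSE)
  ta <- a[seq(na - t + 1, na), ]
  hb <- b[seq_len(t), ]
  all(ta$contig_id == hb$contig_id) &&
    all(ta$orientation == hb$orientation)
}

merge_pair <- function(a, b, t) {
  na <- nrow(a)
  over_a <- seq(na - t + 1, na)
  merged <- a
  if (t > 1) {
    # average the gap estimates inside the shared overlap
    merged$gap_after[over_a[-t]] <-
      (a$gap_after[over_a[-t]] + b$gap_after[seq_len(t - 1)]) / 2
  }
  merged$gap_after[na] <- b$gap_after[t]
  dplyr::bind_rows(merged, b[-seq_len(t), ])
}

#' Merge scaffolds sharing terminal contigs
#'
#' When the last `t` parts of one scaffold equal the first `t` parts of
#' another (contig ids and orientations; the reverse-complemented view of
#' the second scaffold is also tried), the two are merged over the shared
#' parts, averaging the overlap's gap estimates. Repeats to fixpoint with a
#' deterministic processing order.
#'
#' @param scaffolds List of scaffold parts tibbles.
#' @param t Overlap length in contigs (>= 1).
#' @return The merged list of scaffold parts tibbles.
#' @export
merge_scaffolds <- function(scaffolds, t = 2) {
  stopifnot(t >= 1)
  repeat {
    merged_any <- FALSE
    n <- length(scaffolds)
    for (i in seq_len(n)) {
      if (merged_any) break
      for (j in seq_len(n)) {
        if (i == j) next
        b_views <- list(scaffolds[[j]], flip_scaffold(scaffolds[[j]]))
        for (b in b_views) {
          if (tail_head_match(scaffolds[[i]], b, t)) {
            scaffolds[[i]] <- merge_pair(scaffolds[[i]], b, t)
            scaffolds[[j]] <- NULL
            merged_any <- TRUE
            break
          }
        }
        if (merged_any) break
      }
    }
    if (!merged_any) break
  }
  scaffolds
}
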