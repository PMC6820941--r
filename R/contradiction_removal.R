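graph_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$edges[, c("v_i", "v_j")],
    directed = FALSE,
    vertices = graph$vertices$contig_id
  )
}

graph_components <- function(graph) {
  if (nrow(graph$vertices) == 0) {
    return(stats::setNames(integer(), character()))
  }
  igraph::components(graph_igraph(graph))$membership
}

# Exact maximum-weight consistent orientation of one component by
# branch-and-bound over vertex orientations (anchor fixed at 0). `edges` is
# a data frame with integer endpoints ui, vi in 1..n, weight w and logical
# opp (TRUE when the edge demands opposite orientations).
solve_component_orientation <- function(n, edges) {
  if (n == 1 || nrow(edges) == 0) {
    return(list(o = rep(0L, n), satisfied = rep(TRUE, nrow(edges))))
  }
  # BFS vertex order so edges become decided early
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$ui[k]]] <- c(adj[[edges$ui[k]]], k)
    adj[[edges$vi[k]]] <- c(adj[[edges$vi[k]]], k)
  }
  order_ <- integer(0)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order_ <- c(order_, v)
    for (k in adj[[v]]) {
      o <- if (edges$ui[k] == v) edges$vi[k] else edges$ui[k]
      if (!seen[o]) { seen[o] <- TRUE; queue <- c(queue, o) }
    }
  }
  order_ <- c(order_, which(!seen))  # defensive; components are connected
  pos <- integer(n); pos[order_] <- seq_len(n)
  # edge becomes decided when its later endpoint is assigned
  decide_at <- pmax(pos[edges$ui], pos[edges$vi])
  edges_at <- split(seq_len(nrow(edges)), factor(decide_at, levels = 1:n))
  w_total <- sum(edges$w)

  best <- new.env(parent = emptyenv())
  best$obj <- -1
  best$o <- rep(0L, n)
  o <- integer(n)

  recurse <- function(step, current, remaining) {
    if (current + remaining <= best$obj) return()
    if (step > n) {
      best$obj <- current
      best$o <- o
      return()
    }
    v <- order_[step]
    ek <- edges_at[[step]]
    choices <- if (step == 1L) 0L else c(0L, 1L)
    for (val in choices) {
      o[v] <<- val
      gain <- 0
      for (k in ek) {
        same <- o[edges$ui[k]] == o[edges$vi[k]]
        if (same != edges$opp[k]) gain <- gain + edges$w[k]
      }
      recurse(step + 1L, current + gain, remaining - sum(edges$w[ek]))
    }
  }
  recurse(1L, 0, w_total)
  o <- best$o
  same <- o[edges$ui] == o[edges$vi]
  list(o = o, satisfied = ifelse(edges$opp, !same, same))
}

# Deterministic heuristic for oversized components: BFS propagation along a
# maximum-weight spanning tree followed by single-vertex flip hill climbing.
solve_component_orientation_heuristic <- function(n, edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$ui, to = edges$vi), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  mst <- igraph::mst(g, weights = -edges$w)
  o <- rep(NA_integer_, n)
  o[1] <- 0L
  mst_el <- igraph::as_edgelist(mst, names = TRUE)
  mode(mst_el) <- "integer"
  mst_opp <- edges$opp[match(
    paste(pmin(mst_el[, 1], mst_el[, 2]), pmax(mst_el[, 1], mst_el[, 2])),
    paste(pmin(edges$ui, edges$vi), pmax(edges$ui, edges$vi)))]
  repeat {
    progressed <- FALSE
    for (k in seq_len(nrow(mst_el))) {
      u <- mst_el[k, 1]; v <- mst_el[k, 2]
      if (is.na(o[u]) == is.na(o[v])) next
      if (is.na(o[v])) { o[v] <- if (mst_opp[k]) 1L - o[u] else o[u] }
      else { o[u] <- if (mst_opp[k]) 1L - o[v] else o[v] }
      progressed <- TRUE
    }
    if (!progressed) break
  }
  o[is.na(o)] <- 0L
  score <- function(o) {
    same <- o[edges$ui] == o[edges$vi]
    sum(edges$w[ifelse(edges$opp, !same, same)])
  }
  repeat {
    improved <- FALSE
    for (v in 2:n) {
      o2 <- o; o2[v] <- 1L - o2[v]
      if (score(o2) > score(o)) { o <- o2; improved <- TRUE }
    }
    if (!improved) break
  }
  same <- o[edges$ui] == o[edges$vi]
  list(o = o, satisfied = ifelse(edges$opp, !same, same))
}

#' Solve the orientation program and drop unsatisfiable edges
#'
#' Assigns a binary orientation to every unique contig, maximising the total
#' weight of edges whose orientation constraint can be honoured: same-strand
#' edges (FF/RR) require equal orientations, opposite-strand edges (FR/RF)
#' different ones. An edge kept in the solution has its constraint active;
#' the remainder are deemed spurious and removed. Each connected component
#' is solved independently and exactly (one vertex per component is anchored
#' to orientation 0 to break the global flip symmetry); components larger
#' than `max_component` fall back to a deterministic heuristic with a
#' warning.
#'
#' @param graph A `scaffold_graph`.
#' @param params A [scaffold_params()] object.
#' @return A list with elements `graph` (edges restricted to the kept set),
#'   `orientation` (tibble `contig_id`, `o`), `eta` (logical vector over the
#'   input edges, `TRUE` = kept) and `objective` (total kept weight).
#' @export
solve_orientation <- function(graph, params = scaffold_params()) {
  verts <- graph$vertices$contig_id
  o_all <- stats::setNames(rep(0L, length(verts)), verts)
  eta <- rep(TRUE, nrow(graph$edges))
  if (nrow(graph$edges) > 0) {
    membership <- graph_components(graph)
    edge_comp <- membership[graph$edges$v_i]
    for (comp in unique(membership)) {
      cverts <- names(membership)[membership == comp]
      esel <- which(edge_comp == comp)
      if (length(esel) == 0) next
      idx <- stats::setNames(seq_along(cverts), cverts)
      ce <- data.frame(
        ui = idx[graph$edges$v_i[esel]],
        vi = idx[graph$edges$v_j[esel]],
        w = graph$edges$weight[esel],
        opp = is_opposite_type(graph$edges$otype[esel])
      )
      sol <- if (length(cverts) > params$max_component) {
        warning("component with ", length(cverts), " vertices exceeds ",
                "`max_component`; using heuristic orientation")
        solve_component_orientation_heuristic(length(cverts), ce)
      } else {
        solve_component_orientation(length(cverts), ce)
      }
      o_all[cverts] <- sol$o
      eta[esel] <- sol$satisfied
    }
  }
  objective <- sum(graph$edges$weight[eta])
  list(
    graph = new_scaffold_graph(graph$vertices, graph$edges[eta, ]),
    orientation = tibble::tibble(contig_id = names(o_all),
                                 o = unname(o_all)),
    eta = eta,
    objective = objective
  )
}

# Directed view of edges under a solved orientation: u precedes v on the
# forward strand of the layout; the offset constraint is
# p_v - p_u = len(u) + gap.
direct_edges <- function(graph, orientation) {
  if (nrow(graph$edges) == 0) {
    return(tibble::tibble(u = character(), v = character(),
                          c = numeric(), weight = numeric()))
  }
  o <- stats::setNames(orientation$o, orientation$contig_id)
  len <- stats::setNames(graph$vertices$length, graph$vertices$contig_id)
  graph$edges |>
    dplyr::mutate(
      i_first = (.data$otype %in% c("FF", "FR") & o[.data$v_i] == 1L) |
        (.data$otype %in% c("RR", "RF") & o[.data$v_i] == 0L),
      u = dplyr::if_else(.data$i_first, .data$v_i, .data$v_j),
      v = dplyr::if_else(.data$i_first, .data$v_j, .data$v_i),
      c = len[.data$u] + .data$gap
    ) |>
    dplyr::select("u", "v", "c", "weight")
}

# Positions on a forest: zero-residual traversal from each root.
forest_positions <- function(verts, dedges) {
  p <- stats::setNames(rep(NA_real_, length(verts)), verts)
  adj <- lapply(stats::setNames(seq_along(verts), verts), function(i) NULL)
  for (k in seq_len(nrow(dedges))) {
    adj[[dedges$u[k]]] <- rbind(adj[[dedges$u[k]]],
                                data.frame(to = dedges$v[k], d = dedges$c[k]))
    adj[[dedges$v[k]]] <- rbind(adj[[dedges$v[k]]],
                                data.frame(to = dedges$u[k], d = -dedges$c[k]))
  }
  for (root in verts) {
    if (!is.na(p[root])) next
    p[root] <- 0
    queue <- root
    while (length(queue) > 0) {
      x <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[x]]))) {
        to <- adj[[x]]$to[k]
        if (is.na(p[to])) {
          p[to] <- p[x] + adj[[x]]$d[k]
          queue <- c(queue, to)
        }
      }
    }
  }
  p
}

# Weighted least-absolute-deviation positions via the simplex method;
# equivalent to the big-M slack program with phi recovered afterwards.
lp_positions <- function(verts, dedges, L) {
  n <- length(verts)
  m <- nrow(dedges)
  idx <- stats::setNames(seq_len(n), verts)
  A <- matrix(0, 2 * m, n + m)
  b <- numeric(2 * m)
  for (k in seq_len(m)) {
    iu <- idx[dedges$u[k]]; iv <- idx[dedges$v[k]]
    A[2 * k - 1, iv] <- 1; A[2 * k - 1, iu] <- -1; A[2 * k - 1, n + k] <- -1
    b[2 * k - 1] <- dedges$c[k]
    A[2 * k, iv] <- -1; A[2 * k, iu] <- 1; A[2 * k, n + k] <- -1
    b[2 * k] <- -dedges$c[k]
  }
  # positions are translation-invariant, so the simplex non-negativity of p
  # never binds: any optimum can be shifted into the positive orthant
  cc <- c(rep(0, n), dedges$weight)
  sol <- tryCatch(
    pracma::linprog(cc = cc, A = A, b = b, maximize = FALSE,
                    maxiter = max(400L, 40L * (n + m))),
    error = function(e) NULL
  )
  if (!is.null(sol) && !is.null(sol$x) && sol$errno == 1) {
    return(stats::setNames(sol$x[seq_len(n)], verts))
  }
  NULL
}

# Fallback: zero residuals on a maximum-weight spanning tree.
mst_positions <- function(verts, dedges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = dedges$u, to = dedges$v),
    directed = FALSE, vertices = data.frame(name = verts))
  keep <- igraph::mst(g, weights = -dedges$weight)
  el <- igraph::as_edgelist(keep)
  on_tree <- paste(dedges$u, dedges$v) %in%
    c(paste(el[, 1], el[, 2]), paste(el[, 2], el[, 1]))
  forest_positions(verts, dedges[on_tree, , drop = FALSE])
}

#' Solve the position program and drop positionally inconsistent edges
#'
#' With orientations fixed, every edge asserts an offset between its two
#' contigs: predecessor length plus gap estimate. Positions are assigned to
#' maximise the weighted slack objective `sum(w * phi)` under the big-M band
#' `L(phi - 1) <= p_v - p_u - len(u) - g <= L(1 - phi)` with
#' `phi` in `[0, 1]` (`L` is one more than the component's total contig plus
#' absolute gap length, so the band never binds at `phi = 0`); this is
#' equivalent to minimising the weighted absolute residuals. Forest
#' components are solved in closed form with zero residuals; components with
#' cycles go through a simplex solve. Afterwards every edge whose residual
#' `|p_v - p_u - len(u) - g|` exceeds `delta` is removed as spurious.
#'
#' @param graph A `scaffold_graph` (orientation-consistent, see
#'   [solve_orientation()]).
#' @param orientation Orientation tibble from [solve_orientation()].
#' @param params A [scaffold_params()] object.
#' @return A list with `graph` (pruned), `positions` (tibble `contig_id`,
#'   `p`, per-component coordinates with minimum 0), `phi` (numeric vector
#'   over input edges) and `residual` (signed deviations).
#' @export
solve_positions <- function(graph, orientation, params = scaffold_params()) {
  dedges <- direct_edges(graph, orientation)
  verts <- graph$vertices$contig_id
  p <- stats::setNames(rep(0, length(verts)), verts)
  phi <- numeric(nrow(dedges))
  resid <- numeric(nrow(dedges))
  if (nrow(dedges) > 0) {
    membership <- graph_components(graph)
    edge_comp <- membership[dedges$u]
    for (comp in unique(membership)) {
      cverts <- names(membership)[membership == comp]
      esel <- which(edge_comp == comp)
      if (length(esel) == 0) next
      de <- dedges[esel, , drop = FALSE]
      L <- sum(graph$vertices$length[graph$vertices$contig_id %in% cverts]) +
        sum(abs(de$c)) + 1
      if (length(esel) <= length(cverts) - 1) {
        cp <- forest_positions(cverts, de)
      } else {
        cp <- lp_positions(cverts, de, L)
        if (is.null(cp)) {
          warning("position program did not converge for a component; ",
                  "falling back to spanning-tree positions")
          cp <- mst_positions(cverts, de)
        }
      }
      cp <- cp - min(cp)
      p[cverts] <- cp[cverts]
      r <- p[de$v] - p[de$u] - de$c
      resid[esel] <- r
      phi[esel] <- pmax(0, 1 - abs(r) / L)
    }
  }
  keep <- abs(resid) <= params$delta
  list(
    graph = new_scaffold_graph(graph$vertices, graph$edges[keep, ]),
    positions = tibble::tibble(contig_id = verts, p = unname(p)),
    phi = phi,
    residual = resid
  )
}

#' Prune per-end conflicts and residual cycles
#'
#' Each contig has a 5' and a 3' end, and each edge engages one end of each
#' endpoint (determined by its orientation type). When several edges engage
#' the same end of the same contig only the highest-weight one can be real;
#' an edge survives only if it is the chosen edge at both of its ends (ties
#' break by the other endpoint's id, then by orientation type). Any cycle
#' that remains afterwards is broken at its minimum-weight edge, leaving a
#' graph of simple paths.
#'
#' @param graph A `scaffold_graph` after the orientation and position stages.
#' @return The pruned `scaffold_graph`.
#' @export
prune_end_conflicts <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) > 0) {
    otype_rank <- c(FF = 1L, RR = 2L, FR = 3L, RF = 4L)
    slots <- dplyr::bind_rows(
      tibble::tibble(edge = seq_len(nrow(edges)),
                     vertex = edges$v_i, end = edge_end_i(edges$otype),
                     other = edges$v_j, weight = edges$weight,
                     ot = otype_rank[edges$otype]),
      tibble::tibble(edge = seq_len(nrow(edges)),
                     vertex = edges$v_j, end = edge_end_j(edges$otype),
                     other = edges$v_i, weight = edges$weight,
                     ot = otype_rank[edges$otype])
    )
    chosen <- slots |>
      dplyr::group_by(.data$vertex, .data$end) |>
      dplyr::arrange(dplyr::desc(.data$weight), .data$other, .data$ot,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    tab <- table(chosen$edge)
    keep_ids <- as.integer(names(tab)[tab == 2L])
    keep <- seq_len(nrow(edges)) %in% keep_ids
    edges <- edges[keep, ]
  }
  g <- new_scaffold_graph(graph$vertices, edges)
  break_cycles(g)
}

# With per-end degree <= 1, a component is a simple path or a simple cycle;
# cycles have as many edges as vertices and lose their min-weight edge.
break_cycles <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) == 0) return(graph)
  membership <- graph_components(graph)
  edge_comp <- membership[edges$v_i]
  drop <- integer()
  for (comp in unique(edge_comp)) {
    esel <- which(edge_comp == comp)
    nv <- sum(membership == comp)
    if (length(esel) >= nv) {
      sub <- edges[esel, ]
      victim <- esel[order(sub$weight, sub$v_i, sub$v_j)][1]
      drop <- c(drop, victim)
    }
  }
  if (length(drop) > 0) edges <- edges[-drop, ]
  new_scaffold_graph(graph$vertices, edges)
}

#' Remove orientation and position contradictions from a scaffold graph
#'
#' Runs the full cleaning cascade in order: orientation program, position
#' program, per-end pruning with cycle breaking. The result contains only
#' simple paths.
#'
#' @param graph A `scaffold_graph`.
#' @param params A [scaffold_params()] object.
#' @return A list with `graph` (cleaned), `orientation`, `positions`, and a
#'   `removed` count per stage.
#' @export
remove_contradictions <- function(graph, params = scaffold_params()) {
  n0 <- nrow(graph$edges)
  ori <- solve_orientation(graph, params)
  n1 <- nrow(ori$graph$edges)
  pos <- solve_positions(ori$graph, ori$orientation, params)
  n2 <- nrow(pos$graph$edges)
  cleaned <- prune_end_conflicts(pos$graph)
  n3 <- nrow(cleaned$edges)
  list(
    graph = cleaned,
    orientation = ori$orientation,
    positions = pos$positions,
    removed = c(orientation = n0 - n1, position = n1 - n2,
                end_pruning = n2 - n3)
  )
}
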