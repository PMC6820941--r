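#' Project local scaffolds onto unique contigs
#'
#' Drops ambiguous-contig entries from every local scaffold and re-derives
#' the gap between newly adjacent unique contigs as the sum of the
#' intervening read-axis gaps plus the lengths of the skipped contigs:
#' `gap(p, s) = sum_{j=p}^{s-1} scg_j + sum_{j=p+1}^{s-1} LEN(c_j)`. When no
#' contig was skipped this reduces to the original adjacent gap.
#'
#' @param ls Local-scaffold tibble.
#' @param classes Classification tibble from [classify_contigs()].
#' @return A local-scaffold tibble containing only unique contigs, with
#'   re-derived `gap_to_next` values.
#' @export
project_unique <- function(ls, classes) {
  keep_ids <- unique_contig_ids(classes)
  ls |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(
      cum_gap = cumsum(.data$gap_to_next),
      cum_len = cumsum(.data$contig_len)
    ) |>
    dplyr::filter(.data$contig_id %in% keep_ids) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      gap_to_next = dplyr::if_else(
        dplyr::row_number() == dplyr::n(), 0L,
        as.integer(
          dplyr::lead(.data$cum_gap) - .data$cum_gap -
            dplyr::lead(.data$gap_to_next) + .data$gap_to_next +
            dplyr::lead(.data$cum_len) - .data$cum_len -
            dplyr::lead(.data$contig_len)
        ))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"cum_gap", -"cum_len")
}

orientation_pair_type <- function(oa, ob) {
  dplyr::case_when(
    oa == 1L & ob == 1L ~ "FF",
    oa == 0L & ob == 0L ~ "RR",
    oa == 1L & ob == 0L ~ "FR",
    TRUE ~ "RF"
  )
}

#' Per-read edge observations between adjacent unique contigs
#'
#' Extracts every adjacent pair of a projected local-scaffold set as one
#' edge observation under a canonical vertex ordering (`v_i < v_j`
#' lexicographically; swapping the pair reverses entry order and flips both
#' orientations, mapping orientation types FF<->RR and fixing FR/RF). The
#' observation weight is the smaller of the two endpoint alignment spans.
#'
#' @param projected Projected local-scaffold tibble from [project_unique()].
#' @return A tibble with columns `v_i`, `v_j`, `otype`, `gap`, `weight`,
#'   `read_id`.
#' @export
pair_observations <- function(projected) {
  pairs <- adjacent_pairs(projected)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(v_i = character(), v_j = character(),
                          otype = character(), gap = numeric(),
                          weight = numeric(), read_id = character()))
  }
  pairs |>
    dplyr::mutate(
      flip = .data$a > .data$b,
      v_i = dplyr::if_else(.data$flip, .data$b, .data$a),
      v_j = dplyr::if_else(.data$flip, .data$a, .data$b),
      o_i = dplyr::if_else(.data$flip, 1L - .data$ob, .data$oa),
      o_j = dplyr::if_else(.data$flip, 1L - .data$oa, .data$ob),
      otype = orientation_pair_type(.data$o_i, .data$o_j),
      weight = pmin(.data$wa, .data$wb),
      gap = as.numeric(.data$gap)
    ) |>
    dplyr::select("v_i", "v_j", "otype", "gap", "weight", "read_id")
}

#' Aggregate edge observations into scaffold-graph edges
#'
#' For each contig pair the observations are partitioned by orientation
#' type; only the largest class is kept (the orientation vote; ties break by
#' larger summed weight, then by the fixed order FF, RR, FR, RF). The edge
#' gap is the mean observed gap over the winning class, the edge weight the
#' maximum observation weight in it.
#'
#' @param obs Observation tibble from [pair_observations()].
#' @return An edge tibble with columns `v_i`, `v_j`, `otype`, `gap`,
#'   `weight`, `n_support` and a `support` list-column of per-read
#'   `(read_id, gap, weight)` tibbles.
#' @export
aggregate_edge_observations <- function(obs) {
  if (nrow(obs) == 0) return(empty_edges())
  otype_rank <- c(FF = 1L, RR = 2L, FR = 3L, RF = 4L)
  obs |>
    dplyr::group_by(.data$v_i, .data$v_j, .data$otype) |>
    dplyr::summarise(
      support = list(tibble::tibble(read_id, gap, weight)),
      n_support = dplyr::n(),
      sum_weight = sum(.data$weight),
      gap = mean(.data$gap),
      weight = max(.data$weight),
      .groups = "drop_last"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_support),
                   dplyr::desc(.data$sum_weight),
                   otype_rank[.data$otype], .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("v_i", "v_j", "otype", "gap", "weight", "n_support",
                  "support")
}

empty_edges <- function() {
  tibble::tibble(v_i = character(), v_j = character(), otype = character(),
                 gap = numeric(), weight = numeric(), n_support = integer(),
                 support = list())
}

new_scaffold_graph <- function(vertices, edges) {
  structure(list(vertices = vertices, edges = edges),
            class = "scaffold_graph")
}

#' Build the scaffold graph over unique contigs
#'
#' Vertices are all unique contigs (contigs without any edge stay as
#' isolated vertices and are later emitted as singleton scaffolds); edges
#' aggregate the adjacent-pair observations of the projected local
#' scaffolds.
#'
#' @param ls Local-scaffold tibble.
#' @param classes Classification tibble from [classify_contigs()].
#' @return A `scaffold_graph` object: a list with a `vertices` tibble
#'   (`contig_id`, `length`) and an `edges` tibble (see
#'   [aggregate_edge_observations()]).
#' @export
build_scaffold_graph <- function(ls, classes) {
  vertices <- classes |>
    dplyr::filter(.data$label == "unique") |>
    dplyr::select("contig_id", "length")
  edges <- aggregate_edge_observations(pair_observations(
    project_unique(ls, classes)))
  new_scaffold_graph(vertices, edges)
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat(sprintf("<scaffold_graph> %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    print(dplyr::select(x$edges, -"support"), n = 10)
  }
  invisible(x)
}

# End of a vertex engaged by an edge, per orientation type.
edge_end_i <- function(otype) {
  c(FF = "3", RR = "5", FR = "3", RF = "5")[otype]
}
edge_end_j <- function(otype) {
  c(FF = "5", RR = "3", FR = "3", RF = "5")[otype]
}

# TRUE when the edge constraint requires opposite strands (Eq-3 form).
is_opposite_type <- function(otype) otype %in% c("FR", "RF")

#' @exportS3Method generics::tidy
tidy.scaffold_graph <- function(x, ...) {
  dplyr::select(x$edges, -"support")
}

#' @exportS3Method generics::glance
glance.scaffold_graph <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$vertices),
    n_edges = nrow(x$edges),
    total_weight = sum(x$edges$weight),
    mean_support = if (nrow(x$edges)) mean(x$edges$n_support) else NA_real_
  )
}
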