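#' Census of contig positions and neighbours in local scaffolds
#'
#' For every middle-position occurrence of a contig (neither first nor last
#' entry of a local scaffold), accumulates its 5'-end and 3'-end neighbour
#' contig sets. When the occurrence is forward the predecessor along the
#' read is the 5'-end neighbour and the successor the 3'-end neighbour; a
#' reverse occurrence swaps the roles. Contigs shorter than `L_ca` are
#' removed from the local-scaffold view before the census (they are
#' classified ambiguous outright and restored later during insertion).
#'
#' @param ls Local-scaffold tibble (see [build_local_scaffolds()]).
#' @param params A [scaffold_params()] object.
#' @return A tibble with columns `contig_id`, `middle_count`, `n5`, `n3`,
#'   and list-columns `five_prime_neighbours`, `three_prime_neighbours`.
#' @export
neighbour_census <- function(ls, params = scaffold_params()) {
  view <- ls |>
    dplyr::filter(.data$contig_len >= params$L_ca) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  prev = dplyr::lag(.data$contig_id),
                  nxt = dplyr::lead(.data$contig_id)) |>
    dplyr::ungroup()

  middles <- view |>
    dplyr::filter(!is.na(.data$prev), !is.na(.data$nxt)) |>
    dplyr::mutate(
      n5_id = dplyr::if_else(.data$orientation == 1L, .data$prev, .data$nxt),
      n3_id = dplyr::if_else(.data$orientation == 1L, .data$nxt, .data$prev)
    )

  middles |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      middle_count = dplyr::n(),
      five_prime_neighbours = list(sort(unique(.data$n5_id))),
      three_prime_neighbours = list(sort(unique(.data$n3_id))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n5 = lengths(.data$five_prime_neighbours),
      n3 = lengths(.data$three_prime_neighbours)
    )
}

#' Classify contigs as unique or ambiguous
#'
#' A contig is ambiguous when it is shorter than `L_ca` (`reason = "short"`),
#' or when it occurs in the middle position of at least one local scaffold
#' and has more than one distinct 5'-end or more than one distinct 3'-end
#' neighbour across the local scaffolds (`reason = "multi_neighbour"`, the
#' repeat signal). All remaining contigs -- including contigs never aligned
#' by any read -- are unique. Only unique contigs become scaffold-graph
#' vertices; ambiguous contigs are re-inserted into scaffolds later.
#'
#' @param ls Local-scaffold tibble.
#' @param contigs Contig tibble from [read_contigs()].
#' @param params A [scaffold_params()] object.
#' @return A tibble with one row per contig: `contig_id`, `length`, `label`
#'   (`"unique"`/`"ambiguous"`), `reason` (`"short"`, `"multi_neighbour"` or
#'   `"default_unique"`), `n5`, `n3`, `middle_count`.
#' @export
classify_contigs <- function(ls, contigs, params = scaffold_params()) {
  census <- neighbour_census(ls, params)
  contigs |>
    dplyr::select("contig_id", "length") |>
    dplyr::left_join(dplyr::select(census, "contig_id", "middle_count",
                                   "n5", "n3"),
                     by = "contig_id") |>
    dplyr::mutate(
      middle_count = dplyr::coalesce(.data$middle_count, 0L),
      n5 = dplyr::coalesce(.data$n5, 0L),
      n3 = dplyr::coalesce(.data$n3, 0L),
      reason = dplyr::case_when(
        .data$length < params$L_ca ~ "short",
        .data$middle_count >= 1L & (.data$n5 > 1L | .data$n3 > 1L) ~
          "multi_neighbour",
        TRUE ~ "default_unique"
      ),
      label = dplyr::if_else(.data$reason == "default_unique",
                             "unique", "ambiguous")
    ) |>
    dplyr::select("contig_id", "length", "label", "reason",
                  "n5", "n3", "middle_count")
}

unique_contig_ids <- function(classes) {
  classes$contig_id[classes$label == "unique"]
}
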