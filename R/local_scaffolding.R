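#' Resolve read-end alignment conflicts
#'
#' When two or more alignments occupy the same end of a read after revision
#' (revised interval starting at read position 0, or ending at the last read
#' position), only the alignment with the greatest read-axis span survives;
#' ties break by lexicographically smaller contig id. At most two alignments
#' are removed per read, one per end.
#'
#' @param revised Revised alignment tibble for any number of reads.
#' @return The tibble with losing end-anchored alignments removed.
#' @export
dedupe_read_ends <- function(revised) {
  pick_end_winner <- function(df, anchored) {
    if (sum(anchored) <= 1) return(df)
    idx <- which(anchored)
    ord <- idx[order(-df$aln_len[idx], df$contig_id[idx])]
    df[-ord[-1], ]
  }
  revised |>
    dplyr::group_by(.data$read_id) |>
    dplyr::group_modify(function(df, key) {
      df <- pick_end_winner(df, df$sr_p == 0L)
      pick_end_winner(df, df$er_p == df$read_len - 1L)
    }) |>
    dplyr::ungroup()
}

#' Build local scaffolds from each read's reliable alignments
#'
#' Orders each read's surviving alignments along the revised read axis and
#' records, per contig occurrence, its orientation, the signed read-axis gap
#' to the next occurrence (`sr_p(next) - er_p(this) - 1`; negative values
#' indicate overlap) and the pre-revision alignment span. Reads whose
#' alignments were all filtered out yield no rows.
#'
#' @param revised Reliable revised alignment tibble (see
#'   [reliable_alignments()]). Read-end conflicts are resolved internally
#'   via [dedupe_read_ends()].
#' @return A local-scaffold tibble with columns `read_id`, `rank`,
#'   `contig_id`, `orientation` (1 forward / 0 reverse), `gap_to_next`
#'   (0 for the last entry), `aln_len` and `contig_len`.
#' @export
build_local_scaffolds <- function(revised) {
  if (nrow(revised) == 0) return(empty_local_scaffolds())
  revised |>
    dedupe_read_ends() |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$sr_p, .data$sr, .data$contig_id, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      gap_to_next = dplyr::if_else(
        dplyr::row_number() == dplyr::n(), 0L,
        as.integer(dplyr::lead(.data$sr_p) - .data$er_p - 1L))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("read_id", "rank", "contig_id",
                  orientation = "strand", "gap_to_next", "aln_len",
                  "contig_len")
}

empty_local_scaffolds <- function() {
  tibble::tibble(
    read_id = character(), rank = integer(), contig_id = character(),
    orientation = integer(), gap_to_next = integer(), aln_len = integer(),
    contig_len = integer()
  )
}

#' Reverse local scaffolds
#'
#' Produces the opposite-direction view of each local scaffold: entry order
#' reversed, orientations flipped, and gaps re-attached to the junction they
#' describe in the new direction. Both views describe the same physical
#' evidence.
#'
#' @param ls Local-scaffold tibble.
#' @return A local-scaffold tibble of the same shape.
#' @export
reverse_local_scaffolds <- function(ls) {
  ls |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(dplyr::desc(.data$rank), .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      orientation = 1L - .data$orientation,
      gap_to_next = dplyr::if_else(
        dplyr::row_number() == dplyr::n(), 0L,
        dplyr::lead(.data$gap_to_next))
    ) |>
    dplyr::ungroup()
}

adjacent_pairs <- function(ls) {
  ls |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(
      a = .data$contig_id, oa = .data$orientation,
      b = dplyr::lead(.data$contig_id), ob = dplyr::lead(.data$orientation),
      gap = .data$gap_to_next,
      wa = .data$aln_len, wb = dplyr::lead(.data$aln_len)
    ) |>
    dplyr::filter(!is.na(.data$b)) |>
    dplyr::ungroup() |>
    dplyr::select("read_id", "a", "oa", "b", "ob", "gap", "wa", "wb")
}

#' Remove local scaffolds explained by a finer-grained one
#'
#' A read may fail to align to a contig that sits between two others it does
#' align to, producing a coarse local scaffold (A, C) whose gap actually
#' spans a missed contig B. When some other local scaffold orders (A, B, C)
#' with matching orientations of A and C (in either read direction) and
#' `LEN(B) + gap(B, C)` is strictly smaller than the (A, C) gap, the coarse
#' local scaffold is removed. The rule is applied to every adjacent pair of
#' every local scaffold against the witnesses of the full input set.
#'
#' @param ls Local-scaffold tibble.
#' @return The pruned local-scaffold tibble.
#' @export
prune_redundant_local_scaffolds <- function(ls) {
  if (nrow(ls) == 0) return(ls)
  both <- dplyr::bind_rows(
    dplyr::mutate(ls, view = "f"),
    dplyr::mutate(reverse_local_scaffolds(ls), view = "r")
  )

  middles <- both |>
    dplyr::group_by(.data$read_id, .data$view) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(
      a = dplyr::lag(.data$contig_id), oa = dplyr::lag(.data$orientation),
      c = dplyr::lead(.data$contig_id), oc = dplyr::lead(.data$orientation),
      span = .data$contig_len + .data$gap_to_next
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$a), !is.na(.data$c))
  if (nrow(middles) == 0) return(ls)

  triples <- middles |>
    dplyr::group_by(.data$a, .data$oa, .data$c, .data$oc) |>
    dplyr::summarise(min_span = min(.data$span), .groups = "drop")

  doomed <- adjacent_pairs(ls) |>
    dplyr::inner_join(triples,
                      by = c("a", "oa", "b" = "c", "ob" = "oc")) |>
    dplyr::filter(.data$min_span < .data$gap) |>
    dplyr::distinct(.data$read_id)

  dplyr::anti_join(ls, doomed, by = "read_id")
}
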