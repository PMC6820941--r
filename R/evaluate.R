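#' Compare a scaffold layout against a simulated truth layout
#'
#' Restricts each scaffold to the contigs placed exactly once in the truth
#' (repeat contigs are skipped: their placement is intrinsically ambiguous)
#' and counts order/orientation violations: consecutive truth-placed
#' contigs in a scaffold must occupy consecutive truth slots in one
#' consistent direction, with orientations matching that direction. Each
#' offending junction counts one misassembly; per scaffold the better of
#' the two directions is taken, so a perfect layout scores 0 whether or not
#' it is reversed relative to the genome.
#'
#' @param scaffolds Scaffold layout tibble (from a `scaffold_result`).
#' @param truth Truth tibble from the simulator.
#' @return A list with `misassemblies` (total violation count),
#'   `n_junctions` (junctions assessed) and `per_scaffold` (tibble).
#' @export
compare_to_truth <- function(scaffolds, truth) {
  placed_once <- truth |>
    dplyr::count(.data$contig_id) |>
    dplyr::filter(.data$n == 1L) |>
    dplyr::pull(.data$contig_id)
  slot_of <- truth |>
    dplyr::filter(.data$contig_id %in% placed_once) |>
    dplyr::arrange(.data$slot) |>
    dplyr::mutate(slot = dplyr::row_number())
  slot_idx <- stats::setNames(slot_of$slot, slot_of$contig_id)
  slot_ori <- stats::setNames(slot_of$orientation, slot_of$contig_id)

  per <- scaffolds |>
    dplyr::filter(.data$contig_id %in% placed_once) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$index), ]
      m <- nrow(df)
      if (m < 2) {
        return(tibble::tibble(misassemblies = 0L, n_junctions = 0L))
      }
      idx <- unname(slot_idx[df$contig_id])
      tor <- unname(slot_ori[df$contig_id])
      viol_dir <- function(dir) {
        ok_step <- diff(idx) == dir
        # orientation must agree with truth in the forward direction and be
        # flipped in the reverse direction
        expect_o <- if (dir == 1L) tor else 1L - tor
        ok_ori <- df$orientation == expect_o
        sum(!(ok_step & ok_ori[-m] & ok_ori[-1]))
      }
      tibble::tibble(
        misassemblies = min(viol_dir(1L), viol_dir(-1L)),
        n_junctions = m - 1L
      )
    }) |>
    dplyr::ungroup()

  list(misassemblies = sum(per$misassemblies),
       n_junctions = sum(per$n_junctions),
       per_scaffold = per)
}

#' Does a scaffold layout equal the truth layout exactly?
#'
#' `TRUE` when the layout consists of a single scaffold whose full contig
#' order and orientations equal the truth layout, up to whole-scaffold
#' reversal (singleton scaffolds of contigs absent from the truth are not
#' tolerated).
#'
#' @inheritParams compare_to_truth
#' @return Logical scalar.
#' @export
layout_matches_truth <- function(scaffolds, truth) {
  if (dplyr::n_distinct(scaffolds$scaffold_id) != 1) return(FALSE)
  sc <- scaffolds[order(scaffolds$index), ]
  fwd <- identical(sc$contig_id, truth$contig_id) &&
    identical(as.integer(sc$orientation), as.integer(truth$orientation))
  rev_ <- identical(rev(sc$contig_id), truth$contig_id) &&
    identical(as.integer(1L - rev(sc$orientation)),
              as.integer(truth$orientation))
  fwd || rev_
}
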