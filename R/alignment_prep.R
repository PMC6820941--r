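#' Filter alignments by read and contig length
#'
#' Keeps only alignments whose read is strictly longer than `L_r` and whose
#' contig is strictly longer than `L_c`.
#'
#' @param alignments Alignment tibble (see [read_alignments()]).
#' @param params A [scaffold_params()] object.
#' @return The filtered alignment tibble.
#' @export
filter_alignments_by_length <- function(alignments, params = scaffold_params()) {
  dplyr::filter(alignments,
                .data$read_len > params$L_r,
                .data$contig_len > params$L_c)
}

#' Revise alignment coordinates to the implied full-overlap extents
#'
#' Long-read aligners tend to clip noisy alignment ends, so the reported
#' interval underestimates the region a read and contig truly share. Each
#' alignment is extended on both sides until it reaches position 0 of the
#' read or the contig (left) and the last position of the read or the contig
#' (right), whichever is nearer, moving both axes by the same amount:
#' `ext_left = min(sr, sc)` and `ext_right = min(read_len - 1 - er,
#' contig_len - 1 - ec)`. The revised interval is what downstream ordering
#' and gap arithmetic use; the displacement feeds the reliability filter.
#'
#' @param alignments Alignment tibble.
#' @return The tibble with added columns `sr_p`, `er_p`, `sc_p`, `ec_p`
#'   (revised intervals) and `aln_len` (`er - sr`, the pre-revision span on
#'   the read axis).
#' @examples
#' a <- tibble::tibble(read_id = "r", contig_id = "c", sr = 200L, er = 1200L,
#'                     sc = 300L, ec = 1300L, strand = 1L, mapq = 60L,
#'                     read_len = 5000L, contig_len = 2000L)
#' revise_alignments(a)[, c("sr_p", "er_p", "sc_p", "ec_p")]
#' @export
revise_alignments <- function(alignments) {
  dplyr::mutate(alignments,
    ext_left = pmin(.data$sr, .data$sc),
    ext_right = pmin(.data$read_len - 1L - .data$er,
                     .data$contig_len - 1L - .data$ec),
    sr_p = .data$sr - .data$ext_left,
    sc_p = .data$sc - .data$ext_left,
    er_p = .data$er + .data$ext_right,
    ec_p = .data$ec + .data$ext_right,
    aln_len = .data$er - .data$sr,
    ext_left = NULL, ext_right = NULL
  )
}

#' Reliability of revised alignments
#'
#' An alignment is reliable when (i) its mapping quality strictly exceeds
#' `s_m`, (ii) both the read-axis span `er - sr` and the contig-axis span
#' `ec - sc` strictly exceed `l_m`, and (iii) every one of the four
#' endpoints moved strictly less than `alpha` during revision. Only
#' reliable alignments take part in local scaffolding.
#'
#' @param revised Revised alignment tibble (see [revise_alignments()]).
#' @param params A [scaffold_params()] object.
#' @return A logical vector, one element per alignment.
#' @export
is_reliable <- function(revised, params = scaffold_params()) {
  with(revised,
    mapq > params$s_m &
      (er - sr) > params$l_m &
      (ec - sc) > params$l_m &
      (sr - sr_p) < params$alpha &
      (er_p - er) < params$alpha &
      (sc - sc_p) < params$alpha &
      (ec_p - ec) < params$alpha
  )
}

#' Filter, revise and reliability-screen raw alignments
#'
#' Convenience wrapper chaining [filter_alignments_by_length()],
#' [revise_alignments()] and [is_reliable()], returning only the reliable
#' alignments.
#'
#' @inheritParams filter_alignments_by_length
#' @param drop_contigs Optional character vector of contig ids to discard
#'   (e.g. from [drop_contained_contigs()]).
#' @return A revised alignment tibble restricted to reliable records.
#' @export
reliable_alignments <- function(alignments, params = scaffold_params(),
                                drop_contigs = character()) {
  alignments |>
    dplyr::filter(!.data$contig_id %in% drop_contigs) |>
    filter_alignments_by_length(params) |>
    revise_alignments() |>
    dplyr::mutate(reliable = is_reliable(dplyr::pick(dplyr::everything()),
                                         params)) |>
    dplyr::filter(.data$reliable)
}

#' Detect contigs contained in longer contigs
#'
#' Given contig-vs-contig alignments (query contigs aligned to reference
#' contigs, in the same tabular form as read alignments), flags every query
#' contig whose alignment covers at least `containment_fraction` of its
#' length inside a strictly longer contig. Flagged contigs are ignored by
#' the whole pipeline. When no self-alignments are supplied the empty set is
#' returned with a message, since containment detection is optional input.
#'
#' @param self_alignments Contig-vs-contig alignment tibble (`read_id` is
#'   the query contig, `read_len` its length), or `NULL`.
#' @param params A [scaffold_params()] object.
#' @return Character vector of contained contig ids.
#' @export
drop_contained_contigs <- function(self_alignments = NULL,
                                   params = scaffold_params()) {
  if (is.null(self_alignments) || nrow(self_alignments) == 0) {
    message("no contig self-alignments supplied; containment removal skipped")
    return(character())
  }
  self_alignments |>
    dplyr::filter(
      .data$contig_len > .data$read_len,
      .data$read_id != .data$contig_id,
      (.data$er - .data$sr + 1) >=
        params$containment_fraction * .data$read_len
    ) |>
    dplyr::pull(.data$read_id) |>
    unique() |>
    sort()
}
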