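#' Scaffold contigs with long-read alignments
#'
#' Runs the full pipeline: length filtering, coordinate revision and
#' reliability screening of the alignments; per-read local scaffolds with
#' end deduplication and redundancy pruning; unique/ambiguous contig
#' classification; scaffold-graph construction over unique contigs;
#' contradiction removal (orientation program, position program, per-end
#' pruning); simple-path extraction, ambiguous-contig insertion, end
#' extension and terminal merging. Contigs placed nowhere are emitted as
#' singleton scaffolds so the output conserves the input contig set.
#'
#' @param contigs Contig tibble from [read_contigs()].
#' @param alignments Alignment tibble from [read_alignments()].
#' @param params A [scaffold_params()] object.
#' @param classify When `FALSE`, classification is skipped and every contig
#'   is treated as unique (ablation mode; repeats then reach the graph and
#'   must be resolved by contradiction removal alone).
#' @param self_alignments Optional contig-vs-contig alignment tibble for
#'   containment removal (see [drop_contained_contigs()]).
#' @return A `scaffold_result` object: list with `scaffolds` (layout
#'   tibble: `scaffold_id`, `index`, `contig_id`, `orientation`,
#'   `gap_after`), `classes`, `graph` (cleaned), `orientation`, `positions`,
#'   `params` and `report` (per-stage counts).
#' @examples
#' sim <- simulate_scaffolding(sim_config("clean", seed = 1))
#' res <- scaffold_contigs(sim$contigs, sim$alignments)
#' glance(res)
#' @export
scaffold_contigs <- function(contigs, alignments,
                             params = scaffold_params(),
                             classify = TRUE,
                             self_alignments = NULL) {
  contained <- if (is.null(self_alignments)) character() else
    drop_contained_contigs(self_alignments, params)
  usable_contigs <- dplyr::filter(contigs,
                                  !.data$contig_id %in% contained)

  rel <- reliable_alignments(alignments, params, drop_contigs = contained)
  ls0 <- build_local_scaffolds(rel)
  ls <- prune_redundant_local_scaffolds(ls0)

  classes <- if (classify) {
    classify_contigs(ls, usable_contigs, params)
  } else {
    usable_contigs |>
      dplyr::transmute(.data$contig_id, .data$length,
                       label = "unique", reason = "default_unique",
                       n5 = 0L, n3 = 0L, middle_count = 0L)
  }

  graph <- build_scaffold_graph(ls, classes)
  cleaned <- remove_contradictions(graph, params)

  drafts <- extract_simple_paths(cleaned$graph)
  drafts <- insert_ambiguous(drafts, ls, classes)
  drafts <- extend_ends(drafts, ls, classes, params)
  drafts <- merge_scaffolds(drafts, params$t)

  placed <- unique(unlist(lapply(drafts, function(p) p$contig_id)))
  leftover <- setdiff(usable_contigs$contig_id, placed)
  for (id in sort(leftover)) {
    drafts[[length(drafts) + 1]] <- scaffold_parts(id, 1L, 0)
  }

  len_of <- stats::setNames(usable_contigs$length,
                            usable_contigs$contig_id)
  scaffolds <- purrr::imap(drafts, function(p, i) {
    dplyr::mutate(p,
                  scaffold_id = sprintf("scaffold_%04d", i),
                  index = dplyr::row_number())
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("scaffold_id", "index", "contig_id", "orientation",
                  "gap_after")

  spans <- scaffolds |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::summarise(
      span = sum(len_of[.data$contig_id]) +
        sum(pmax(round(.data$gap_after[-dplyr::n()]), 1)),
      .groups = "drop")

  report <- list(
    n_alignments_in = nrow(alignments),
    n_alignments_reliable = nrow(rel),
    n_contigs = nrow(contigs),
    n_contained = length(contained),
    n_local_scaffolds = dplyr::n_distinct(ls0$read_id),
    n_local_scaffolds_pruned = dplyr::n_distinct(ls0$read_id) -
      dplyr::n_distinct(ls$read_id),
    n_unique = sum(classes$label == "unique"),
    n_ambiguous = sum(classes$label == "ambiguous"),
    n_edges_built = nrow(graph$edges),
    n_edges_removed = cleaned$removed,
    n_scaffolds = length(drafts),
    total_span = sum(spans$span),
    largest_scaffold = max(spans$span),
    params = unclass(params)
  )

  structure(
    list(scaffolds = scaffolds, classes = classes, graph = cleaned$graph,
         orientation = cleaned$orientation, positions = cleaned$positions,
         local_scaffolds = ls, params = params, report = report),
    class = "scaffold_result"
  )
}

#' @export
print.scaffold_result <- function(x, ...) {
  r <- x$report
  cat("<scaffold_result>\n")
  cat(sprintf("  alignments: %d in, %d reliable\n",
              r$n_alignments_in, r$n_alignments_reliable))
  cat(sprintf("  contigs: %d (%d unique, %d ambiguous, %d contained)\n",
              r$n_contigs, r$n_unique, r$n_ambiguous, r$n_contained))
  cat(sprintf("  graph: %d edges built, %d removed\n",
              r$n_edges_built, sum(r$n_edges_removed)))
  cat(sprintf("  scaffolds: %d, total span %d bp, largest %d bp\n",
              r$n_scaffolds, r$total_span, r$largest_scaffold))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy scaffold layout
#'
#' @param x A `scaffold_result`.
#' @param ... Unused.
#' @return The scaffold layout tibble (one row per placed contig).
#' @exportS3Method generics::tidy
tidy.scaffold_result <- function(x, ...) x$scaffolds

#' One-row summary of a scaffolding run
#'
#' @param x A `scaffold_result`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @exportS3Method generics::glance
glance.scaffold_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_scaffolds = r$n_scaffolds,
    total_span = r$total_span,
    largest_scaffold = r$largest_scaffold,
    n_unique = r$n_unique,
    n_ambiguous = r$n_ambiguous,
    n_alignments_reliable = r$n_alignments_reliable,
    n_edges_built = r$n_edges_built,
    n_edges_removed = sum(r$n_edges_removed)
  )
}

#' Plot a scaffold layout
#'
#' Draws each scaffold as a horizontal track of oriented contig segments
#' (colour = orientation), offset by the clamped gap runs used in the FASTA
#' rendering.
#'
#' @param object A `scaffold_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scaffold_result <- function(object, ...) {
  len_of <- stats::setNames(object$classes$length,
                            object$classes$contig_id)
  df <- object$scaffolds |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::mutate(
      len = len_of[.data$contig_id],
      n_gap = ifelse(dplyr::row_number() == dplyr::n(),
                     0, pmax(round(.data$gap_after), 1)),
      start = cumsum(dplyr::lag(.data$len + .data$n_gap, default = 0)),
      end = .data$start + .data$len
    ) |>
    dplyr::ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$scaffold_id, yend = .data$scaffold_id,
                   colour = factor(.data$orientation,
                                   levels = c(1, 0),
                                   labels = c("forward", "reverse"))),
      linewidth = 4, lineend = "butt") +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "orientation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write the run report as JSON
#'
#' @param result A `scaffold_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(result, path) {
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
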