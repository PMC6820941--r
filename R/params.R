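#' Scaffolding parameters
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' published method where it states them (`s_m`, `l_m`, `alpha`) and
#' conservative practitioner choices elsewhere.
#'
#' @param s_m Minimum mapping quality; an alignment is reliable only if its
#'   MAPQ is strictly greater than `s_m`. Default 20.
#' @param l_m Minimum alignment span in bp; both the read-axis span
#'   (`er - sr`) and contig-axis span (`ec - sc`) must strictly exceed it.
#'   Default 100.
#' @param alpha Maximum coordinate revision displacement in bp: each of the
#'   four endpoints may move strictly less than `alpha` during revision for
#'   the alignment to stay reliable. Default 150.
#' @param L_r Minimum long-read length in bp (strict). Default 500.
#' @param L_c Minimum contig length in bp (strict); must exceed `l_m`.
#'   Default 200.
#' @param L_ca Ambiguity length cutoff in bp: contigs strictly shorter are
#'   classified ambiguous outright. Default 1000.
#' @param t Number of terminal contigs that must coincide for two scaffolds
#'   to be merged. Default 2.
#' @param containment_fraction Fraction of a contig's length that must be
#'   covered inside a strictly longer contig for it to be dropped as
#'   contained. Default 0.95.
#' @param delta Maximum tolerated deviation in bp between an edge's gap
#'   estimate and the gap implied by the solved positions; larger deviations
#'   mark the edge spurious. Default 1000.
#' @param max_component Largest connected component (vertex count) solved
#'   exactly by the orientation program; larger components fall back to a
#'   deterministic heuristic with a warning. Default 2000 never triggers the
#'   fallback at the problem sizes this package targets.
#'
#' @return An object of class `scaffold_params` (a named list).
#' @examples
#' scaffold_params()
#' scaffold_params(L_ca = 2000, t = 1)
#' @export
scaffold_params <- function(s_m = 20, l_m = 100, alpha = 150,
                            L_r = 500, L_c = 200, L_ca = 1000, t = 2,
                            containment_fraction = 0.95, delta = 1000,
                            max_component = 2000) {
  p <- list(
    s_m = as.integer(s_m), l_m = as.integer(l_m), alpha = as.integer(alpha),
    L_r = as.integer(L_r), L_c = as.integer(L_c), L_ca = as.integer(L_ca),
    t = as.integer(t),
    containment_fraction = as.numeric(containment_fraction),
    delta = as.numeric(delta),
    max_component = as.integer(max_component)
  )
  num <- vapply(p, function(x) x[[1]], numeric(1))
  if (any(num < 0)) {
    stop("all scaffolding parameters must be non-negative", call. = FALSE)
  }
  if (p$l_m >= p$L_c) {
    stop("`l_m` must be smaller than `L_c` (no reliable alignment could ",
         "exist otherwise)", call. = FALSE)
  }
  if (p$containment_fraction > 1) {
    stop("`containment_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "scaffold_params")
}

#' @export
print.scaffold_params <- function(x, ...) {
  cat("<scaffold_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
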