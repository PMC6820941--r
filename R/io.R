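#' Read a contig set from FASTA
#'
#' Parses a FASTA file of assembled contigs. Sequences are uppercased; the
#' record identifier is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per contig and columns `contig_id`,
#'   `length` (bp) and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT", ">c2", "ttaagg"), fa)
#' read_contigs(fa)
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) {
    stop("contig FASTA not found: ", path, call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate contig id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(seqs) > 0 && any(Biostrings::width(seqs) == 0)) {
    stop("zero-length contig record in ", path, call. = FALSE)
  }
  tibble::tibble(
    contig_id = ids,
    length = Biostrings::width(seqs),
    sequence = unname(toupper(as.character(seqs)))
  )
}

#' Read long-read-to-contig alignments from SAM/BAM
#'
#' Converts mapped records of a SAM or BAM file into the internal 0-based
#' inclusive coordinate convention. Reference (contig) coordinates come from
#' `POS` and the reference-consuming CIGAR length; read coordinates are
#' clip-aware and always expressed on the read's original orientation, so
#' for reverse-strand records the SAM query offsets are complemented against
#' the full read length. Read lengths are derived from the CIGAR (soft and
#' hard clips included). Secondary and supplementary records are retained as
#' candidate alignments; unmapped records are dropped.
#'
#' @param path Path to a SAM or BAM file whose `@SQ` names match `contigs`.
#' @param contigs Contig tibble from [read_contigs()].
#' @return A tibble with columns `read_id`, `contig_id`, `sr`, `er`
#'   (0-based inclusive read interval, original orientation), `sc`, `ec`
#'   (0-based inclusive contig interval), `strand` (1 forward / 0 reverse),
#'   `mapq`, `read_len` and `contig_len`.
#' @export
read_alignments <- function(path, contigs) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  bam <- path
  if (!is_bam_file(path)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(rec$qname) == 0) {
    return(empty_alignments())
  }
  rname <- as.character(rec$rname)
  unknown <- setdiff(unique(rname), contigs$contig_id)
  if (length(unknown) > 0) {
    stop("alignment reference(s) absent from contig set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  bad_cigar <- is.na(rec$cigar) | rec$cigar == "*"
  if (any(bad_cigar)) {
    warning(sum(bad_cigar), " mapped record(s) without a CIGAR skipped; ",
            "read length underivable")
  }
  keep <- !bad_cigar
  cigar <- rec$cigar[keep]

  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  per_record <- function(op, ln) {
    qa <- sum(ln[op %in% c("M", "I", "=", "X")])
    left <- 0L
    i <- 1L
    while (i <= length(op) && op[i] %in% c("S", "H")) {
      left <- left + ln[i]; i <- i + 1L
    }
    right <- 0L
    j <- length(op)
    while (j >= 1L && op[j] %in% c("S", "H")) {
      right <- right + ln[j]; j <- j - 1L
    }
    rl <- sum(ln[op %in% c("M", "I", "S", "H", "=", "X")])
    ref <- sum(ln[op %in% c("M", "D", "N", "=", "X")])
    c(qa = qa, left = left, right = right, read_len = rl, ref = ref)
  }
  mat <- mapply(per_record, ops, lens)
  qa <- mat["qa", ]; left <- mat["left", ]; right <- mat["right", ]
  read_len <- mat["read_len", ]; ref_span <- mat["ref", ]

  reverse <- bitwAnd(rec$flag[keep], 16L) > 0L
  sr <- ifelse(reverse, right, left)
  er <- sr + qa - 1

  aln <- tibble::tibble(
    read_id = rec$qname[keep],
    contig_id = rname[keep],
    sr = as.integer(sr),
    er = as.integer(er),
    sc = as.integer(rec$pos[keep] - 1L),
    ec = as.integer(rec$pos[keep] - 1L + ref_span - 1L),
    strand = ifelse(reverse, 0L, 1L),
    mapq = as.integer(rec$mapq[keep]),
    read_len = as.integer(read_len)
  )
  # hard-clip-aware lengths must agree across a read's records; keep the max
  aln <- aln |>
    dplyr::group_by(.data$read_id) |>
    dplyr::mutate(read_len = max(.data$read_len)) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      dplyr::select(contigs, "contig_id", contig_len = "length"),
      by = "contig_id"
    )
  aln
}

is_bam_file <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  length(magic) == 4 && rawToChar(magic[1:3]) == "BAM"
}

empty_alignments <- function() {
  tibble::tibble(
    read_id = character(), contig_id = character(),
    sr = integer(), er = integer(), sc = integer(), ec = integer(),
    strand = integer(), mapq = integer(),
    read_len = integer(), contig_len = integer()
  )
}

#' Per-read summary of an alignment table
#'
#' @param alignments Alignment tibble from [read_alignments()].
#' @return A tibble with columns `read_id` and `read_len`.
#' @export
alignment_reads <- function(alignments) {
  dplyr::distinct(alignments, .data$read_id, .data$read_len)
}

#' Write scaffolds to FASTA and a layout table
#'
#' Renders each scaffold as the concatenation of its oriented contig
#' sequences (reverse-complemented when orientation is 0), separated by
#' `max(round(gap), 1)` `N` characters. The layout TSV preserves the signed,
#' unclamped gap estimates alongside each contig's 0-based start offset in
#' the rendered sequence.
#'
#' @param scaffolds Scaffold layout tibble (columns `scaffold_id`, `index`,
#'   `contig_id`, `orientation`, `gap_after`).
#' @param contigs Contig tibble from [read_contigs()].
#' @param fasta_path Output FASTA path.
#' @param layout_path Output TSV path.
#' @return Invisibly, the layout tibble written (with offsets and `+`/`-`
#'   orientation codes).
#' @export
write_scaffolds <- function(scaffolds, contigs, fasta_path, layout_path) {
  missing_ids <- setdiff(unique(scaffolds$contig_id), contigs$contig_id)
  if (length(missing_ids) > 0) {
    stop("scaffold layout references unknown contig(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  seq_of <- stats::setNames(contigs$sequence, contigs$contig_id)
  len_of <- stats::setNames(contigs$length, contigs$contig_id)

  layout <- scaffolds |>
    dplyr::arrange(.data$scaffold_id, .data$index) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::mutate(
      n_gap = ifelse(dplyr::row_number() == dplyr::n(),
                     0, pmax(round(.data$gap_after), 1)),
      offset = cumsum(dplyr::lag(unname(len_of[.data$contig_id]) +
                                   .data$n_gap, default = 0))
    ) |>
    dplyr::ungroup()

  pieces <- layout |>
    dplyr::mutate(
      part = unname(ifelse(.data$orientation == 1L,
                           seq_of[.data$contig_id],
                           revcomp(seq_of[.data$contig_id]))),
      part = paste0(.data$part, strrep("N", .data$n_gap))
    ) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::summarise(sequence = paste(.data$part, collapse = ""),
                     .groups = "drop")

  out <- Biostrings::DNAStringSet(stats::setNames(pieces$sequence,
                                                  pieces$scaffold_id))
  Biostrings::writeXStringSet(out, fasta_path)

  tsv <- layout |>
    dplyr::transmute(
      .data$scaffold_id, .data$index, .data$contig_id,
      orientation = ifelse(.data$orientation == 1L, "+", "-"),
      gap_after = .data$gap_after,
      offset = .data$offset
    )
  readr::write_tsv(tsv, layout_path)
  invisible(tsv)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
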