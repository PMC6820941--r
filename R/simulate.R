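#' Simulation configuration
#'
#' Parameter set for the bundled generator of synthetic genomes, fragmented
#' contig sets and noisy alignment records. Three presets bundle the
#' validation conditions: `"clean"` (100 kb genome, 20 contigs, no repeats,
#' 20x coverage, no coordinate noise), `"noisy"` (the same with 100 bp
#' endpoint jitter -- below the default revision tolerance `alpha` = 150 --
#' and 10% record dropout) and `"repeat"` (the clean setting plus 3 exact
#' copies of a 2 kb repeat unit, collapsed into a single repeat contig as an
#' assembler would).
#'
#' @param preset `"clean"`, `"noisy"`, `"repeat"`, or `NULL` to take every
#'   value from the arguments.
#' @param genome_length Genome size in bp.
#' @param n_contigs Number of single-copy contigs the genome is cut into.
#' @param repeat_copies Number of exact repeat-unit placements (0 = none).
#' @param repeat_unit_length Repeat unit length in bp.
#' @param read_min,read_max Read length range (uniform), bp.
#' @param coverage Mean sequencing depth.
#' @param coord_noise Maximum endpoint jitter in bp added to every emitted
#'   alignment coordinate.
#' @param p_missing Probability that an overlapped contig emits no
#'   alignment record for a read.
#' @param gap_min,gap_max Range of true inter-contig gaps, bp.
#' @param min_segment Minimum single-copy contig length, bp.
#' @param repeat_mode `"collapsed"` (repeat copies all align to the single
#'   repeat contig with high MAPQ; classification must resolve them) or
#'   `"low_mapq"` (records drawn with MAPQ below the default `s_m`, so the
#'   reliability filter removes them).
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(preset = NULL,
                       genome_length = 100000, n_contigs = 20,
                       repeat_copies = 0, repeat_unit_length = 2000,
                       read_min = 6000, read_max = 12000, coverage = 20,
                       coord_noise = 0, p_missing = 0,
                       gap_min = 20, gap_max = 200, min_segment = 2000,
                       repeat_mode = c("collapsed", "low_mapq"),
                       seed = 1) {
  repeat_mode <- match.arg(repeat_mode)
  cfg <- list(genome_length = genome_length, n_contigs = n_contigs,
              repeat_copies = repeat_copies,
              repeat_unit_length = repeat_unit_length,
              read_min = read_min, read_max = read_max, coverage = coverage,
              coord_noise = coord_noise, p_missing = p_missing,
              gap_min = gap_min, gap_max = gap_max,
              min_segment = min_segment, repeat_mode = repeat_mode,
              seed = as.integer(seed))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("clean", "noisy", "repeat"))
    if (preset == "noisy") {
      cfg$coord_noise <- 100
      cfg$p_missing <- 0.1
    }
    if (preset == "repeat") {
      cfg$repeat_copies <- 3
    }
  }
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome, its truth layout, and a fragmented contig set
#'
#' Generates a random genome carrying `repeat_copies` exact insertions of
#' one repeat unit, then cuts it into contigs separated by short
#' unsequenced gaps. Single-copy segments become individual contigs with a
#' random truth orientation (the stored contig sequence is
#' reverse-complemented relative to the genome when the orientation is 0);
#' all repeat copies collapse into one contig, placed once per copy in the
#' truth layout -- the situation an assembler leaves behind for an exact
#' repeat.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `genome` (character), `contigs` (contig tibble) and
#'   `truth` (tibble `slot`, `contig_id`, `orientation`, `true_gap`,
#'   `genome_start`, `genome_end`).
#' @export
simulate_genome_and_contigs <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_contigs
  # single-copy segment lengths: even split of the non-repeat, non-gap span
  n_slots <- n + cfg$repeat_copies
  gaps <- sample(seq(cfg$gap_min, cfg$gap_max), n_slots - 1, replace = TRUE)
  uniq_total <- cfg$genome_length - sum(gaps) -
    cfg$repeat_copies * cfg$repeat_unit_length
  extra <- uniq_total - n * cfg$min_segment
  stopifnot(extra >= 0)
  prop <- stats::runif(n)
  seg_len <- cfg$min_segment + floor(extra * prop / sum(prop))
  seg_len[1] <- seg_len[1] + (uniq_total - sum(seg_len))
  stopifnot(all(seg_len >= cfg$min_segment))

  # interleave repeat placements at interior slot positions, spaced apart
  slot_is_repeat <- rep(FALSE, n_slots)
  if (cfg$repeat_copies > 0) {
    pos <- seq(2, n_slots - 1,
               length.out = cfg$repeat_copies + 2)[-c(1, cfg$repeat_copies + 2)]
    slot_is_repeat[round(pos)] <- TRUE
    if (sum(slot_is_repeat) < cfg$repeat_copies) {
      free <- setdiff(seq(2, n_slots - 1), which(slot_is_repeat))
      slot_is_repeat[sample(free,
                            cfg$repeat_copies - sum(slot_is_repeat))] <- TRUE
    }
  }
  repeat_seq <- if (cfg$repeat_copies > 0) random_dna(cfg$repeat_unit_length)

  uniq_ids <- sprintf("contig_%02d", seq_len(n))
  uniq_seq_genome <- vapply(seg_len, random_dna, character(1))
  orientations <- stats::setNames(sample(c(0L, 1L), n, replace = TRUE),
                                  uniq_ids)

  slots <- list()
  genome_pieces <- character(n_slots)
  next_uniq <- 1L
  pos0 <- 0L
  for (k in seq_len(n_slots)) {
    if (slot_is_repeat[k]) {
      id <- "repeat_01"; o <- 1L; piece <- repeat_seq
    } else {
      id <- uniq_ids[next_uniq]
      o <- orientations[[id]]
      piece <- uniq_seq_genome[next_uniq]
      next_uniq <- next_uniq + 1L
    }
    g <- if (k < n_slots) gaps[k] else 0L
    slots[[k]] <- tibble::tibble(
      slot = k, contig_id = id, orientation = o, true_gap = g,
      genome_start = pos0, genome_end = pos0 + nchar(piece) - 1L)
    genome_pieces[k] <- piece
    pos0 <- pos0 + nchar(piece) + g
  }
  truth <- dplyr::bind_rows(slots)
  gap_seqs <- c(vapply(gaps, random_dna, character(1)), "")
  genome <- paste(paste0(genome_pieces, gap_seqs), collapse = "")

  contig_rows <- truth |>
    dplyr::distinct(.data$contig_id, .keep_all = TRUE) |>
    dplyr::mutate(
      sequence = substring(genome, .data$genome_start + 1,
                           .data$genome_end + 1),
      sequence = ifelse(.data$orientation == 1L, .data$sequence,
                        revcomp(.data$sequence)),
      length = nchar(.data$sequence)
    ) |>
    dplyr::select("contig_id", "length", "sequence") |>
    dplyr::arrange(.data$contig_id)

  list(genome = genome, contigs = contig_rows, truth = truth)
}

jitter_interval <- function(s, e, lo, hi, noise) {
  if (noise > 0) {
    s <- s + sample.int(2L * noise + 1L, 1L) - noise - 1L
    e <- e + sample.int(2L * noise + 1L, 1L) - noise - 1L
  }
  s <- max(lo, min(s, hi - 1L))
  e <- max(s + 1L, min(e, hi))
  c(s, e)
}

#' Simulate long-read-to-contig alignment records
#'
#' Samples reads uniformly from the genome at the configured coverage and
#' length range, from either strand. Every truth placement overlapped by at
#' least `l_m + 1` bases yields one alignment record with endpoints
#' jittered by at most `coord_noise` bp (never beyond it), dropped with
#' probability `p_missing`. In the default `"collapsed"` repeat mode the
#' repeat contig receives all repeat-copy alignments at full MAPQ; in
#' `"low_mapq"` mode those records get MAPQ drawn strictly below 20.
#'
#' @param sim Output of [simulate_genome_and_contigs()].
#' @param cfg The same [sim_config()] object.
#' @param l_m Minimum overlap used for record emission (matches the
#'   pipeline's `l_m` default).
#' @return A list with `alignments` (alignment tibble in the
#'   [read_alignments()] format) and `reads` (tibble `read_id`,
#'   `read_len`).
#' @export
simulate_alignments <- function(sim, cfg, l_m = 100) {
  set.seed(cfg$seed + 1L)
  G <- nchar(sim$genome)
  n_reads <- max(1L, round(cfg$coverage * G /
                             ((cfg$read_min + cfg$read_max) / 2)))
  if (cfg$coverage == 0) n_reads <- 0L
  len_of <- stats::setNames(sim$contigs$length, sim$contigs$contig_id)

  reads <- tibble::tibble(
    read_id = sprintf("read_%05d", seq_len(n_reads)),
    rl = if (n_reads) sample(seq(cfg$read_min, cfg$read_max), n_reads,
                             replace = TRUE) else integer(),
    start = if (n_reads) sample.int(G, n_reads) - 1L else integer(),
    fwd = if (n_reads) sample(c(TRUE, FALSE), n_reads, replace = TRUE)
          else logical()
  ) |>
    dplyr::mutate(end = pmin(.data$start + .data$rl - 1L, G - 1L),
                  read_len = .data$end - .data$start + 1L)

  recs <- list()
  for (r in seq_len(n_reads)) {
    rs <- reads$start[r]; re <- reads$end[r]; rl <- reads$read_len[r]
    fwd <- reads$fwd[r]
    hits <- sim$truth |>
      dplyr::filter(.data$genome_end >= rs, .data$genome_start <= re)
    for (k in seq_len(nrow(hits))) {
      os <- max(rs, hits$genome_start[k])
      oe <- min(re, hits$genome_end[k])
      if (oe - os + 1L < l_m + 1L) next
      if (cfg$p_missing > 0 && stats::runif(1) < cfg$p_missing) next
      cid <- hits$contig_id[k]
      to <- hits$orientation[k]
      lc <- len_of[[cid]]
      a <- os - hits$genome_start[k]
      b <- oe - hits$genome_start[k]
      if (to == 1L) { sc <- a; ec <- b } else { sc <- lc - 1L - b
                                                ec <- lc - 1L - a }
      if (fwd) { sr <- os - rs; er <- oe - rs } else { sr <- re - oe
                                                       er <- re - os }
      strand <- if (to == if (fwd) 1L else 0L) 1L else 0L
      ji <- jitter_interval(sr, er, 0L, rl - 1L, cfg$coord_noise)
      jc <- jitter_interval(sc, ec, 0L, lc - 1L, cfg$coord_noise)
      mapq <- 60L
      if (grepl("^repeat_", cid) && cfg$repeat_mode == "low_mapq") {
        mapq <- sample.int(20L, 1L) - 1L
      }
      recs[[length(recs) + 1]] <- tibble::tibble(
        read_id = reads$read_id[r], contig_id = cid,
        sr = ji[1], er = ji[2], sc = jc[1], ec = jc[2],
        strand = strand, mapq = mapq,
        read_len = rl, contig_len = lc)
    }
  }
  aln <- if (length(recs)) dplyr::bind_rows(recs) else empty_alignments()
  list(alignments = aln,
       reads = dplyr::select(reads, "read_id", "read_len"))
}

#' Run the whole simulator
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `genome`, `contigs`, `truth`, `alignments`, `reads`
#'   and the `config` used.
#' @examples
#' sim <- simulate_scaffolding(sim_config("clean", seed = 1))
#' nrow(sim$contigs)
#' @export
simulate_scaffolding <- function(cfg = sim_config()) {
  sim <- simulate_genome_and_contigs(cfg)
  aln <- simulate_alignments(sim, cfg)
  c(sim, aln, list(config = cfg))
}

#' Write simulated alignments as a SAM file
#'
#' Emits valid SAM with `@SQ` headers for the contig set and one record per
#' alignment. Read bases are not stored (`SEQ = *`); the CIGAR encodes the
#' clip lengths and an `M`/`I` or `M`/`D` body so that read and contig
#' spans round-trip exactly through [read_alignments()].
#'
#' @param alignments Alignment tibble.
#' @param contigs Contig tibble.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, contigs, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id, contigs$length)
  )
  a <- alignments
  qspan <- a$er - a$sr + 1L
  rspan <- a$ec - a$sc + 1L
  body_m <- pmin(qspan, rspan)
  extra <- abs(qspan - rspan)
  body <- paste0(body_m, "M",
                 ifelse(extra == 0, "",
                        paste0(extra, ifelse(qspan > rspan, "I", "D"))))
  left <- ifelse(a$strand == 1L, a$sr, a$read_len - 1L - a$er)
  right <- ifelse(a$strand == 1L, a$read_len - 1L - a$er, a$sr)
  cigar <- paste0(ifelse(left > 0, paste0(left, "S"), ""),
                  body,
                  ifelse(right > 0, paste0(right, "S"), ""))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   a$read_id, ifelse(a$strand == 1L, 0L, 16L),
                   a$contig_id, a$sc + 1L, a$mapq, cigar)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write simulator outputs to a directory
#'
#' Writes `contigs.fa`, `alignments.sam`, `reads.info.tsv` and `truth.tsv`.
#'
#' @param sim Output of [simulate_scaffolding()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(sim$contigs$sequence,
                                             sim$contigs$contig_id)),
    file.path(dir, "contigs.fa"))
  write_alignments_sam(sim$alignments, sim$contigs,
                       file.path(dir, "alignments.sam"))
  readr::write_tsv(sim$reads, file.path(dir, "reads.info.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
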