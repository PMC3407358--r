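# Accepts a one-row tibble from read_fasta(), a row subset, or a bare string.
genome_seq <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1L, "seq" %in% names(genome))
    return(gsub("U", "T", toupper(genome$seq[[1]]), fixed = TRUE))
  }
  stopifnot(is.character(genome), length(genome) == 1L)
  gsub("U", "T", toupper(genome), fixed = TRUE)
}

genome_id <- function(genome) {
  if (is.data.frame(genome) && "id" %in% names(genome)) genome$id[[1]] else NA_character_
}

#' Find forward-strand open reading frames
#'
#' Scans all three forward reading frames for ORFs (`ATG` ... stop, the stop
#' codon included in the span) of at least `min_len_nt` nucleotides.
#' Positive-sense RNA virus genomes are translated genome-sense, so only the
#' forward strand is scanned. By default, nested same-frame starts are
#' suppressed: for each stop codon only the longest ORF (earliest start after
#' the previous in-frame stop) is reported; set `all_starts = TRUE` to report
#' every start.
#'
#' Reading frames are reported relative to a reference ORF — by default the
#' longest ORF found (in a nidovirus genome, ORF1a). The mapping follows the
#' convention used for programmed ribosomal frameshifting: with
#' `d = (start - ref_start) mod 3`, `d = 0` is frame `0`, `d = 1` is `+1`, and
#' `d = 2` is `-1` — so the ORF downstream of a -1 frameshift is in frame
#' `-1`.
#'
#' @param genome A one-row tibble from [read_fasta()] or a nucleotide string.
#' @param min_len_nt Minimum ORF length in nt (start through stop inclusive);
#'   must be a positive multiple of 3. Default 150.
#' @param all_starts If `TRUE`, report every `ATG` for each stop rather than
#'   only the longest ORF per stop.
#' @return Tibble sorted by `start` with columns `name`, `start`, `end`,
#'   `length_nt`, `frame_rel`, `protein` (translation including the terminal
#'   `'*'`). Empty tibble if no ORF qualifies.
#' @export
#' @examples
#' find_orfs("AAATGGCTTAAAA", min_len_nt = 9)
find_orfs <- function(genome, min_len_nt = 150L, all_starts = FALSE) {
  stopifnot(min_len_nt >= 3L, min_len_nt %% 3L == 0L)
  seq <- genome_seq(genome)
  n <- nchar(seq)
  empty <- tibble(name = character(), start = integer(), end = integer(),
                  length_nt = integer(), frame_rel = integer(),
                  protein = character())
  if (n < min_len_nt) return(empty)

  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (off in 0:2) {
    starts_nt <- seq.int(1L + off, n - 2L, by = 3L)
    if (length(starts_nt) == 0L) next
    codons <- substring(seq, starts_nt, starts_nt + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    open_starts <- integer()  # ATGs since the last in-frame stop
    for (k in seq_along(codons)) {
      if (is_start[k]) open_starts <- c(open_starts, k)
      if (is_stop[k]) {
        if (length(open_starts) > 0L) {
          use <- if (all_starts) open_starts else open_starts[1L]
          for (s in use) {
            orf_start <- starts_nt[s]
            orf_end <- starts_nt[k] + 2L
            if (orf_end - orf_start + 1L >= min_len_nt) {
              found[[length(found) + 1L]] <- c(orf_start, orf_end)
            }
          }
        }
        open_starts <- integer()
      }
    }
  }
  if (length(found) == 0L) return(empty)

  coords <- do.call(rbind, found)
  ord <- order(coords[, 1L], coords[, 2L])
  coords <- coords[ord, , drop = FALSE]
  start <- coords[, 1L]
  end <- coords[, 2L]
  ref_start <- start[[which.max(end - start + 1L)]]
  protein <- vapply(seq_along(start), function(i) {
    suppressWarnings(translate_orf(seq, start[[i]], end[[i]]))
  }, character(1))
  tibble(
    name = sprintf("ORF_%02d", seq_along(start)),
    start = as.integer(start),
    end = as.integer(end),
    length_nt = as.integer(end - start + 1L),
    frame_rel = relative_frame(ref_start, start),
    protein = protein
  )
}

#' Reading frame of one ORF relative to another
#'
#' Maps the start-offset difference `d = (query_start - ref_start) mod 3` to
#' the conventional frame labels `d = 0 -> 0`, `d = 1 -> +1`, `d = 2 -> -1`,
#' so that an ORF expressed via a -1 programmed ribosomal frameshift from the
#' reference ORF is labelled `-1`.
#'
#' @param ref_start Start coordinate (1-based) of the reference ORF.
#' @param query_start Start coordinate(s) of the query ORF(s); vectorised.
#' @return Integer vector in `{-1, 0, +1}`.
#' @export
relative_frame <- function(ref_start, query_start) {
  d <- (as.integer(query_start) - as.integer(ref_start)) %% 3L
  unname(c(0L, 1L, -1L)[d + 1L])
}

#' Overlap in nucleotides between two genome intervals
#'
#' @param start_a,end_a,start_b,end_b 1-based inclusive coordinates;
#'   vectorised.
#' @return Integer overlap size (0 if disjoint).
#' @export
orf_overlap <- function(start_a, end_a, start_b, end_b) {
  as.integer(pmax(0L, pmin(end_a, end_b) - pmax(start_a, start_b) + 1L))
}

#' Scan a genome for a motif allowing mismatches
#'
#' Finds all positions where the motif matches with Hamming distance at most
#' `max_mismatch` (no indels), optionally restricted to a region. `U` and `T`
#' are equivalent in both genome and motif, so RNA motifs such as the
#' slippery sequence `"GGAUUUU"` or candidate transcription-regulating
#' sequences can be scanned directly against a DNA-stored genome.
#'
#' @param genome A one-row tibble from [read_fasta()] or a nucleotide string.
#' @param motif Non-empty nucleotide motif (RNA or DNA alphabet).
#' @param max_mismatch Maximum number of mismatches (default 0).
#' @param region Optional `c(start, end)` 1-based inclusive interval to scan.
#' @return Tibble of hits sorted by position: `motif` (as supplied),
#'   `position` (1-based genome coordinate of the first matched base),
#'   `mismatches`, `context` (genome sequence ±10 nt around the hit).
#' @export
#' @examples
#' scan_motif("AAGGATTTTAA", "GGAUUUU")
scan_motif <- function(genome, motif, max_mismatch = 0L, region = NULL) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) > 0L)
  seq <- genome_seq(genome)
  n <- nchar(seq)
  pat <- gsub("U", "T", toupper(motif), fixed = TRUE)
  if (is.null(region)) {
    region <- c(1L, n)
  }
  stopifnot(length(region) == 2L, region[1] >= 1L, region[2] <= n,
            region[1] <= region[2])
  empty <- tibble(motif = character(), position = integer(),
                  mismatches = integer(), context = character())
  if (nchar(pat) > region[2] - region[1] + 1L) {
    warn("Motif is longer than the scanned region; no hits possible")
    return(empty)
  }
  window <- substr(seq, region[1], region[2])
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(window),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (length(m) == 0L) return(empty)
  pos <- Biostrings::start(m) + region[1] - 1L
  mism <- vapply(seq_along(pos), function(i) {
    hit <- substr(seq, pos[i], pos[i] + nchar(pat) - 1L)
    sum(strsplit(hit, "")[[1]] != strsplit(pat, "")[[1]])
  }, integer(1))
  keep <- mism <= max_mismatch
  pos <- pos[keep]
  mism <- mism[keep]
  ord <- order(pos)
  pos <- pos[ord]
  mism <- mism[ord]
  context <- substr(rep(seq, length(pos)),
                    pmax(1L, pos - 10L),
                    pmin(n, pos + nchar(pat) - 1L + 10L))
  tibble(motif = motif, position = as.integer(pos),
         mismatches = as.integer(mism), context = context)
}

#' Export ORF annotations as GFF3
#'
#' @param orfs Tibble from [find_orfs()].
#' @param seqid Sequence ID used in column 1.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orf_gff3 <- function(orfs, seqid, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tnidotax\tCDS\t%d\t%d\t.\t+\t0\tID=%s;frame_rel=%d",
                     seqid, orfs$start, orfs$end, orfs$name, orfs$frame_rel))
  writeLines(lines, path)
  invisible(path)
}

#' Plot an ORF map by reading frame
#'
#' Draws each ORF as a horizontal segment in its relative reading frame
#' (-1, 0, +1), mirroring the standard genome-organisation diagram for
#' nidoviruses.
#'
#' @param orfs Tibble from [find_orfs()].
#' @return A ggplot object.
#' @export
plot_orf_map <- function(orfs) {
  ggplot2::ggplot(orfs,
                  ggplot2::aes(x = .data$start, xend = .data$end,
                               y = factor(.data$frame_rel, levels = c(-1, 0, 1)),
                               yend = factor(.data$frame_rel, levels = c(-1, 0, 1)))) +
    ggplot2::geom_segment(linewidth = 4, lineend = "butt", colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "Genome position (nt)", y = "Reading frame") +
    ggplot2::theme_minimal()
}
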