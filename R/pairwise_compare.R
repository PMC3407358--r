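nt_substitution_matrix <- function(letters_present, match = 2, mismatch = -3) {
  letters <- union(c("A", "C", "G", "T", "N"), letters_present)
  m <- matrix(mismatch, nrow = length(letters), ncol = length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  # ambiguity codes are scored neutrally against everything
  amb <- setdiff(letters, c("A", "C", "G", "T"))
  m[amb, ] <- 0
  m[, amb] <- 0
  m
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment. Defaults mirror common practice:
#' amino acids use BLOSUM62 with gap open 11 / extend 1; nucleotides use
#' match +2 / mismatch -3 with gap open 5 / extend 2. A gap of length `L`
#' costs `gap_open + L * gap_extend`. All parameters are surfaced because the
#' per-ORF identities of interest are robust to, but not independent of, the
#' scoring scheme.
#'
#' @param a,b Sequences (non-empty strings) over the same alphabet.
#' @param alphabet `"aa"` or `"nt"`.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers);
#'   defaults depend on `alphabet`.
#' @param id_a,id_b Optional sequence labels.
#' @return A `pairwise_alignment` object: list with `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b` (equal-length strings with `'-'`), `score`,
#'   `alphabet`, `gap_open`, `gap_extend`.
#' @export
#' @examples
#' aln <- global_align("MKV", "MRV", alphabet = "aa")
#' percent_identity(aln)
global_align <- function(a, b, alphabet = c("aa", "nt"),
                         gap_open = NULL, gap_extend = NULL,
                         id_a = "a", id_b = "b") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(a), is.character(b), nchar(a) > 0L, nchar(b) > 0L)
  a <- toupper(a)
  b <- toupper(b)
  if (alphabet == "nt") {
    a <- gsub("U", "T", a, fixed = TRUE)
    b <- gsub("U", "T", b, fixed = TRUE)
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    letters_present <- unique(strsplit(paste0(a, b), "")[[1]])
    submat <- nt_substitution_matrix(letters_present)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
  } else {
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = data_env$BLOSUM62,
      gapOpening = gap_open, gapExtension = gap_extend
    )
  }
  out <- list(
    id_a = id_a, id_b = id_b,
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    alphabet = alphabet, gap_open = gap_open, gap_extend = gap_extend
  )
  structure(out, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global pairwise alignment (", x$alphabet, "), score ",
      format(x$score), "\n", sep = "")
  cat(x$id_a, ": ", substr(x$aligned_a, 1, 60),
      if (nchar(x$aligned_a) > 60) "..." else "", "\n", sep = "")
  cat(x$id_b, ": ", substr(x$aligned_b, 1, 60),
      if (nchar(x$aligned_b) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname global_align
#' @param x A `pairwise_alignment` object.
#' @param ... Unused.
#' @method glance pairwise_alignment
#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble(
    id_a = x$id_a, id_b = x$id_b, alphabet = x$alphabet,
    score = x$score, columns = nchar(x$aligned_a),
    identity_excl_gaps = percent_identity(x, "excl_gaps"),
    identity_aligned_columns = percent_identity(x, "aligned_columns")
  )
}

#' Percent identity of a pairwise alignment
#'
#' Two denominators are supported: `"excl_gaps"` (default) counts only
#' columns with a residue in both rows, `"aligned_columns"` uses all
#' alignment columns. For near-length-matched ORFs the two differ
#' negligibly, but the convention is fixed and recorded in outputs.
#'
#' @param aln A `pairwise_alignment`, or a list/tibble row with `aligned_a`
#'   and `aligned_b`.
#' @param mode `"excl_gaps"` or `"aligned_columns"`.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln, mode = c("excl_gaps", "aligned_columns")) {
  mode <- match.arg(mode)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  matches <- sum(both & ca == cb)
  denom <- if (mode == "excl_gaps") sum(both) else length(ca)
  if (denom == 0L) {
    abort("Percent identity undefined: zero-column denominator")
  }
  100 * matches / denom
}

#' Per-ORF comparison table between two genomes
#'
#' Builds a per-ORF report for a genome pair: nucleotide identity from a
#' global alignment of the ORF nucleotide sequences, amino-acid identity
#' from a global alignment of their translations (terminal stop stripped),
#' and reading frames relative to the first listed ORF pair (conventionally
#' ORF1a) in each genome.
#'
#' @param genome_a,genome_b One-row tibbles from [read_fasta()] or
#'   nucleotide strings.
#' @param orf_pairs Tibble with columns `orf_name`, `start_a`, `end_a`,
#'   `start_b`, `end_b` and optionally `product`; the first row is the
#'   frame reference.
#' @param identity_mode Passed to [percent_identity()].
#' @return Tibble with one row per ORF pair: `orf_name`, `length_nt_a`,
#'   `length_nt_b`, `frame_a`, `frame_b`, `identity_nt`, `identity_aa`,
#'   `product`.
#' @export
orf_table <- function(genome_a, genome_b, orf_pairs,
                      identity_mode = "excl_gaps") {
  stopifnot(is.data.frame(orf_pairs),
            all(c("orf_name", "start_a", "end_a", "start_b", "end_b") %in%
                  names(orf_pairs)),
            nrow(orf_pairs) >= 1L)
  seq_a <- genome_seq(genome_a)
  seq_b <- genome_seq(genome_b)
  product <- if ("product" %in% names(orf_pairs)) orf_pairs$product
             else rep(NA_character_, nrow(orf_pairs))

  strip_stop <- function(p) sub("\\*$", "", p)
  rows <- purrr::map(seq_len(nrow(orf_pairs)), function(i) {
    r <- orf_pairs[i, ]
    nt_a <- substr(seq_a, r$start_a, r$end_a)
    nt_b <- substr(seq_b, r$start_b, r$end_b)
    aa_a <- strip_stop(suppressWarnings(translate_orf(seq_a, r$start_a, r$end_a)))
    aa_b <- strip_stop(suppressWarnings(translate_orf(seq_b, r$start_b, r$end_b)))
    tibble(
      orf_name = r$orf_name,
      length_nt_a = r$end_a - r$start_a + 1L,
      length_nt_b = r$end_b - r$start_b + 1L,
      frame_a = relative_frame(orf_pairs$start_a[[1]], r$start_a),
      frame_b = relative_frame(orf_pairs$start_b[[1]], r$start_b),
      identity_nt = percent_identity(
        global_align(nt_a, nt_b, "nt"), identity_mode),
      identity_aa = percent_identity(
        global_align(aa_a, aa_b, "aa"), identity_mode),
      product = product[[i]]
    )
  })
  dplyr::bind_rows(rows)
}
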