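#' Read genome sequences from a FASTA file
#'
#' Parses a (possibly RNA) FASTA file into a tibble of genome records, one row
#' per header. RNA input is accepted and normalised internally: `U` is treated
#' as equivalent to `T` so that all downstream coordinate and motif arithmetic
#' works on a single alphabet. The original alphabet is recorded so
#' [write_fasta()] can restore `U` on output.
#'
#' @param path Path to a FASTA file.
#' @param source Free-text provenance stored with each record; defaults to
#'   `path`.
#'
#' @return A tibble with one row per record and columns
#'   \describe{
#'     \item{id}{record identifier (first whitespace-delimited token of the
#'       header)}
#'     \item{seq}{upper-case nucleotide sequence with `U` normalised to `T`}
#'     \item{length}{sequence length in nt}
#'     \item{alphabet}{`"rna"` if the input used `U`, otherwise `"dna"`}
#'     \item{source}{provenance string}
#'   }
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">virA a demo genome", "ACGUACGU"), fa)
#' read_fasta(fa)
read_fasta <- function(path, source = path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Failed to parse FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file '", path, "' contains no records"))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate record IDs in '", path, "': ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  raw <- toupper(as.character(set))
  for (i in seq_along(raw)) {
    bad <- setdiff(unique(strsplit(raw[[i]], "")[[1]]), IUPAC_NT)
    if (length(bad) > 0L) {
      abort(paste0("Record '", ids[[i]], "' contains non-IUPAC characters: ",
                   paste(bad, collapse = ", ")))
    }
    if (nchar(raw[[i]]) == 0L) {
      abort(paste0("Record '", ids[[i]], "' has an empty sequence"))
    }
  }
  alphabet <- ifelse(grepl("U", raw, fixed = TRUE), "rna", "dna")
  tibble(
    id = unname(ids),
    seq = unname(gsub("U", "T", raw, fixed = TRUE)),
    length = unname(nchar(raw)),
    alphabet = alphabet,
    source = source
  )
}

#' Write sequence records to FASTA
#'
#' Writes a tibble of records (as returned by [read_fasta()], or any tibble
#' with `id` and `seq` columns) to FASTA, line-wrapped at 60 columns. Records
#' whose `alphabet` is `"rna"` are written with `U` in place of `T`.
#'
#' @param records Tibble with columns `id` and `seq` (optionally `alphabet`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  seqs <- records$seq
  if ("alphabet" %in% names(records)) {
    rna <- !is.na(records$alphabet) & records$alphabet == "rna"
    seqs[rna] <- gsub("T", "U", seqs[rna], fixed = TRUE)
  }
  set <- Biostrings::BStringSet(setNames(seqs, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Translate a genome interval with the standard genetic code
#'
#' Translates the 1-based inclusive interval `[start, end]` of a nucleotide
#' sequence using the standard genetic code. Stop codons are rendered as
#' `'*'`; an internal stop raises a warning (not an error) because ORF
#' annotations may be provisional. Codons containing ambiguity codes
#' translate to `'X'`.
#'
#' @param seq Nucleotide string (`U` allowed, treated as `T`).
#' @param start,end 1-based inclusive coordinates; `end - start + 1` must be a
#'   multiple of 3.
#' @return Amino-acid string of length `(end - start + 1) / 3`.
#' @export
#' @examples
#' translate_orf("ATGGCTTAA", 1, 9)  # "MA*"
translate_orf <- function(seq, start = 1L, end = nchar(seq)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (start < 1L || end > n || end < start) {
    abort(paste0("Coordinates [", start, ", ", end,
                 "] outside sequence of length ", n))
  }
  len <- end - start + 1L
  if (len %% 3L != 0L) {
    abort(paste0("Interval length ", len, " is not divisible by 3"))
  }
  sub <- gsub("U", "T", toupper(substr(seq, start, end)), fixed = TRUE)
  codons <- substring(sub, seq(1L, len, by = 3L), seq(3L, len, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  if (any(aa[-length(aa)] == "*")) {
    warn(paste0("Internal stop codon at codon position ",
                paste(which(aa[-length(aa)] == "*"), collapse = ", ")))
  }
  paste(aa, collapse = "")
}

#' Read an aligned amino-acid FASTA as a domain alignment
#'
#' Reads one conserved-domain multiple alignment (aligned FASTA, gap `'-'`)
#' into a long tibble suitable for [concat_domains()]. All rows must have the
#' same length; taxa must be unique; all-gap rows are rejected.
#'
#' @param path Path to an aligned amino-acid FASTA file.
#' @param domain Domain name attached to every row (e.g. `"RdRp"`); defaults
#'   to the file name without extension.
#' @return Tibble with columns `domain`, `taxon`, `seq`.
#' @export
read_alignment <- function(path, domain = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Alignment file not found: ", path))
  }
  domain <- domain %||% sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("Alignment file '", path, "' contains no records"))
  }
  taxa <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  rows <- toupper(as.character(set))
  domain_alignment(taxa, rows, domain = domain)
}

#' Build a domain alignment tibble from taxa and aligned rows
#'
#' @param taxa Character vector of unique taxon IDs.
#' @param rows Equal-length aligned amino-acid strings (gap `'-'`), one per
#'   taxon.
#' @param domain Domain name.
#' @return Tibble with columns `domain`, `taxon`, `seq`.
#' @export
domain_alignment <- function(taxa, rows, domain = "domain") {
  stopifnot(length(taxa) == length(rows))
  if (anyDuplicated(taxa)) {
    abort(paste0("Duplicate taxa in alignment '", domain, "': ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    abort(paste0("Alignment '", domain, "' rows differ in length (",
                 paste(unique(widths), collapse = ", "), ")"))
  }
  if (any(gsub("-", "", rows, fixed = TRUE) == "")) {
    abort(paste0("Alignment '", domain, "' contains an all-gap row"))
  }
  tibble(domain = domain, taxon = unname(taxa), seq = unname(rows))
}
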