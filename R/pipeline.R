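#' Run the full demarcation analysis and write reports
#'
#' End-to-end orchestration of the genetics-based classification: read (or
#' accept) per-domain alignments, concatenate the requested domains, compute
#' the PED matrix, compile the divergence distribution, derive demarcation
#' thresholds, summarise intra-species divergence of labelled reference
#' species, and classify query pairs. All stage outputs are written to
#' `out_dir` along with a machine-readable JSON summary embedding the
#' package version, the full configuration and the seed.
#'
#' @param alignments Long tibble `domain`, `taxon`, `seq`, or a named list
#'   of aligned FASTA paths (names = domain names).
#' @param labels Optional reference labels: tibble `taxon`, `species`, a
#'   named vector, or a path to a TSV with those columns.
#' @param domains Domain names to concatenate (default: all present).
#' @param queries Optional tibble `taxon_a`, `taxon_b` of pairs to classify.
#' @param out_dir Output directory.
#' @param model,gamma_shape Distance model, see [ped()].
#' @param bin_width Histogram bin width.
#' @param n_levels Number of demarcation levels sought.
#' @param dataset Name recorded for the concatenated dataset.
#' @param seed Integer seed recorded in the summary (the analysis itself is
#'   deterministic; the seed matters when `alignments` come from
#'   [simulate_taxonomy()]).
#' @return Invisibly, a list with `concat`, `ped`, `histogram`,
#'   `demarcation`, `intra_max` (or `NULL`), `verdicts` (or `NULL`), and
#'   `summary` (the JSON content as a list).
#' @export
run_demarcation_pipeline <- function(alignments, labels = NULL,
                                     domains = NULL, queries = NULL,
                                     out_dir = tempfile("nidotax_run_"),
                                     model = "poisson", gamma_shape = 1,
                                     bin_width = 0.01, n_levels = 1L,
                                     dataset = NULL, seed = NA_integer_) {
  if (is.character(alignments)) {
    paths <- alignments
    if (is.null(names(paths))) {
      names(paths) <- sub("\\.[^.]*$", "", basename(paths))
    }
    for (p in paths) {
      if (!file.exists(p)) abort(paste0("Alignment file not found: ", p))
    }
    alignments <- dplyr::bind_rows(
      purrr::imap(paths, function(p, d) read_alignment(p, domain = d)))
  }
  if (is.character(labels) && length(labels) == 1L) {
    if (!file.exists(labels)) {
      abort(paste0("Labels file not found: ", labels))
    }
    labels <- as_tibble(utils::read.delim(labels, sep = "\t",
                                          stringsAsFactors = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  concat <- concat_domains(alignments, domains = domains, name = dataset)
  m <- ped_matrix(concat, model = model, gamma_shape = gamma_shape)
  h <- ped_histogram(m, bin_width = bin_width)
  dem <- find_thresholds(m, n_levels = n_levels)
  intra <- if (!is.null(labels)) intra_group_max(m, labels) else NULL
  verdicts <- NULL
  if (!is.null(queries)) {
    stopifnot(all(c("taxon_a", "taxon_b") %in% names(queries)))
    verdicts <- dplyr::bind_rows(purrr::map(seq_len(nrow(queries)), function(i) {
      classify_pair(m, queries$taxon_a[[i]], queries$taxon_b[[i]],
                    labels = labels,
                    thresholds = if (length(dem$thresholds) > 0L) dem else NULL)
    }))
  }

  write_ped_matrix(m, file.path(out_dir, "ped_matrix.tsv"), "tsv")
  write_ped_matrix(m, file.path(out_dir, "ped_matrix.phy"), "phylip")
  write.table(h, file.path(out_dir, "ped_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tidy(dem), file.path(out_dir, "demarcation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(intra)) {
    write.table(intra, file.path(out_dir, "intra_species_max.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(verdicts)) {
    write.table(verdicts, file.path(out_dir, "pair_verdicts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    tool = "nidotax",
    version = as.character(packageVersion("nidotax")),
    seed = seed,
    config = list(domains = domains %||% unique(alignments$domain),
                  dataset = dataset, model = model,
                  gamma_shape = gamma_shape, bin_width = bin_width,
                  n_levels = n_levels),
    n_taxa = nrow(concat),
    n_pairs = nrow(concat) * (nrow(concat) - 1) / 2,
    thresholds = dem$thresholds,
    max_intra_species = if (!is.null(intra)) max(intra$max_ped) else NULL,
    verdicts = if (!is.null(verdicts)) verdicts else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(concat = concat, ped = m, histogram = h, demarcation = dem,
                 intra_max = intra, verdicts = verdicts, summary = summary,
                 out_dir = out_dir))
}
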