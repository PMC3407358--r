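#' Concatenate conserved-domain alignments into one dataset
#'
#' Joins per-domain amino-acid alignments column-wise in the requested
#' order, restricted to the taxa present in every requested domain (taxon
#' order follows the first domain; a warning reports dropped taxa). This is
#' how the conserved-replicase datasets are built: e.g. a nidovirus-wide
#' dataset from 3CLpro + RdRp + HEL1, and a larger one adding ExoN + OMT.
#'
#' @param alignments Long tibble with columns `domain`, `taxon`, `seq` (e.g.
#'   several [read_alignment()] results row-bound together), or a list of
#'   such tibbles.
#' @param domains Character vector of domain names, in concatenation order.
#' @param name Optional dataset name (e.g. `"D1"`).
#' @return A `concat_alignment`: tibble with columns `taxon`, `seq`, plus
#'   attributes `block_spans` (tibble `domain`, `start`, `end` of each
#'   domain's column interval) and `dataset`.
#' @export
concat_domains <- function(alignments, domains = NULL, name = NULL) {
  if (is.list(alignments) && !is.data.frame(alignments)) {
    alignments <- dplyr::bind_rows(alignments)
  }
  stopifnot(is.data.frame(alignments),
            all(c("domain", "taxon", "seq") %in% names(alignments)))
  domains <- domains %||% unique(alignments$domain)
  stopifnot(length(domains) >= 1L)
  missing <- setdiff(domains, unique(alignments$domain))
  if (length(missing) > 0L) {
    abort(paste0("Requested domain(s) not present: ",
                 paste(missing, collapse = ", ")))
  }
  blocks <- purrr::map(domains, function(d) {
    blk <- alignments[alignments$domain == d, ]
    widths <- unique(nchar(blk$seq))
    if (length(widths) > 1L) {
      abort(paste0("Alignment '", d, "' rows differ in length"))
    }
    blk
  })
  taxa_sets <- purrr::map(blocks, "taxon")
  common <- Reduce(intersect, taxa_sets)
  if (length(common) == 0L) {
    abort("Domain alignments share no taxa")
  }
  all_taxa <- unique(unlist(taxa_sets))
  dropped <- setdiff(all_taxa, common)
  if (length(dropped) > 0L) {
    warn(paste0("Dropping ", length(dropped),
                " taxa absent from some domain(s): ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
  }
  taxa <- taxa_sets[[1]][taxa_sets[[1]] %in% common]

  widths <- vapply(blocks, function(b) nchar(b$seq[[1]]), integer(1))
  ends <- cumsum(widths)
  spans <- tibble(domain = domains,
                  start = as.integer(ends - widths + 1L),
                  end = as.integer(ends))
  rows <- vapply(taxa, function(tx) {
    paste(vapply(blocks, function(b) b$seq[[match(tx, b$taxon)]],
                 character(1)), collapse = "")
  }, character(1))
  out <- tibble(taxon = taxa, seq = unname(rows))
  structure(out, block_spans = spans, dataset = name,
            class = c("concat_alignment", class(out)))
}

#' Block spans of a concatenated alignment
#' @param x A `concat_alignment`.
#' @return Tibble `domain`, `start`, `end` (1-based column intervals).
#' @export
block_spans <- function(x) attr(x, "block_spans")

ped_from_p <- function(p, model, gamma_shape = 1) {
  switch(model,
    p = p,
    poisson = {
      if (any(p >= 1)) abort("p-distance of 1 cannot be Poisson-corrected")
      -log(1 - p)
    },
    gamma_poisson = {
      if (any(p >= 1)) abort("p-distance of 1 cannot be Gamma-corrected")
      stopifnot(gamma_shape > 0)
      gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1)
    },
    abort(paste0("Unknown distance model: ", model))
  )
}

#' Pairwise evolutionary distance between two aligned rows
#'
#' Computes the proportion of differing residues over compared columns and
#' optionally corrects it for multiple substitutions. Compared columns
#' exclude any column that is gapped (`'-'`) or ambiguous (`'X'`) in either
#' row (pairwise deletion). Models:
#' \describe{
#'   \item{`p`}{uncorrected p-distance, `p = mismatches / compared`}
#'   \item{`poisson`}{Poisson correction, `-ln(1 - p)`}
#'   \item{`gamma_poisson`}{Gamma-rate Poisson correction with shape `a`:
#'     `a * ((1 - p)^(-1/a) - 1)`}
#' }
#' For any `p > 0`, `p < poisson < gamma_poisson(a)`; at the small
#' intra-species distances this package is typically used at (around
#' 0.02-0.04 substitutions/site) the three nearly coincide.
#'
#' @param row_a,row_b Equal-length aligned amino-acid strings.
#' @param model `"p"`, `"poisson"` (default) or `"gamma_poisson"`.
#' @param gamma_shape Gamma shape parameter `a > 0` (default 1).
#' @return Estimated substitutions per site (non-negative number).
#' @export
#' @examples
#' ped("MKVA", "MRVA", model = "p")       # 0.25
#' ped("MKVA", "MRVA", model = "poisson") # -log(0.75)
ped <- function(row_a, row_b, model = c("poisson", "p", "gamma_poisson"),
                gamma_shape = 1) {
  model <- match.arg(model)
  stopifnot(nchar(row_a) == nchar(row_b))
  ca <- strsplit(toupper(row_a), "")[[1]]
  cb <- strsplit(toupper(row_b), "")[[1]]
  ok <- ca != "-" & cb != "-" & ca != "X" & cb != "X"
  n <- sum(ok)
  if (n == 0L) abort("No comparable columns between rows (all gap/ambiguous)")
  p <- sum(ca[ok] != cb[ok]) / n
  ped_from_p(p, model, gamma_shape)
}

#' Pairwise evolutionary distance matrix over an alignment
#'
#' Applies [ped()] to every pair of taxa in a (concatenated) alignment.
#'
#' @param aln A `concat_alignment`, or any tibble with `taxon` and `seq`
#'   columns of equal-length aligned rows.
#' @param model,gamma_shape See [ped()].
#' @return A `ped_matrix`: list with `taxa`, `values` (symmetric matrix,
#'   zero diagonal), `model`, `gamma_shape`, `dataset`.
#' @export
ped_matrix <- function(aln, model = c("poisson", "p", "gamma_poisson"),
                       gamma_shape = 1) {
  model <- match.arg(model)
  stopifnot(is.data.frame(aln), all(c("taxon", "seq") %in% names(aln)),
            nrow(aln) >= 2L)
  taxa <- aln$taxon
  chars <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  ok <- chars != "-" & chars != "X"
  n <- length(taxa)
  vals <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cc <- ok[i, ] & ok[j, ]
      m <- sum(cc)
      if (m == 0L) {
        abort(paste0("No comparable columns between '", taxa[i], "' and '",
                     taxa[j], "'"))
      }
      p <- sum(chars[i, cc] != chars[j, cc]) / m
      vals[i, j] <- vals[j, i] <- ped_from_p(p, model, gamma_shape)
    }
  }
  structure(list(taxa = taxa, values = vals, model = model,
                 gamma_shape = if (model == "gamma_poisson") gamma_shape else NA_real_,
                 dataset = attr(aln, "dataset")),
            class = "ped_matrix")
}

#' @export
print.ped_matrix <- function(x, ...) {
  cat("Pairwise evolutionary distance matrix: ", length(x$taxa), " taxa, ",
      "model ", x$model,
      if (!is.na(x$gamma_shape)) paste0(" (shape ", x$gamma_shape, ")"),
      if (!is.null(x$dataset)) paste0(", dataset ", x$dataset),
      "\n", sep = "")
  v <- ped_values(x)
  cat("PED range: ", format(min(v), digits = 3), " - ",
      format(max(v), digits = 3), " over ", length(v), " pairs\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.ped_matrix <- function(x, ...) x$values

#' @export
as.dist.ped_matrix <- function(m, ...) as.dist(m$values)

# lower-triangle values, one per unordered pair
ped_values <- function(m) m$values[lower.tri(m$values)]

#' Tidy a PED matrix into one row per taxon pair
#'
#' @param x A `ped_matrix`.
#' @param ... Unused.
#' @return Tibble `taxon_a`, `taxon_b`, `ped` with `n(n-1)/2` rows.
#' @method tidy ped_matrix
#' @export
tidy.ped_matrix <- function(x, ...) {
  n <- length(x$taxa)
  idx <- which(lower.tri(x$values), arr.ind = TRUE)
  tibble(taxon_a = x$taxa[idx[, 2]], taxon_b = x$taxa[idx[, 1]],
         ped = x$values[idx]) |>
    dplyr::arrange(match(.data$taxon_a, x$taxa), match(.data$taxon_b, x$taxa))
}

#' Frequency distribution of pairwise distances
#'
#' Bins the `n(n-1)/2` pairwise distances into half-open intervals
#' `[k*w, (k+1)*w)`; counts sum exactly to the number of pairs. This is the
#' divergence distribution on which demarcation thresholds are read off.
#'
#' @param m A `ped_matrix`.
#' @param bin_width Positive bin width (substitutions/site). Default 0.01.
#' @return Tibble `bin_lower`, `bin_upper`, `count`, including empty bins
#'   between 0 and the maximum distance.
#' @export
ped_histogram <- function(m, bin_width = 0.01) {
  stopifnot(bin_width > 0)
  v <- ped_values(m)
  k <- floor(v / bin_width)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  tibble(bin_lower = (0:kmax) * bin_width,
         bin_upper = (1:(kmax + 1L)) * bin_width,
         count = as.integer(counts))
}

#' Maximum intra-group divergence per labelled group
#'
#' For each group with at least two members, returns the maximum PED
#' between its members — the reference quantity against which a candidate
#' pair's distance is compared for a same-species verdict. Singleton groups
#' carry no intra-group divergence and are dropped with a notice.
#'
#' @param m A `ped_matrix`.
#' @param labels Tibble with columns `taxon` and a group column (default
#'   `species`), or a named character vector `taxon -> group`.
#' @param group Name of the group column when `labels` is a tibble.
#' @return Tibble `group`, `n`, `max_ped`, sorted by `max_ped`.
#' @export
intra_group_max <- function(m, labels, group = "species") {
  lab <- as_label_vector(labels, group)
  missing <- setdiff(m$taxa, names(lab))
  if (length(missing) > 0L) {
    abort(paste0("Unlabelled taxa: ", paste(head(missing, 5), collapse = ", ")))
  }
  lab <- lab[m$taxa]
  sizes <- table(lab)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    inform(paste0("Dropping ", length(small),
                  " singleton group(s) with no intra-group pairs"))
  }
  keep <- names(sizes)[sizes >= 2L]
  if (length(keep) == 0L) {
    inform("No group has two or more members; intra-group divergence undefined")
    return(tibble(group = character(), n = integer(), max_ped = numeric()))
  }
  out <- purrr::map(keep, function(g) {
    members <- m$taxa[lab == g]
    sub <- m$values[members, members]
    tibble(group = g, n = length(members), max_ped = max(sub[lower.tri(sub)]))
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$max_ped)
}

as_label_vector <- function(labels, group = "species") {
  if (is.data.frame(labels)) {
    stopifnot("taxon" %in% names(labels), group %in% names(labels))
    setNames(as.character(labels[[group]]), labels$taxon)
  } else {
    stopifnot(!is.null(names(labels)))
    labels
  }
}

#' Write a PED matrix to disk
#'
#' @param m A `ped_matrix`.
#' @param path Output path.
#' @param format `"tsv"` (square, with `#` metadata header lines) or
#'   `"phylip"` (square PHYLIP distance matrix).
#' @return `path`, invisibly.
#' @export
write_ped_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "phylip") {
    lines <- c(sprintf("%5d", length(m$taxa)),
               vapply(seq_along(m$taxa), function(i) {
                 paste0(formatC(m$taxa[i], width = -10),
                        paste(sprintf("%.6f", m$values[i, ]), collapse = " "))
               }, character(1)))
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# model: ", m$model),
                 paste0("# gamma_shape: ", m$gamma_shape),
                 paste0("# dataset: ", m$dataset %||% NA)), con)
    df <- as.data.frame(m$values)
    df <- cbind(taxon = m$taxa, df)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Plot the divergence distribution of a PED matrix
#'
#' Histogram of all pairwise distances, the standard display for reading
#' off the separation between intra- and inter-species divergence.
#'
#' @param object A `ped_matrix`.
#' @param bin_width Bin width (substitutions/site).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ped_matrix
#' @export
autoplot.ped_matrix <- function(object, bin_width = 0.01, ...) {
  h <- ped_histogram(object, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lower + bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey30") +
    ggplot2::labs(x = "Pairwise evolutionary distance (subst./site)",
                  y = "Number of virus pairs",
                  title = paste0("PED distribution (", object$model, ")")) +
    ggplot2::theme_minimal()
}
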