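#' Configuration for a hierarchical taxonomy simulation
#'
#' Defines the study conditions for the synthetic benchmark: a set of virus
#' species, each with several isolates, whose intra-species divergence is
#' well separated from inter-species divergence — the bimodal distance
#' structure that threshold-based demarcation assumes. Defaults simulate 5
#' species of 4 isolates with intra-species depth 0.03 and inter-species
#' depth 0.6 substitutions/site across three conserved "domains" of
#' 300/500/250 aa (1,050 columns total), echoing the scale of concatenated
#' replicase-domain datasets.
#'
#' @param n_species Number of species.
#' @param isolates_per_species Isolates (leaves) per species.
#' @param intra_species_depth Expected substitutions/site separating two
#'   isolates of one species; must be positive and smaller than
#'   `inter_species_depth`.
#' @param inter_species_depth Expected substitutions/site separating
#'   isolates of different species.
#' @param domain_lengths Integer vector of domain lengths (aa).
#' @param indel_rate Single-residue deletion events per site per unit branch
#'   length (default 0: no gaps).
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 5L, isolates_per_species = 4L,
                       intra_species_depth = 0.03,
                       inter_species_depth = 0.6,
                       domain_lengths = c(300L, 500L, 250L),
                       indel_rate = 0, seed = 1L) {
  stopifnot(n_species >= 2L, isolates_per_species >= 1L,
            intra_species_depth > 0,
            intra_species_depth < inter_species_depth,
            all(domain_lengths >= 1L), indel_rate >= 0)
  structure(
    list(n_species = as.integer(n_species),
         isolates_per_species = as.integer(isolates_per_species),
         intra_species_depth = intra_species_depth,
         inter_species_depth = inter_species_depth,
         n_domains = length(domain_lengths),
         domain_lengths = as.integer(domain_lengths),
         indel_rate = indel_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate the species tree for a taxonomy simulation
#'
#' Builds a deterministic star-of-stars topology: every species hangs off
#' the root at depth `inter_species_depth / 2`, and every isolate hangs off
#' its species node at depth `intra_species_depth / 2`. Consequently the
#' path length between two isolates of one species is exactly
#' `intra_species_depth`, and between isolates of different species exactly
#' `inter_species_depth` — all pairwise divergences sit at two depths,
#' mirroring the bimodal distance structure the demarcation method assumes.
#'
#' @param cfg A [sim_config()].
#' @return An `ape` `phylo` tree with tips `sp<i>_iso<j>`.
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  stem <- (cfg$inter_species_depth - cfg$intra_species_depth) / 2
  tip <- cfg$intra_species_depth / 2
  species <- vapply(seq_len(cfg$n_species), function(i) {
    tips <- sprintf("sp%02d_iso%02d:%.*f", i,
                    seq_len(cfg$isolates_per_species), 10, tip)
    sprintf("(%s)sp%02d:%.*f", paste(tips, collapse = ","), i, 10, stem)
  }, character(1))
  ape::read.tree(text = paste0("(", paste(species, collapse = ","), ")root;"))
}

# Evolve one character vector along a branch of length t: substitutions are
# a Poisson process at rate 1 per site, each event replacing the residue
# with one of the other 19 uniformly; deletions (if enabled) are a Poisson
# process at indel_rate and are irreversible ('-' stays '-').
mutate_chars <- function(chars, t, indel_rate = 0) {
  live <- chars != "-"
  k <- integer(length(chars))
  k[live] <- rpois(sum(live), t)
  emax <- if (any(live)) max(k) else 0L
  for (e in seq_len(emax)) {
    idx <- which(k >= e)
    cur <- match(chars[idx], AA20)
    step <- sample.int(19L, length(idx), replace = TRUE)
    chars[idx] <- AA20[(cur - 1L + step) %% 20L + 1L]
  }
  if (indel_rate > 0 && any(live)) {
    del <- rpois(sum(live), indel_rate * t) > 0L
    chars[which(live)[del]] <- "-"
  }
  chars
}

#' Evolve domain alignments along a tree
#'
#' Draws a uniform-random root sequence per domain and evolves it along
#' every branch under a 20-state uniform substitution model (rate 1
#' substitution per site per unit branch length, replacements uniform over
#' the 19 other residues). Each domain evolves independently. Because the
#' model is uniform, the expected p-distance between two leaves at total
#' divergence `t` has the closed form
#' `(19/20) * (1 - exp(-20 t / 19))`, which the test suite uses as an
#' oracle. Deletions (single-residue, irreversible) are applied at
#' `cfg$indel_rate`; the true alignment is emitted directly, never
#' re-estimated.
#'
#' @param tree An `ape` `phylo`, e.g. from [simulate_tree()].
#' @param cfg A [sim_config()]; `cfg$seed` seeds the simulation.
#' @return Long tibble `domain`, `taxon`, `seq` of aligned rows (domains
#'   named `dom1`, `dom2`, ...).
#' @export
evolve_alignments <- function(tree, cfg) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  lens <- tree$edge.length[order(tree$edge[, 1L])]
  # preorder: parents always precede children in ape's cladewise numbering
  ord <- order(edges[, 1L])
  out <- purrr::map(seq_len(cfg$n_domains), function(d) {
    L <- cfg$domain_lengths[[d]]
    node_seq <- vector("list", max(tree$edge))
    node_seq[[root]] <- sample(AA20, L, replace = TRUE)
    for (e in ord) {
      parent <- edges[e, 1L]
      child <- edges[e, 2L]
      node_seq[[child]] <- mutate_chars(node_seq[[parent]], lens[[e]],
                                        cfg$indel_rate)
    }
    tibble(domain = paste0("dom", d),
           taxon = tree$tip.label,
           seq = vapply(seq_len(n_tip),
                        function(i) paste(node_seq[[i]], collapse = ""),
                        character(1)))
  })
  dplyr::bind_rows(out)
}

#' Expected p-distance under the uniform 20-state model
#'
#' Closed form for the expected proportion of differing sites between two
#' sequences separated by total branch length `t` under the simulator's
#' substitution model: `(19/20) * (1 - exp(-20 t / 19))`.
#'
#' @param t Total divergence (substitutions/site); vectorised.
#' @return Expected p-distance in `[0, 19/20)`.
#' @export
expected_p_distance <- function(t) {
  (19 / 20) * (1 - exp(-20 * t / 19))
}

#' Ground-truth labels and expected distance gap of a simulation
#'
#' @param cfg A [sim_config()].
#' @param tree The simulated tree (optional; rebuilt from `cfg` if omitted).
#' @return List with `labels` (tibble `taxon`, `species`) and
#'   `expected_gap`, the interval `c(intra, inter)` of expected p-distances
#'   at the two tree depths — every intra-species pair has expectation at
#'   the lower end, every inter-species pair at the upper end.
#' @export
ground_truth <- function(cfg, tree = NULL) {
  tree <- tree %||% simulate_tree(cfg)
  labels <- tibble(
    taxon = tree$tip.label,
    species = sub("_iso\\d+$", "", tree$tip.label)
  )
  gap <- c(intra = expected_p_distance(cfg$intra_species_depth),
           inter = expected_p_distance(cfg$inter_species_depth))
  list(labels = labels, expected_gap = gap)
}

#' Simulate a full synthetic taxonomy
#'
#' Convenience wrapper: tree + evolved domain alignments + ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A `taxonomy_sim` list: `config`, `tree`, `alignments` (long
#'   tibble `domain`, `taxon`, `seq`), `labels`, `expected_gap`.
#' @export
#' @examples
#' sim <- simulate_taxonomy(sim_config(n_species = 2, isolates_per_species = 2,
#'                                     domain_lengths = 50, seed = 7))
#' sim$labels
simulate_taxonomy <- function(cfg = sim_config()) {
  tree <- simulate_tree(cfg)
  aln <- evolve_alignments(tree, cfg)
  truth <- ground_truth(cfg, tree)
  structure(list(config = cfg, tree = tree, alignments = aln,
                 labels = truth$labels, expected_gap = truth$expected_gap),
            class = "taxonomy_sim")
}

#' @export
print.taxonomy_sim <- function(x, ...) {
  cat("Simulated taxonomy: ", x$config$n_species, " species x ",
      x$config$isolates_per_species, " isolates, ",
      x$config$n_domains, " domain(s), ",
      sum(x$config$domain_lengths), " aa total (seed ", x$config$seed, ")\n",
      sep = "")
  cat(sprintf("Expected p-distance gap: intra %.4f, inter %.4f\n",
              x$expected_gap[["intra"]], x$expected_gap[["inter"]]))
  invisible(x)
}

#' Write a simulated taxonomy to disk
#'
#' Writes one aligned FASTA per domain, a labels TSV, the tree in newick
#' format, and a JSON manifest carrying the config and expected distance
#' gap.
#'
#' @param sim A `taxonomy_sim`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_taxonomy_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in unique(sim$alignments$domain)) {
    blk <- sim$alignments[sim$alignments$domain == d, ]
    write_fasta(tibble(id = blk$taxon, seq = blk$seq),
                file.path(out_dir, paste0(d, ".aln.fasta")))
  }
  write.table(sim$labels, file.path(out_dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  jsonlite::write_json(
    list(config = unclass(sim$config),
         expected_gap = as.list(sim$expected_gap)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
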