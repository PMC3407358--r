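test_that("concat_domains concatenates blocks and records spans", {
  a1 <- domain_alignment(c("a", "b", "c", "d"),
                         rep(strrep("M", 10), 4), "3CLpro")
  a2 <- domain_alignment(c("a", "b", "c", "d"),
                         rep(strrep("K", 10), 4), "RdRp")
  cc <- concat_domains(dplyr::bind_rows(a1, a2), name = "D1")
  expect_equal(nrow(cc), 4L)
  expect_equal(nchar(cc$seq[[1]]), 20L)
  spans <- block_spans(cc)
  expect_equal(spans$domain, c("3CLpro", "RdRp"))
  expect_equal(spans$start, c(1L, 11L))
  expect_equal(spans$end, c(10L, 20L))
})

test_that("concat_domains restricts to the common taxa with a warning", {
  a1 <- domain_alignment(c("a", "b", "c"), rep("MMM", 3), "d1")
  a2 <- domain_alignment(c("a", "b"), rep("KKK", 2), "d2")
  expect_warning(cc <- concat_domains(dplyr::bind_rows(a1, a2)), "Dropping")
  expect_equal(cc$taxon, c("a", "b"))
  a3 <- domain_alignment(c("x", "y"), rep("PPP", 2), "d3")
  expect_error(concat_domains(dplyr::bind_rows(a1, a3)), "share no taxa")
  expect_error(concat_domains(a1, domains = c("d1", "missing")),
               "not present")
})

test_that("block spans partition the concatenated columns", {
  a1 <- domain_alignment(c("a", "b"), rep(strrep("A", 7), 2), "x")
  a2 <- domain_alignment(c("a", "b"), rep(strrep("C", 5), 2), "y")
  a3 <- domain_alignment(c("a", "b"), rep(strrep("D", 3), 2), "z")
  cc <- concat_domains(list(a1, a2, a3), domains = c("x", "y", "z"))
  spans <- block_spans(cc)
  expect_equal(spans$start[1], 1L)
  expect_equal(spans$end[nrow(spans)], nchar(cc$seq[[1]]))
  expect_true(all(spans$start[-1] == spans$end[-nrow(spans)] + 1L))
})

test_that("ped matches closed forms for each model", {
  expect_equal(ped("MKVA", "MKVA", "p"), 0)
  expect_equal(ped("MKVA", "MKVA", "poisson"), 0)
  expect_equal(ped("MKVA", "MKVA", "gamma_poisson"), 0)
  # exactly 10% mismatches over 100 columns
  a <- strrep("A", 100)
  b <- paste0(strrep("R", 10), strrep("A", 90))
  expect_equal(ped(a, b, "p"), 0.1)
  expect_equal(ped(a, b, "poisson"), -log(0.9))
  expect_equal(ped(a, b, "poisson"), 0.10536, tolerance = 1e-4)
  expect_equal(ped(a, b, "gamma_poisson", gamma_shape = 1), 1 / 0.9 - 1)
  expect_equal(ped(a, b, "gamma_poisson", gamma_shape = 1), 0.11111,
               tolerance = 1e-4)
})

test_that("pairwise deletion excludes gapped and ambiguous columns", {
  # columns: (M,M) ok match; (-,K) excluded; (X,V) excluded; (A,R) mismatch
  expect_equal(ped("M-XA", "MKVR", "p"), 0.5)
  expect_error(ped("--", "AA", "p"), "No comparable columns")
  expect_error(ped("AAAA", "RRRR", "poisson"), "cannot be Poisson")
  expect_equal(ped("AAAA", "RRRR", "p"), 1)
})

test_that("distance corrections are ordered p <= poisson <= gamma", {
  withr::local_seed(61)
  for (rep in 1:200) {
    len <- 50
    a <- random_aa_string(len)
    b <- random_aa_string(len)
    shape <- stats::runif(1, 0.2, 5)
    p <- ped(a, b, "p")
    if (p >= 1) next
    pois <- ped(a, b, "poisson")
    gam <- ped(a, b, "gamma_poisson", gamma_shape = shape)
    expect_true(p <= pois + 1e-12)
    expect_true(pois <= gam + 1e-12)
    if (p > 0) {
      expect_true(p < pois && pois < gam)
    }
  }
})

test_that("ped_matrix is symmetric with zero diagonal and hand-counted values", {
  aln <- tibble::tibble(taxon = c("a", "b"), seq = c("MKVA", "MKVA"))
  m <- ped_matrix(aln, "p")
  expect_equal(unname(m$values), matrix(0, 2, 2))

  aln3 <- tibble::tibble(taxon = c("a", "b", "c"),
                         seq = c("MKVA", "MRVA", "MRTA"))
  m3 <- ped_matrix(aln3, "p")
  expect_equal(m3$values["a", "b"], 0.25)
  expect_equal(m3$values["a", "c"], 0.5)
  expect_equal(m3$values["b", "c"], 0.25)
  expect_equal(m3$values, t(m3$values))
  expect_equal(unname(diag(m3$values)), rep(0, 3))
  expect_equal(nrow(tidy(m3)), 3L)  # n(n-1)/2 unique pairs
})

test_that("histogram bins are half-open and conserve the pair count", {
  m0 <- make_ped_matrix(3, values = c(0, 0, 0))
  h0 <- ped_histogram(m0, 0.05)
  expect_equal(sum(h0$count), 3L)
  expect_equal(h0$count[[1]], 3L)

  m <- make_ped_matrix(3, values = c(0.1, 0.2, 0.25))
  h <- ped_histogram(m, 0.1)
  expect_equal(h$count, c(0L, 1L, 2L))
  expect_equal(h$bin_lower, c(0, 0.1, 0.2))

  withr::local_seed(7)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    mr <- make_ped_matrix(n)
    expect_equal(sum(ped_histogram(mr, stats::runif(1, 0.01, 0.3))$count),
                 n * (n - 1) / 2)
  }
})

test_that("intra-group maxima come from within-group pairs only", {
  m <- make_ped_matrix(4, values = c(0.1, 0.5, 0.6, 0.55, 0.45, 0.2))
  # one group holding all taxa: global maximum
  all_in <- intra_group_max(m, setNames(rep("g", 4), m$taxa))
  expect_equal(all_in$max_ped, max(m$values))
  # two singleton groups: empty result with a notice
  expect_message(
    none <- intra_group_max(
      m, tibble::tibble(taxon = m$taxa,
                        species = c("s1", "s2", "s3", "s4"))),
    "singleton|undefined")
  expect_equal(nrow(none), 0L)
})

test_that("simulated species maxima sit below the inter-species minimum", {
  sim <- simulate_taxonomy(sim_config(seed = 101))
  m <- ped_matrix(concat_domains(sim$alignments))
  intra <- intra_group_max(m, sim$labels)
  expect_equal(nrow(intra), 5L)
  pairs <- tidy(m)
  lab <- setNames(sim$labels$species, sim$labels$taxon)
  inter_min <- min(pairs$ped[lab[pairs$taxon_a] != lab[pairs$taxon_b]])
  expect_true(all(intra$max_ped < inter_min))
})
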