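test_that("single-linkage partitions are threshold-graph components", {
  m <- make_ped_matrix(4, values = c(0.05, 0.5, 0.55,   # a-b, a-c, a-d
                                     0.52, 0.57,        # b-c, b-d
                                     0.04))             # c-d
  expect_equal(max(single_linkage_partition(m, 0.01)), 4L)  # all singletons
  expect_equal(max(single_linkage_partition(m, 0.6)), 1L)   # one cluster
  two <- single_linkage_partition(m, 0.2)
  expect_equal(max(two), 2L)
  expect_equal(unname(two), c(1L, 1L, 2L, 2L))
})

test_that("partitions agree with a brute-force component oracle", {
  withr::local_seed(71)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    m <- make_ped_matrix(n)
    t <- stats::runif(1)
    expect_true(same_partition(single_linkage_partition(m, t),
                               oracle_components(m$values, t)))
  }
})

test_that("clustering cost is zero exactly when a threshold separates", {
  m <- make_ped_matrix(4, values = c(0.05, 0.5, 0.55, 0.52, 0.57, 0.04))
  expect_equal(clustering_cost(m, 0.2), 0)
  # a single pair at PED 0.5 splits apart below threshold: no violation
  m2 <- make_ped_matrix(2, values = 0.5)
  expect_equal(clustering_cost(m2, 0.3), 0)
  # hand case: distances {0.1, 0.4, 0.45}; oracle confirms every threshold
  m3 <- make_ped_matrix(3, values = c(0.1, 0.4, 0.45))
  for (t in c(0.05, 0.2, 0.42, 0.5)) {
    expect_equal(clustering_cost(m3, t), oracle_cost(m3$values, t))
  }
  # threshold inside the upper cloud does create violations
  expect_gt(clustering_cost(m3, 0.42), 0)
})

test_that("clustering cost matches the exhaustive oracle on random matrices", {
  withr::local_seed(73)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    m <- make_ped_matrix(n)
    t <- stats::runif(1)
    expect_equal(clustering_cost(m, t), oracle_cost(m$values, t))
  }
})

test_that("thresholds land inside the gaps of a two-level hierarchy", {
  withr::local_seed(79)
  # 8 taxa: 4 species of 2, grouped into 2 genera
  vals <- matrix(0, 8, 8)
  species <- rep(1:4, each = 2)
  genus <- rep(1:2, each = 4)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      d <- if (species[i] == species[j]) stats::runif(1, 0.01, 0.04)
           else if (genus[i] == genus[j]) stats::runif(1, 0.25, 0.35)
           else stats::runif(1, 0.7, 0.9)
      vals[i, j] <- vals[j, i] <- d
    }
  }
  m <- make_ped_matrix(8, values = vals[lower.tri(vals)])
  dem <- find_thresholds(m, n_levels = 2)
  expect_length(dem$thresholds, 2L)
  expect_true(dem$thresholds[1] > 0.04 && dem$thresholds[1] < 0.25)
  expect_true(dem$thresholds[2] > 0.35 && dem$thresholds[2] < 0.7)
  expect_true(same_partition(dem$partitions[[1]], species))
  expect_true(same_partition(dem$partitions[[2]], genus))
  # the finer partition is nested in the coarser
  expect_true(refines(dem$partitions[[1]], dem$partitions[[2]]))
  expect_equal(glance(dem)$n_levels, 2L)
})

test_that("degenerate distance structures warn instead of inventing cutoffs", {
  flat <- make_ped_matrix(4, values = rep(0.3, 6))
  expect_warning(dem <- find_thresholds(flat), "no informative|Only")
  expect_length(dem$thresholds, 0L)
  expect_equal(nrow(tidy(dem)), 0L)
  duo <- make_ped_matrix(2, values = 0.2)
  expect_warning(dem2 <- find_thresholds(duo), "no informative|Only")
  expect_length(dem2$thresholds, 0L)
})

test_that("lower thresholds refine higher ones on random matrices", {
  withr::local_seed(83)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    m <- make_ped_matrix(n)
    ts <- sort(stats::runif(2))
    finer <- single_linkage_partition(m, ts[1])
    coarser <- single_linkage_partition(m, ts[2])
    expect_true(refines(finer, coarser))
  }
})

test_that("pair classification agrees with simulated ground truth", {
  sim <- simulate_taxonomy(sim_config(seed = 103))
  m <- ped_matrix(concat_domains(sim$alignments))

  # a taxon against itself: distance zero, conspecific under any criterion
  self <- classify_pair(m, "sp01_iso01", "sp01_iso01", labels = sim$labels)
  expect_equal(self$ped, 0)
  expect_true(self$same_group)

  intra <- classify_pair(m, "sp01_iso01", "sp01_iso02", labels = sim$labels)
  expect_true(intra$same_group)
  expect_equal(intra$criterion, "intra_species_max")
  inter <- classify_pair(m, "sp01_iso01", "sp02_iso01", labels = sim$labels)
  expect_false(inter$same_group)

  dem <- find_thresholds(m)
  v <- classify_pair(m, "sp01_iso01", "sp01_iso02", thresholds = dem)
  expect_true(v$same_group)
  expect_equal(v$criterion, "threshold_level_1")
  expect_false(classify_pair(m, "sp01_iso01", "sp03_iso01",
                             thresholds = dem)$same_group)

  expect_error(classify_pair(m, "sp01_iso01", "nope", labels = sim$labels),
               "not in distance matrix")
  expect_error(classify_pair(m, "sp01_iso01", "sp01_iso02"),
               "labels.*thresholds|thresholds")
})
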