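test_that("identical sequences align without gaps at 100% identity", {
  aln <- global_align("MAKVLT", "MAKVLT", "aa")
  expect_equal(aln$aligned_a, "MAKVLT")
  expect_equal(aln$aligned_b, "MAKVLT")
  expect_equal(percent_identity(aln), 100)
})

test_that("a single deletion yields one gap column with the optimal score", {
  aln <- global_align("ACGT", "AGT", "nt")
  expect_equal(nchar(aln$aligned_a), 4L)
  expect_equal(lengths(regmatches(aln$aligned_b,
                                  gregexpr("-", aln$aligned_b))), 1L)
  submat <- nidotax:::nt_substitution_matrix(c("A", "C", "G", "T"))
  expect_equal(aln$score, oracle_affine_score("ACGT", "AGT", submat, 5, 2))
  # removing gaps recovers the inputs
  expect_equal(gsub("-", "", aln$aligned_a), "ACGT")
  expect_equal(gsub("-", "", aln$aligned_b), "AGT")
})

test_that("one substitution in three residues gives 2/3 matched columns", {
  aln <- global_align("MKV", "MRV", "aa")
  expect_equal(nchar(aln$aligned_a), 3L)
  expect_equal(percent_identity(aln), 100 * 2 / 3)
})

test_that("alignment scores equal the quadratic-space DP oracle", {
  withr::local_seed(41)
  for (rep in 1:20) {
    a <- random_aa_string(sample(5:50, 1))
    b <- random_aa_string(sample(5:50, 1))
    aln <- global_align(a, b, "aa")
    expect_equal(aln$score, oracle_affine_score(a, b, blosum62, 11, 1))
  }
  submat <- nidotax:::nt_substitution_matrix(c("A", "C", "G", "T"))
  for (rep in 1:20) {
    a <- random_nt_string(sample(5:50, 1))
    b <- random_nt_string(sample(5:50, 1))
    aln <- global_align(a, b, "nt")
    expect_equal(aln$score, oracle_affine_score(a, b, submat, 5, 2))
  }
})

test_that("identity conventions differ only through gap columns", {
  aln <- list(aligned_a = "AC-T", aligned_b = "ACGT")
  expect_equal(percent_identity(aln, "excl_gaps"), 100)
  expect_equal(percent_identity(aln, "aligned_columns"), 75)
  expect_error(percent_identity(list(aligned_a = "--", aligned_b = "A-"),
                                "excl_gaps"), "zero-column")
})

test_that("percent identity is symmetric", {
  withr::local_seed(43)
  for (rep in 1:10) {
    a <- random_aa_string(30)
    b <- random_aa_string(25)
    expect_equal(percent_identity(global_align(a, b, "aa")),
                 percent_identity(global_align(b, a, "aa")))
  }
})

test_that("identity degrades monotonically with added mutations, on average", {
  withr::local_seed(47)
  base <- random_aa_string(100)
  aa <- strsplit(base, "")[[1]]
  mean_identity <- function(k, reps = 100) {
    mean(vapply(seq_len(reps), function(r) {
      mut <- aa
      idx <- sample(100, k)
      mut[idx] <- vapply(mut[idx], function(x) {
        sample(setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                       x), 1)
      }, character(1))
      percent_identity(global_align(base, paste(mut, collapse = ""), "aa"))
    }, numeric(1)))
  }
  ms <- vapply(c(5, 15, 30), mean_identity, numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("orf_table reports identities and frames for a genome pair", {
  # a two-ORF genome compared against itself: everything identical
  g <- paste0("AA", "ATGGCTGCTGCTGCTTAA", "C", "ATGAAAAAAAAATAG")
  pairs <- tibble::tibble(
    orf_name = c("ORF1", "ORF2"),
    start_a = c(3L, 22L), end_a = c(20L, 36L),
    start_b = c(3L, 22L), end_b = c(20L, 36L),
    product = c("polyprotein", "nucleocapsid")
  )
  tab <- orf_table(g, g, pairs)
  expect_equal(tab$identity_nt, c(100, 100))
  expect_equal(tab$identity_aa, c(100, 100))
  expect_equal(tab$frame_a, tab$frame_b)
  expect_equal(tab$frame_a[[1]], 0L)
  expect_equal(tab$product, c("polyprotein", "nucleocapsid"))
})

test_that("orf_table recovers a planted amino-acid divergence", {
  withr::local_seed(53)
  # build an ORF from 200 random codons plus a stop; mutate 10% of residues
  aa_letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  codon_of <- vapply(aa_letters, function(x) {
    names(Biostrings::GENETIC_CODE)[match(x, Biostrings::GENETIC_CODE)]
  }, character(1))
  prot_a <- sample(aa_letters, 200, replace = TRUE)
  prot_b <- prot_a
  idx <- sample(200, 20)
  prot_b[idx] <- vapply(prot_b[idx],
                        function(x) sample(setdiff(aa_letters, x), 1),
                        character(1))
  orf_a <- paste0(paste(codon_of[prot_a], collapse = ""), "TAA")
  orf_b <- paste0(paste(codon_of[prot_b], collapse = ""), "TAA")
  tab <- orf_table(orf_a, orf_b, tibble::tibble(
    orf_name = "planted", start_a = 1L, end_a = nchar(orf_a),
    start_b = 1L, end_b = nchar(orf_b)))
  expect_true(abs(tab$identity_aa - 90) <= 2)
})
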