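# Independent oracles, deliberately naive: brute-force enumeration and
# textbook DP, never sharing code with the implementation under test.

# Gotoh affine-gap global alignment score; a gap of length L costs
# open + L * extend (the convention of global_align()).
oracle_affine_score <- function(a, b, submat, open, extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in A (consume B)
  F <- matrix(NEG, n + 1, m + 1)  # gap in B (consume A)
  M[1, 1] <- 0
  for (j in seq_len(m)) E[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) F[i + 1, 1] <- -(open + i * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], E[i, j], F[i, j]) + s
      E[i + 1, j + 1] <- max(E[i + 1, j] - extend,
                             max(M[i + 1, j], F[i + 1, j]) - open - extend)
      F[i + 1, j + 1] <- max(F[i, j + 1] - extend,
                             max(M[i, j + 1], E[i, j + 1]) - open - extend)
    }
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# exhaustive ORF scan: every ATG, walk codon by codon to the first stop
oracle_orfs <- function(seq, min_len) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (i in seq_len(max(0, n - 2))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i
    while (j + 2 <= n) {
      if (substr(seq, j, j + 2) %in% stops) {
        if (j + 2 - i + 1 >= min_len) {
          hits[[length(hits) + 1]] <- c(start = i, end = j + 2)
        }
        break
      }
      j <- j + 3
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  df <- as.data.frame(do.call(rbind, hits))
  df[order(df$start, df$end), , drop = FALSE]
}

# drop nested same-stop ORFs, keeping the longest per (frame, stop)
oracle_longest_per_stop <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$end, (df$start - 1) %% 3)
  keep <- !duplicated(key)  # df sorted by start: first = longest
  df[keep, , drop = FALSE]
}

# connected components of the graph joining pairs with d <= t (BFS)
oracle_components <- function(d, t) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(d[v, ] <= t & is.na(comp) & seq_len(n) != v)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# clustering cost from first principles: enumerate all pairs
oracle_cost <- function(d, t) {
  comp <- oracle_components(d, t)
  total <- 0
  n <- nrow(d)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (comp[i] == comp[j]) {
        total <- total + max(0, d[i, j] - t)
      } else {
        total <- total + max(0, t - d[i, j])
      }
    }
  }
  total
}

# a ped_matrix with given (or random uniform) off-diagonal values
make_ped_matrix <- function(n, values = NULL, model = "p") {
  taxa <- sprintf("t%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  values <- values %||% stats::runif(n * (n - 1) / 2)
  d[lower.tri(d)] <- values
  d <- d + t(d)
  structure(list(taxa = taxa, values = d, model = model,
                 gamma_shape = NA_real_, dataset = NULL),
            class = "ped_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# are two cluster assignments the same partition (up to label names)?
same_partition <- function(p, q) {
  stopifnot(length(p) == length(q))
  all(outer(p, p, "==") == outer(q, q, "=="))
}

# does every cluster of the finer partition lie inside one coarser cluster?
refines <- function(finer, coarser) {
  all(tapply(coarser, finer, function(x) length(unique(x)) == 1))
}

random_aa_string <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

random_nt_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
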