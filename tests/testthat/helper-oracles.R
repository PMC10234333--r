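# Independent plain-R oracles used to cross-check the package's
# implementations. These deliberately share no code with the package
# internals: the Smith-Waterman below is a direct textbook DP, the MCL a
# literal matrix iteration, and the average-linkage clustering a naive
# agglomeration.

# Textbook affine-gap local alignment (match/mismatch scoring). Returns the
# best score with match/column counts and the aligned query span.
oracle_sw <- function(q, s, match = 1, mismatch = -1, gap_open = 5,
                      gap_ext = 2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  ptr <- array(0L, c(n + 1, m + 1, 3))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      ptr[i, j, 2] <- if (M[i - 1, j] - gap_open - gap_ext >=
                          X[i - 1, j] - gap_ext) 1L else 2L
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      ptr[i, j, 3] <- if (M[i, j - 1] - gap_open - gap_ext >=
                          Y[i, j - 1] - gap_ext) 1L else 2L
      sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N") match else mismatch
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0)
      k <- which.max(prev)
      M[i, j] <- max(prev[k] + sub, 0)
      ptr[i, j, 1] <- if (prev[k] <= 0) 0L else k
    }
  }
  best <- unname(which(M == max(M), arr.ind = TRUE)[1, ])
  score <- M[best[1], best[2]]
  # traceback for counts
  i <- best[1]; j <- best[2]; state <- 1L
  matches <- cols <- 0L; qend <- i - 1; qstart <- i - 1
  while (i > 1 && j > 1) {
    if (state == 1L) {
      if (M[i, j] <= 0) break
      cols <- cols + 1L
      if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N")
        matches <- matches + 1L
      p <- ptr[i, j, 1]
      i <- i - 1; j <- j - 1
      qstart <- i
      if (p == 0L || p == 4L) break
      state <- if (p == 1L) 1L else if (p == 2L) 2L else 3L
    } else if (state == 2L) {
      cols <- cols + 1L
      p <- ptr[i, j, 2]; i <- i - 1
      state <- if (p == 1L) 1L else 2L
    } else {
      cols <- cols + 1L
      p <- ptr[i, j, 3]; j <- j - 1
      state <- if (p == 1L) 1L else 3L
    }
  }
  list(score = score, matches = matches, cols = cols,
       q_span = qend - qstart + 1)
}

# Literal Markov-clustering iteration on a weighted adjacency matrix.
oracle_mcl <- function(adj, inflation, prune = 1e-5, tol = 1e-6,
                       max_iter = 100) {
  n <- nrow(adj)
  for (i in seq_len(n)) adj[i, i] <- max(adj[, i])
  M <- adj
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    E <- E^inflation
    E[E < prune] <- 0
    for (j in seq_len(n)) {
      cs <- sum(E[, j])
      if (cs > 0) E[, j] <- E[, j] / cs
    }
    if (max(abs(E - M)) < tol) { M <- E; break }
    M <- E
  }
  keep <- (M > prune) | (t(M) > prune)
  # connected components by BFS
  comp <- rep(0L, n); cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cid
      queue <- c(queue, which(keep[u, ] & comp == 0))
    }
  }
  split(seq_len(n), comp)
}

# Naive agglomerative average-linkage clustering returning the cophenetic
# (merge-height) matrix.
oracle_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dd <- d
  coph <- matrix(0, n, n)
  while (length(active) > 1) {
    k <- length(active)
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      if (dd[i, j] < best[1]) best <- c(dd[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    for (a in active[[i]]) for (b in active[[j]])
      coph[a, b] <- coph[b, a] <- best[1]
    merged <- c(active[[i]], active[[j]])
    # average linkage on original pairwise distances
    newd <- sapply(seq_len(k)[-c(i, j)], function(t)
      mean(d[merged, active[[t]], drop = FALSE]))
    keep <- seq_len(k)[-c(i, j)]
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], newd), c(newd, 0))
    active <- c(active[keep], list(merged))
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# Enumerate COG triangles by brute force from a BBH edge list.
oracle_triangles <- function(edges, genome_of) {
  prots <- sort(unique(c(edges$a, edges$b)))
  has_edge <- function(u, v)
    any((edges$a == u & edges$b == v) | (edges$a == v & edges$b == u))
  tris <- list()
  if (length(prots) < 3) return(tris)
  for (cmb in asplit(combn(prots, 3), 2)) {
    v <- as.character(cmb)
    if (length(unique(genome_of[v])) == 3 &&
        has_edge(v[1], v[2]) && has_edge(v[1], v[3]) &&
        has_edge(v[2], v[3]))
      tris[[length(tris) + 1]] <- sort(v)
  }
  tris
}

# Build a synthetic hits table (the all_vs_all_hits format) from an edge
# list with scores; emits both directions.
make_hits <- function(a, b, genome_a, genome_b, score,
                      identity = 90, coverage = 0.9) {
  one <- data.frame(query_id = a, subject_id = b, query_genome = genome_a,
                    subject_genome = genome_b, identity_pct = identity,
                    coverage_of_longest = coverage, score = score,
                    stringsAsFactors = FALSE)
  two <- data.frame(query_id = b, subject_id = a, query_genome = genome_b,
                    subject_genome = genome_a, identity_pct = identity,
                    coverage_of_longest = coverage, score = score,
                    stringsAsFactors = FALSE)
  rbind(one, two)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_aa_seq <- function(n)
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n,
               replace = TRUE), collapse = "")

# Mutate exactly k positions of a sequence (substitutions to a different
# base/residue), returning the mutated string.
mutate_exact <- function(seq, k, alphabet = c("A", "C", "G", "T"),
                         at = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(at)) at <- sample(length(chars), k)
  for (i in at) chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  paste(chars, collapse = "")
}
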