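test_that("Jukes-Cantor distances follow the closed form and its domain", {
  aln <- multiple_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(unname(jc_distance(aln)["a", "b"]), 0)

  # p = 0.10 over 100 columns
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  d <- jc_distance(multiple_alignment(c(a = a, b = b)))
  expect_equal(unname(d["a", "b"]), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-10)

  # gap and N columns are excluded pairwise
  d2 <- jc_distance(multiple_alignment(c(a = "ACGT-NAC", b = "ACGTTTAC")))
  expect_equal(unname(d2["a", "b"]), 0)

  # p >= 0.75 is out of the model's domain
  sat <- multiple_alignment(c(a = strrep("A", 100),
                              b = paste0(strrep("C", 75), strrep("A", 25))))
  expect_error(jc_distance(sat), "0.75")
  expect_error(jc_distance(multiple_alignment(c(a = "----", b = "AAAA"))),
               "comparable")
})

test_that("neighbor joining is exact on a known additive 4-taxon matrix", {
  # tree ((A:1,B:2):5,(C:3,D:4)) -> additive distances
  d <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]], d)
  # pendant branch lengths recovered exactly
  tip_edges <- tree$edge[, 2] <= 4
  pend <- setNames(tree$edge.length[tip_edges],
                   tree$tip.label[tree$edge[tip_edges, 2]])
  expect_equal(pend[LETTERS[1:4]],
               c(A = 1, B = 2, C = 3, D = 4))
  expect_error(neighbor_joining(d[1:2, 1:2]), "three")
})

test_that("three equidistant taxa resolve with equal pendant lengths", {
  d <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(d) <- 0
  tree <- neighbor_joining(d)
  expect_equal(sort(tree$edge.length), c(1, 1, 1))
})

test_that("NJ inverts tree-to-distance conversion on random binary trees", {
  set.seed(271)
  for (trial in 1:10) {
    nt <- sample(4:10, 1)
    true_tree <- ape::rtree(nt)
    d <- ape::cophenetic.phylo(true_tree)
    nj <- neighbor_joining(d)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("bootstrap supports are reproducible and certain for clear splits", {
  set.seed(277)
  base <- random_dna(300)
  twin <- mutate_exact(base, 1)            # nearly identical sister
  far_anc <- mutate_exact(base, 90)        # distant clade ancestor
  far1 <- mutate_exact(far_anc, 10)
  far2 <- mutate_exact(far_anc, 12)
  far3 <- mutate_exact(far_anc, 14)
  aln <- multiple_alignment(c(t1 = base, t2 = twin, f1 = far1, f2 = far2,
                              f3 = far3))
  tr <- suppressWarnings(bootstrap_support(aln, n_replicates = 100, seed = 31))
  tr2 <- suppressWarnings(bootstrap_support(aln, n_replicates = 100, seed = 31))
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # the identical pair t1/t2 must be supported in every replicate: find the
  # internal node realizing that bipartition (either side of the split)
  ntip <- ape::Ntip(tr)
  split_node <- NA
  for (nd in (ntip + 1):(ntip + tr$Nnode)) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    if (setequal(tips, c("t1", "t2")) ||
        setequal(tips, c("f1", "f2", "f3"))) split_node <- nd
  }
  expect_false(is.na(split_node))
  expect_equal(as.numeric(tr$node.label[split_node - ntip]), 100)
})

test_that("bootstrap supports match a direct re-implementation on the same RNG stream", {
  set.seed(283)
  seqs <- c(a = random_dna(200))
  seqs["b"] <- mutate_exact(seqs["a"], 10)
  seqs["c"] <- mutate_exact(seqs["a"], 60)
  seqs["d"] <- mutate_exact(seqs["c"], 12)
  seqs["e"] <- mutate_exact(seqs["a"], 70)
  aln <- multiple_alignment(seqs)
  tr <- suppressWarnings(bootstrap_support(aln, n_replicates = 60, seed = 41))
  # independent recomputation: same resampling stream, ape machinery
  chars <- do.call(rbind, strsplit(aln$seqs, ""))
  main <- suppressWarnings(neighbor_joining(jc_distance(aln)))
  reps <- local({
    old <- .Random.seed
    on.exit(.Random.seed <<- old)
    set.seed(41)
    out <- list()
    for (i in 1:60) {
      cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
      b <- apply(chars[, cols], 1, paste, collapse = "")
      out[[i]] <- suppressWarnings(
        neighbor_joining(jc_distance(multiple_alignment(b))))
    }
    out
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  expect_equal(as.numeric(tr$node.label), round(100 * counts / 60, 1))
})

test_that("alignment trimming drops gappy and unconserved columns in short runs", {
  same <- multiple_alignment(c(a = strrep("ACGT", 5), b = strrep("ACGT", 5)))
  expect_equal(trim_alignment(same)$seqs, same$seqs)

  # a 60 % gap column is removed
  aln <- multiple_alignment(c(s1 = paste0(strrep("A", 10), "-"),
                              s2 = paste0(strrep("A", 10), "-"),
                              s3 = paste0(strrep("A", 10), "-"),
                              s4 = paste0(strrep("A", 10), "A"),
                              s5 = paste0(strrep("A", 10), "A")))
  tr <- trim_alignment(aln, min_block_length = 1)
  expect_equal(attr(tr, "kept_columns"), 1:10)

  # planted clean block between noisy flanks
  set.seed(293)
  n_seq <- 6
  flank <- function(w) replicate(n_seq, paste(
    sample(c("A", "C", "G", "T", "-", "-", "-"), w, replace = TRUE),
    collapse = ""))
  block <- strrep("ACGTG", 4)  # 20 conserved columns
  seqs <- paste0(flank(7), block, flank(7))
  aln2 <- multiple_alignment(setNames(seqs, paste0("s", 1:n_seq)))
  tr2 <- trim_alignment(aln2, min_block_length = 5)
  expect_true(all(attr(tr2, "kept_columns") %in% 8:27))
  expect_true(all(8:27 %in% attr(tr2, "kept_columns")))

  tiny <- multiple_alignment(c(a = "----", b = "ACGT"))
  expect_error(trim_alignment(tiny), "every column")
})

test_that("concatenation sums columns, keeps a partition map, and preserves NJ topology", {
  set.seed(307)
  taxa <- paste0("t", 1:5)
  mk_aln <- function(ncol) {
    base <- random_dna(ncol)
    seqs <- c(base, vapply(2:5, function(i)
      mutate_exact(base, max(1, round(ncol * 0.05 * i))), ""))
    multiple_alignment(setNames(seqs, taxa))
  }
  a1 <- mk_aln(100); a2 <- mk_aln(100); a3 <- mk_aln(80)
  cc <- concatenate_alignments(list(a1, a2))
  expect_equal(cc$n_columns, 200)
  expect_equal(attr(cc, "partition_map")$end, c(100, 200))

  bad <- multiple_alignment(setNames(rep("ACGT", 5),
                                     c(taxa[1:4], "other")))
  expect_error(concatenate_alignments(list(a1, bad)), "other")

  t123 <- suppressWarnings(neighbor_joining(jc_distance(
    concatenate_alignments(list(a1, a2, a3)))))
  t321 <- suppressWarnings(neighbor_joining(jc_distance(
    concatenate_alignments(list(a3, a2, a1)))))
  expect_true(ape::all.equal.phylo(ape::unroot(t123), ape::unroot(t321),
                                   use.edge.length = FALSE))
})

test_that("trimmed output columns are a subset of input columns", {
  set.seed(311)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T", "-"), 60,
                                    replace = TRUE, prob = c(.3, .3, .2, .1, .1)),
                             collapse = ""))
  aln <- multiple_alignment(setNames(seqs, paste0("q", 1:5)))
  tr <- tryCatch(trim_alignment(aln, min_block_length = 2),
                 error = function(e) NULL)
  if (!is.null(tr)) {
    kept <- attr(tr, "kept_columns")
    chars_in <- do.call(rbind, strsplit(aln$seqs, ""))
    chars_out <- do.call(rbind, strsplit(tr$seqs, ""))
    expect_equal(chars_out, chars_in[, kept], ignore_attr = TRUE)
  } else succeed()
})
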