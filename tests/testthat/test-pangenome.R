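test_that("all-vs-all hits apply the 70/70 rule", {
  set.seed(101)
  base <- random_aa_seq(250)
  p1 <- proteome("gA", c(a1 = base))
  p2 <- proteome("gB", c(b1 = base))
  hits <- all_vs_all_hits(list(p1, p2))
  expect_equal(nrow(hits), 2)  # both directions
  expect_equal(hits$identity_pct[1], 100)
  expect_equal(hits$coverage_of_longest[1], 1.0)

  # ~55 % identity, full coverage: identity filter rejects
  far <- mutate_exact(base, 150, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV",
                                                     "")[[1]])
  hits2 <- all_vs_all_hits(list(proteome("gA", c(a1 = base)),
                                proteome("gB", c(b1 = far))),
                           prefilter = FALSE)
  expect_equal(nrow(hits2), 0)

  # identical half, but alignment covers only 50 % of the longer sequence
  half <- substr(base, 1, 125)
  hits3 <- all_vs_all_hits(list(proteome("gA", c(a1 = base)),
                                proteome("gB", c(b1 = half))),
                           prefilter = FALSE)
  expect_equal(nrow(hits3), 0)

  expect_error(all_vs_all_hits(list(p1)), "at least two")
})

test_that("BDBH builds one cluster per reference protein from mutual best hits", {
  set.seed(103)
  sim <- simulate_proteomes(n_genomes = 3, n_families = 6,
                            within_identity = 0.9, seed = 17)
  hits <- all_vs_all_hits(sim$proteomes)
  gids <- vapply(sim$proteomes, `[[`, "", "genome_id")
  cl <- bdbh_cluster(hits, sim$proteomes, gids[1])
  expect_length(cl, 6)
  expect_true(all(vapply(cl, function(x) nrow(x$members), 0L) == 3))
  # every cluster is one whole true family
  fams <- lapply(cl, function(x)
    unique(unname(sim$truth$family_of[x$members$protein])))
  expect_true(all(lengths(fams) == 1))
  expect_error(bdbh_cluster(hits, sim$proteomes, "nope"), "reference")
})

test_that("COG triangles form, merge on shared edges, and need closure", {
  gof <- c(a = "g1", b = "g2", c = "g3", d = "g4")
  # one family in three genomes, all mutual BBHs -> one triangle
  h3 <- make_hits(c("a", "a", "b"), c("b", "c", "c"),
                  gof[c("a", "a", "b")], gof[c("b", "c", "c")],
                  score = c(50, 40, 45))
  cl <- cog_triangles_cluster(h3)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members$protein, c("a", "b", "c"))

  # two triangles sharing the a-b edge merge into one 4-member cluster
  h4 <- make_hits(c("a", "a", "b", "a", "b"), c("b", "c", "c", "d", "d"),
                  gof[c("a", "a", "b", "a", "b")],
                  gof[c("b", "c", "c", "d", "d")], score = 50)
  cl4 <- cog_triangles_cluster(h4)
  expect_length(cl4, 1)
  expect_setequal(cl4[[1]]$members$protein, c("a", "b", "c", "d"))

  # bipartite-only BBHs close no triangle
  hbip <- make_hits(c("a", "b"), c("c", "d"), c("g1", "g1"), c("g2", "g2"),
                    score = 50)
  hbip <- rbind(hbip, make_hits("a", "d2", "g1", "g3", score = 10))
  expect_length(cog_triangles_cluster(hbip), 0)

  expect_error(cog_triangles_cluster(make_hits("a", "b", "g1", "g2", 50)),
               "three genomes")
})

test_that("COG triangles agree with brute-force triangle enumeration", {
  set.seed(107)
  for (trial in 1:5) {
    n_genomes <- 4
    prots <- paste0("p", 1:10)
    gof <- setNames(sample(paste0("g", 1:n_genomes), 10, replace = TRUE),
                    prots)
    pairs <- t(combn(prots, 2))
    keep <- gof[pairs[, 1]] != gof[pairs[, 2]] & runif(nrow(pairs)) < 0.4
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0) next
    # make every edge a mutual best hit by keeping at most one edge per
    # (protein, other-genome) pair
    seen <- character(); take <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      k1 <- paste(pairs[r, 1], gof[pairs[r, 2]])
      k2 <- paste(pairs[r, 2], gof[pairs[r, 1]])
      if (!(k1 %in% seen) && !(k2 %in% seen)) {
        take[r] <- TRUE
        seen <- c(seen, k1, k2)
      }
    }
    pairs <- pairs[take, , drop = FALSE]
    hits <- make_hits(pairs[, 1], pairs[, 2], gof[pairs[, 1]],
                      gof[pairs[, 2]], score = 50)
    cl <- cog_triangles_cluster(hits)
    tris <- oracle_triangles(data.frame(a = pairs[, 1], b = pairs[, 2]),
                             gof)
    in_cluster <- unique(unlist(lapply(cl, function(x) x$members$protein)))
    in_triangle <- unique(unlist(tris))
    expect_setequal(as.character(in_cluster), as.character(in_triangle))
  }
})

test_that("Markov clustering separates components and matches the oracle", {
  # two disconnected cliques
  cliq <- rbind(make_hits(c("a", "a", "b"), c("b", "c", "c"),
                          c("g1", "g1", "g2"), c("g2", "g3", "g3"), 40),
                make_hits(c("x", "x", "y"), c("y", "z", "z"),
                          c("g1", "g1", "g2"), c("g2", "g3", "g3"), 40))
  cl <- omcl_cluster(cliq)
  expect_length(cl, 2)
  expect_setequal(lapply(cl, function(x) sort(x$members$protein)),
                  list(c("a", "b", "c"), c("x", "y", "z")))

  # 5-node path graph vs literal MCL iteration
  path_prots <- paste0("n", 1:5)
  ph <- make_hits(path_prots[1:4], path_prots[2:5],
                  paste0("g", 1:4), paste0("g", 2:5), score = 30)
  cl_path <- omcl_cluster(ph, inflation = 1.5)
  adj <- matrix(0, 5, 5, dimnames = list(path_prots, path_prots))
  for (i in 1:4) adj[i, i + 1] <- adj[i + 1, i] <- 30
  oracle <- oracle_mcl(adj, inflation = 1.5)
  oracle_sets <- lapply(oracle, function(ix) sort(path_prots[ix]))
  got_sets <- lapply(cl_path, function(x) sort(x$members$protein))
  expect_setequal(got_sets, oracle_sets)

  expect_error(omcl_cluster(ph, inflation = 1), "> 1")
})

test_that("higher inflation never yields fewer Markov clusters", {
  set.seed(109)
  for (trial in 1:20) {
    n <- sample(5:9, 1)
    prots <- paste0("p", seq_len(n))
    pairs <- t(combn(prots, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (sum(keep) < 2) next
    pairs <- pairs[keep, , drop = FALSE]
    hits <- make_hits(pairs[, 1], pairs[, 2],
                      paste0("g_", pairs[, 1]), paste0("g_", pairs[, 2]),
                      score = round(runif(nrow(pairs), 20, 60)))
    n_low <- length(omcl_cluster(hits, inflation = 1.2))
    n_high <- length(omcl_cluster(hits, inflation = 5))
    expect_gte(n_high, n_low)
  }
})

test_that("all three algorithms recover separated families; consensus keeps single-copy", {
  sim <- simulate_proteomes(n_genomes = 5, n_families = 10,
                            within_identity = 0.9, seed = 211)
  hits <- all_vs_all_hits(sim$proteomes)
  gids <- vapply(sim$proteomes, `[[`, "", "genome_id")
  truth_sets <- split(names(sim$truth$family_of), sim$truth$family_of)
  truth_sets <- lapply(truth_sets, sort)
  for (cl in list(bdbh_cluster(hits, sim$proteomes, gids[1]),
                  cog_triangles_cluster(hits), omcl_cluster(hits))) {
    got <- lapply(cl, function(x) sort(x$members$protein))
    expect_setequal(got, unname(truth_sets))
  }
})

test_that("consensus core excludes disagreements and multi-copy families", {
  # five multi-copy families among 50 drop out of the strict consensus
  sim <- simulate_proteomes(n_genomes = 4, n_families = 20,
                            within_identity = 0.9,
                            copy_number = rep(c(2L, 1L), c(3, 17)),
                            seed = 223)
  hits <- all_vs_all_hits(sim$proteomes)
  gids <- vapply(sim$proteomes, `[[`, "", "genome_id")
  bd <- bdbh_cluster(hits, sim$proteomes, gids[1])
  ct <- cog_triangles_cluster(hits)
  om <- omcl_cluster(hits)
  core <- consensus_core(bd, ct, om, gids)
  expect_lte(length(core), 17)
  fams <- unique(unlist(lapply(core, function(x)
    unname(sim$truth$family_of[x$members$protein]))))
  # no multi-copy family survives the single-copy rule
  expect_false(any(fams %in% c("fam001", "fam002", "fam003")))
  counts <- vapply(core, function(x) nrow(x$members), 0L)
  expect_true(all(counts == 4))
})

test_that("compartment labels follow the core/soft-core/shell/cloud rules", {
  occ11 <- matrix(1L, 1, 11)
  pm <- pangenome_matrix(occ11)
  expect_equal(unname(pm$compartments), "core")

  occ <- matrix(0L, 3, 103)
  occ[1, 1:2] <- 1L        # cloud (2 genomes)
  occ[2, 1:99] <- 1L       # soft-core (96.1 %)
  occ[3, 1:50] <- 1L       # shell
  pm <- pangenome_matrix(occ)
  expect_equal(unname(pm$compartments), c("cloud", "soft-core", "shell"))
  tab <- table(pm$compartments)
  expect_equal(sum(tab), nrow(occ))
})

test_that("pan-genes are exactly the in-group-exclusive clusters", {
  genomes <- paste0("g", 1:10)
  occ <- matrix(0L, 4, 10, dimnames = list(paste0("c", 1:4), genomes))
  occ[1, 1:5] <- 1L               # all ingroup, no outgroup -> pan-gene
  occ[2, c(1:5, 6)] <- 1L         # leaks into outgroup
  occ[3, 1:4] <- 1L               # misses one ingroup genome
  occ[4, ] <- 1L                  # core
  pm <- pangenome_matrix(occ)
  pg <- pan_genes(pm, ingroup = genomes[1:5], outgroup = genomes[6:10])
  expect_equal(as.character(pg), "c1")
  # invariant under permutation of genome order
  pg2 <- pan_genes(pm, ingroup = rev(genomes[1:5]),
                   outgroup = sample(genomes[6:10]))
  expect_equal(as.character(pg2), "c1")
  expect_error(pan_genes(pm, genomes[1:5], genomes[5:10]), "overlap")
  expect_error(pan_genes(pm, character(), genomes[6:10]), "non-empty")
})

test_that("planted in-group exclusive families are recovered end to end", {
  n_in <- 6; n_out <- 5; n_excl <- 8; n_shared <- 6
  presence <- rbind(
    matrix(rep(c(1L, 0L), c(n_in, n_out)), n_excl, n_in + n_out,
           byrow = TRUE),
    matrix(1L, n_shared, n_in + n_out))
  sim <- simulate_proteomes(n_genomes = n_in + n_out,
                            n_families = n_excl + n_shared,
                            within_identity = 0.9, presence = presence,
                            seed = 229)
  hits <- all_vs_all_hits(sim$proteomes)
  om <- omcl_cluster(hits)
  ct <- cog_triangles_cluster(hits)
  pan <- pan_genome_clusters(om, ct, sim$proteomes)
  gids <- sim$truth$genome_ids
  pm <- compartmentalize(pan, gids)
  pg <- pan_genes(pm, ingroup = gids[1:n_in],
                  outgroup = gids[(n_in + 1):(n_in + n_out)])
  expect_length(pg, n_excl)
  fams <- vapply(attr(pg, "clusters"), function(x)
    unname(sim$truth$family_of[x$members$protein[1]]), "")
  expect_setequal(fams, sprintf("fam%03d", seq_len(n_excl)))
})

test_that("pathway profiles score seed presence at the 30 % floor", {
  set.seed(131)
  seed1 <- random_aa_seq(200)
  seed2 <- random_aa_seq(220)
  seeds <- list(sequence_record("s1", seed1, kind = "protein"),
                sequence_record("s2", seed2, kind = "protein"))
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  g_full <- proteome("gFull", c(q1 = seed1, q2 = seed2))
  # ~50 % identity homolog of seed1 only
  homolog <- mutate_exact(seed1, 100, alphabet = aa)
  g_half <- proteome("gHalf", c(r1 = homolog, r2 = random_aa_seq(210)))
  prof <- pathway_profile(seeds, list(g_full, g_half))
  expect_equal(unname(prof["s1", ]), c(1L, 1L))
  expect_equal(unname(prof["s2", "gFull"]), 1L)
  expect_equal(unname(prof["s2", "gHalf"]), 0L)
  expect_equal(unname(attr(prof, "complete")), c(TRUE, FALSE))
  expect_error(pathway_profile(list(), list(g_full)), "seed")
})
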