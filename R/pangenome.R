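# Ortholog clustering from proteomes under the 70/70 rule, with three
# algorithms (BDBH, COG triangles, Markov clustering), strict consensus
# cores, pan-genome compartments, pan-genes, and pathway profiles.

#' Protein similarity thresholds
#'
#' The 70/70 family rule: two proteins are candidate family members only if
#' they share at least 70 % identity over at least 70 % of the length of the
#' longest sequence. Pathway searches use a permissive 30 % identity floor
#' with a 50 %-of-seed coverage requirement (set
#' `pathway_min_coverage = 0` to use the identity floor alone).
#'
#' @param min_identity_pct Minimum percent identity for family hits.
#' @param min_coverage_fraction Minimum alignment coverage of the longest
#'   sequence.
#' @param pathway_min_identity_pct Identity floor for pathway seed searches.
#' @param pathway_min_coverage Fraction of the seed length that must be
#'   aligned in pathway searches.
#' @return An object of class `similarity_thresholds`.
#' @export
similarity_thresholds <- function(min_identity_pct = 70,
                                  min_coverage_fraction = 0.70,
                                  pathway_min_identity_pct = 30,
                                  pathway_min_coverage = 0.5) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            min_coverage_fraction > 0, min_coverage_fraction <= 1,
            pathway_min_identity_pct > 0, pathway_min_identity_pct <= 100,
            pathway_min_coverage >= 0, pathway_min_coverage <= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_coverage_fraction = min_coverage_fraction,
                 pathway_min_identity_pct = pathway_min_identity_pct,
                 pathway_min_coverage = pathway_min_coverage),
            class = "similarity_thresholds")
}

# Local alignment of two protein sequences (BLOSUM62, affine 11/1).
# Returns identity over alignment columns (gaps included), the aligned span
# on each sequence, and the raw score.
align_protein_pair <- function(a, b) {
  hit <- .sw_align_cpp(encode_seq(a, AA_ALPHABET), encode_seq(b, AA_ALPHABET),
                       aa_submat(), gap_open = 10, gap_ext = 1,
                       ambig = 20L)
  if (!isTRUE(hit$found)) return(NULL)
  list(identity_pct = 100 * hit$matches / hit$cols,
       span_a = hit$q_end - hit$q_start + 1,
       span_b = hit$s_end - hit$s_start + 1,
       score = hit$score)
}

# k-mer prefilter: candidate unordered protein pairs sharing at least
# `min_shared` length-k words. Proteins separated families (<= 40 % identity)
# practically never share 5-mers, so the all-vs-all stays near-linear.
candidate_pairs <- function(seqs, k = 5L, min_shared = 3L) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    len <- nchar(s)
    if (len < k) return(s)
    unique(substring(s, 1:(len - k + 1), k:len))
  })
  dt <- data.table::data.table(
    kmer = unlist(km),
    prot = rep.int(seq_len(n), lengths(km)))
  data.table::setkey(dt, kmer)
  pair_dt <- dt[dt, on = "kmer", allow.cartesian = TRUE][prot < i.prot]
  if (nrow(pair_dt) == 0)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  counts <- pair_dt[, .N, by = .(a = prot, b = i.prot)]
  as.matrix(counts[N >= min_shared, .(a, b)])
}

#' All-versus-all proteome similarity search
#'
#' Aligns every candidate protein pair (a shared k-mer prefilter keeps the
#' search near-linear for well-separated families; set `prefilter = FALSE`
#' to force the full quadratic search) and keeps hits passing the 70/70
#' rule. Hits are reported in both directions; self-hits are excluded.
#'
#' @param proteomes List of [proteome()] objects (>= 2).
#' @param thresholds [similarity_thresholds()].
#' @param prefilter Use the shared-k-mer prefilter.
#' @return A data.frame of hits: `query_id`, `subject_id`, `query_genome`,
#'   `subject_genome`, `identity_pct`, `coverage_of_longest`, `score`.
#' @export
all_vs_all_hits <- function(proteomes, thresholds = similarity_thresholds(),
                            prefilter = TRUE) {
  if (length(proteomes) < 2) stop("need at least two proteomes")
  for (p in proteomes)
    if (length(p$proteins) == 0) stop("empty proteome: ", p$genome_id)
  prot_ids <- unlist(lapply(proteomes, function(p) record_ids(p$proteins)))
  if (anyDuplicated(prot_ids))
    stop("protein ids must be unique across proteomes: ",
         prot_ids[duplicated(prot_ids)][1])
  genomes <- rep(vapply(proteomes, `[[`, "", "genome_id"),
                 vapply(proteomes, function(p) length(p$proteins), 0L))
  seqs <- unlist(lapply(proteomes, function(p)
    vapply(p$proteins, `[[`, "", "sequence")))
  lens <- nchar(seqs)
  pairs <- if (prefilter) candidate_pairs(seqs) else {
    idx <- which(upper.tri(diag(length(seqs))), arr.ind = TRUE)
    cbind(a = idx[, "row"], b = idx[, "col"])
  }
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    al <- align_protein_pair(seqs[i], seqs[j])
    if (is.null(al)) next
    longest <- max(lens[i], lens[j])
    cov <- (if (lens[i] >= lens[j]) al$span_a else al$span_b) / longest
    if (al$identity_pct >= thresholds$min_identity_pct &&
        cov >= thresholds$min_coverage_fraction)
      rows[[r]] <- data.frame(query_id = prot_ids[i], subject_id = prot_ids[j],
                              query_genome = genomes[i],
                              subject_genome = genomes[j],
                              identity_pct = al$identity_pct,
                              coverage_of_longest = cov, score = al$score,
                              stringsAsFactors = FALSE)
  }
  one_way <- do.call(rbind, rows)
  if (is.null(one_way))
    one_way <- data.frame(query_id = character(), subject_id = character(),
                          query_genome = character(),
                          subject_genome = character(),
                          identity_pct = numeric(),
                          coverage_of_longest = numeric(), score = numeric(),
                          stringsAsFactors = FALSE)
  back <- one_way
  names(back)[c(1, 2, 3, 4)] <- c("subject_id", "query_id", "subject_genome",
                                  "query_genome")
  hits <- rbind(one_way, back[names(one_way)])
  rownames(hits) <- NULL
  attr(hits, "proteins") <- data.frame(protein_id = prot_ids,
                                       genome_id = genomes,
                                       stringsAsFactors = FALSE)
  hits
}

ortho_cluster <- function(cluster_id, genome, protein, algorithm) {
  structure(list(cluster_id = cluster_id,
                 members = data.frame(genome = genome, protein = protein,
                                      stringsAsFactors = FALSE),
                 algorithm = algorithm),
            class = "ortho_cluster")
}

#' @export
print.ortho_cluster <- function(x, ...) {
  cat(sprintf("<%s cluster '%s': %d proteins / %d genomes>\n", x$algorithm,
              x$cluster_id, nrow(x$members), length(unique(x$members$genome))))
  invisible(x)
}

cluster_key <- function(cl) {
  paste(sort(paste(cl$members$genome, cl$members$protein, sep = "\r")),
        collapse = "\n")
}

# Best hit of every query protein in every other genome, deterministic ties:
# higher score, then higher identity, then lexicographically smaller subject.
best_hits_table <- function(hits) {
  dt <- data.table::as.data.table(
    hits[hits$query_genome != hits$subject_genome, , drop = FALSE])
  if (nrow(dt) == 0) return(dt)
  data.table::setorder(dt, query_id, subject_genome, -score, -identity_pct,
                       subject_id)
  dt[, utils::head(.SD, 1), by = .(query_id, subject_genome)]
}

# Bidirectional best-hit pairs across genomes (each is the other's top hit).
bbh_pairs <- function(hits) {
  best <- best_hits_table(hits)
  if (nrow(best) == 0)
    return(data.frame(a = character(), b = character(),
                      genome_a = character(), genome_b = character(),
                      stringsAsFactors = FALSE))
  fwd <- best[, .(a = query_id, b = subject_id, genome_a = query_genome,
                  genome_b = subject_genome)]
  rev <- fwd[, .(a = b, b = a)]
  keep <- fwd[rev, on = c("a", "b"), nomatch = 0L]
  keep <- keep[a < b]
  as.data.frame(keep)
}

#' Reference-based bidirectional best-hit (BDBH) clustering
#'
#' For every protein of the reference genome, collects the protein of each
#' other genome that forms a bidirectional best hit with it. Reference
#' proteins with no partner anywhere yield singleton clusters.
#'
#' @param hits Output of [all_vs_all_hits()].
#' @param proteomes The proteomes the hits were computed from.
#' @param reference_genome Genome id used as the reference.
#' @return List of `ortho_cluster` objects (one per reference protein).
#' @export
bdbh_cluster <- function(hits, proteomes, reference_genome) {
  genome_ids <- vapply(proteomes, `[[`, "", "genome_id")
  if (!reference_genome %in% genome_ids)
    stop("reference genome not among proteomes: ", reference_genome)
  ref <- proteomes[[match(reference_genome, genome_ids)]]
  pairs <- bbh_pairs(hits)
  out <- vector("list", length(ref$proteins))
  for (i in seq_along(ref$proteins)) {
    pid <- ref$proteins[[i]]$id
    sel <- pairs[pairs$a == pid | pairs$b == pid, , drop = FALSE]
    partners <- ifelse(sel$a == pid, sel$b, sel$a)
    partner_genomes <- ifelse(sel$a == pid, sel$genome_b, sel$genome_a)
    out[[i]] <- ortho_cluster(paste0("bdbh_", pid),
                              c(reference_genome, partner_genomes),
                              c(pid, partners), "BDBH")
  }
  out
}

#' COG-triangles clustering
#'
#' Builds inter-genome bidirectional best-hit pairs, assembles triangles
#' (three mutually-BBH proteins from three distinct genomes), and merges
#' triangles sharing an edge. Proteins in no triangle remain unclustered.
#'
#' @param hits Output of [all_vs_all_hits()] over at least three genomes.
#' @return List of `ortho_cluster` objects.
#' @export
cog_triangles_cluster <- function(hits) {
  genomes <- unique(c(hits$query_genome, hits$subject_genome))
  if (length(genomes) < 3)
    stop("COG-triangles needs hits over at least three genomes")
  pairs <- bbh_pairs(hits)
  if (nrow(pairs) == 0) return(list())
  prot_genome <- c(setNames(pairs$genome_a, pairs$a),
                   setNames(pairs$genome_b, pairs$b))
  g <- igraph::graph_from_data_frame(pairs[, c("a", "b")], directed = FALSE)
  tri <- igraph::triangles(g)
  if (length(tri) == 0) return(list())
  tri <- matrix(igraph::V(g)$name[as.integer(tri)], ncol = 3, byrow = TRUE)
  distinct <- apply(tri, 1, function(v) length(unique(prot_genome[v])) == 3)
  tri <- tri[distinct, , drop = FALSE]
  if (nrow(tri) == 0) return(list())
  # union-find over triangles keyed by shared (sorted) edges
  edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")
  parent <- seq_len(nrow(tri))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- new.env(parent = emptyenv())
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    for (ek in c(edge_key(v[1], v[2]), edge_key(v[1], v[3]),
                 edge_key(v[2], v[3]))) {
      prev <- edges[[ek]]
      if (is.null(prev)) edges[[ek]] <- t
      else {
        ra <- find(prev); rb <- find(t)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(nrow(tri)), find, 0L)
  groups <- split(seq_len(nrow(tri)), roots)
  out <- lapply(seq_along(groups), function(ci) {
    prots <- sort(unique(as.vector(tri[groups[[ci]], ])))
    ortho_cluster(sprintf("cogt_%04d", ci), unname(prot_genome[prots]), prots,
                  "COGT")
  })
  out
}

#' Markov (OrthoMCL-style) clustering of the protein similarity graph
#'
#' Builds a symmetric graph weighted by the pairwise alignment score
#' (equal in both directions for the built-in aligner, i.e. the
#' min(score_ab, score_ba) convention), then runs Markov clustering
#' independently on each connected component: self-loops at each node's
#' maximum incident weight, column normalization, and alternating expansion
#' (matrix square) and inflation (element-wise power, re-normalize) with
#' pruning below `prune` until the maximum column change drops below `tol`
#' or `max_iter` iterations. Clusters are the connected components of the
#' converged matrix. The iteration is deterministic.
#'
#' @param hits Output of [all_vs_all_hits()].
#' @param inflation Inflation exponent (> 1; default 1.5).
#' @param prune,tol,max_iter Numerical controls.
#' @return List of `ortho_cluster` objects (singletons included for
#'   proteins with hits to no other protein are not listed; see
#'   [pan_genome_clusters()]).
#' @export
omcl_cluster <- function(hits, inflation = 1.5, prune = 1e-5, tol = 1e-6,
                         max_iter = 100L) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (nrow(hits) == 0) return(list())
  key <- paste(pmin(hits$query_id, hits$subject_id),
               pmax(hits$query_id, hits$subject_id), sep = "\r")
  w <- tapply(hits$score, key, min)  # min over the two directions
  uv <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  prot_genome <- c(setNames(hits$query_genome, hits$query_id),
                   setNames(hits$subject_genome, hits$subject_id))
  edges <- data.frame(a = uv[, 1], b = uv[, 2], w = as.numeric(w),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  igraph::E(g)$weight <- edges$w
  comp <- igraph::components(g)$membership
  out <- list()
  for (cid in sort(unique(comp))) {
    verts <- names(comp)[comp == cid]
    sub <- igraph::induced_subgraph(g, verts)
    adj <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    parts <- mcl_partition(adj, inflation, prune, tol, max_iter)
    for (p in parts)
      out[[length(out) + 1]] <- sort(rownames(adj)[p])
  }
  out <- out[order(vapply(out, `[`, "", 1))]
  lapply(seq_along(out), function(ci)
    ortho_cluster(sprintf("omcl_%04d", ci),
                  unname(prot_genome[out[[ci]]]), out[[ci]], "OMCL"))
}

# Core MCL iteration on a dense weighted adjacency matrix; returns a list of
# integer index vectors (the partition).
mcl_partition <- function(adj, inflation, prune = 1e-5, tol = 1e-6,
                          max_iter = 100L) {
  n <- nrow(adj)
  if (n == 1) return(list(1L))
  diag(adj) <- apply(adj, 2, max)       # self-loops at max incident weight
  M <- sweep(adj, 2, colSums(adj), "/")
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M                        # expansion
    M2 <- M2^inflation                   # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("Markov clustering did not converge in ", max_iter,
            " iterations; returning current partition")
  link <- (M > prune) | (t(M) > prune)
  gg <- igraph::graph_from_adjacency_matrix(link, mode = "undirected",
                                            diag = FALSE)
  unname(split(seq_len(n), igraph::components(gg)$membership))
}

#' Strict consensus core of three clusterings
#'
#' Retains the clusters whose member sets are identical across the three
#' algorithms and that contain exactly one protein from every genome
#' (single-copy core families).
#'
#' @param bdbh,cogt,omcl Cluster lists from the three algorithms.
#' @param genomes Character vector of all genome ids in the analysis.
#' @return List of consensus `ortho_cluster` objects.
#' @export
consensus_core <- function(bdbh, cogt, omcl, genomes) {
  keysets <- lapply(list(bdbh, cogt, omcl), function(cl)
    vapply(cl, cluster_key, ""))
  shared <- Reduce(intersect, keysets)
  idx <- match(shared, keysets[[1]])
  out <- list()
  for (i in idx) {
    cl <- bdbh[[i]]
    tab <- table(cl$members$genome)
    if (length(tab) == length(genomes) && all(names(tab) %in% genomes) &&
        all(tab == 1)) {
      cl$algorithm <- "consensus"
      cl$cluster_id <- sub("^bdbh_", "core_", cl$cluster_id)
      out[[length(out) + 1]] <- cl
    }
  }
  out
}

#' Assemble the pan-genome cluster set from OMCL and COG-triangles
#'
#' The pan-genome is the set of clusters found with identical member sets by
#' both OMCL and COG-triangles, extended with the OMCL clusters whose
#' members are not covered by any such consensus cluster (COG-triangles is
#' structurally blind to families present in fewer than three genomes), and
#' finally with singleton clusters for proteins assigned to no cluster, so
#' that strain-specific genes appear in the cloud compartment.
#'
#' @param omcl,cogt Cluster lists from the two algorithms.
#' @param proteomes The proteomes under analysis (source of the full protein
#'   universe).
#' @return List of `ortho_cluster` objects covering every protein exactly
#'   once.
#' @export
pan_genome_clusters <- function(omcl, cogt, proteomes) {
  okeys <- vapply(omcl, cluster_key, "")
  ckeys <- vapply(cogt, cluster_key, "")
  both <- omcl[okeys %in% ckeys]
  covered <- unlist(lapply(both, function(cl) cl$members$protein))
  extra <- Filter(function(cl) !any(cl$members$protein %in% covered), omcl)
  out <- c(both, extra)
  covered <- unlist(lapply(out, function(cl) cl$members$protein))
  singles <- list()
  for (p in proteomes) {
    for (pr in p$proteins) {
      if (!(pr$id %in% covered))
        singles[[length(singles) + 1]] <-
          ortho_cluster(paste0("single_", pr$id), p$genome_id, pr$id, "OMCL")
    }
  }
  out <- c(out, singles)
  for (i in seq_along(out)) out[[i]]$cluster_id <- sprintf("pan_%05d", i)
  out
}

#' Build a compartment-labeled pan-genome matrix from clusters
#'
#' Labels every cluster core (present in all genomes), soft-core (in at
#' least `soft_core_fraction` of the genomes but not all), cloud (in only
#' one or two genomes), or shell (everything else), and assembles the
#' cluster-by-genome occupancy count matrix.
#'
#' @param clusters List of `ortho_cluster` objects (e.g. from
#'   [pan_genome_clusters()]).
#' @param genomes Character vector of all genome ids.
#' @param soft_core_fraction Soft-core occupancy fraction (default 0.95).
#' @return A [pangenome_matrix()] object.
#' @export
compartmentalize <- function(clusters, genomes, soft_core_fraction = 0.95) {
  occ <- matrix(0L, nrow = length(clusters), ncol = length(genomes),
                dimnames = list(vapply(clusters, `[[`, "", "cluster_id"),
                                genomes))
  for (i in seq_along(clusters)) {
    tab <- table(clusters[[i]]$members$genome)
    miss <- setdiff(names(tab), genomes)
    if (length(miss))
      stop("cluster member genome not in genome list: ", miss[1])
    occ[i, names(tab)] <- as.integer(tab)
  }
  pangenome_matrix(occ, clusters = clusters,
                   soft_core_fraction = soft_core_fraction)
}

#' Pan-genome occupancy matrix with compartment labels
#'
#' @param occupancy Integer cluster-by-genome count matrix (rownames are
#'   cluster ids, colnames genome ids).
#' @param clusters Optional list of the underlying `ortho_cluster` objects.
#' @param soft_core_fraction Soft-core occupancy fraction (default 0.95).
#' @return An object of class `pangenome_matrix` with elements `occupancy`,
#'   `genomes`, `compartments`, `clusters`.
#' @export
pangenome_matrix <- function(occupancy, clusters = NULL,
                             soft_core_fraction = 0.95) {
  stopifnot(is.matrix(occupancy), all(occupancy >= 0))
  if (is.null(rownames(occupancy)))
    rownames(occupancy) <- sprintf("pan_%05d", seq_len(nrow(occupancy)))
  if (is.null(colnames(occupancy)))
    colnames(occupancy) <- sprintf("g%03d", seq_len(ncol(occupancy)))
  n_genomes <- ncol(occupancy)
  present <- rowSums(occupancy > 0)
  if (any(present == 0))
    stop("pan-genome clusters must occur in at least one genome")
  compartments <- ifelse(
    present == n_genomes, "core",
    ifelse(present >= soft_core_fraction * n_genomes, "soft-core",
           ifelse(present <= 2, "cloud", "shell")))
  names(compartments) <- rownames(occupancy)
  structure(list(occupancy = occupancy, genomes = colnames(occupancy),
                 compartments = compartments, clusters = clusters,
                 soft_core_fraction = soft_core_fraction),
            class = "pangenome_matrix")
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  tab <- table(factor(x$compartments,
                      levels = c("core", "soft-core", "shell", "cloud")))
  cat(sprintf("<pan-genome matrix: %d clusters x %d genomes>\n",
              nrow(x$occupancy), length(x$genomes)))
  cat(sprintf("  core %d | soft-core %d | shell %d | cloud %d\n",
              tab["core"], tab["soft-core"], tab["shell"], tab["cloud"]))
  invisible(x)
}

#' In-group exclusive pan-genes
#'
#' Clusters present (occupancy >= 1) in every in-group genome and absent
#' from every out-group genome.
#'
#' @param matrix A [pangenome_matrix()].
#' @param ingroup,outgroup Disjoint, non-empty character vectors of genome
#'   ids.
#' @return Character vector of cluster ids (with the matching clusters as
#'   attribute `clusters` when available).
#' @export
pan_genes <- function(matrix, ingroup, outgroup) {
  stopifnot(inherits(matrix, "pangenome_matrix"))
  if (!length(ingroup) || !length(outgroup))
    stop("ingroup and outgroup must both be non-empty")
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup overlap: ",
         paste(intersect(ingroup, outgroup), collapse = ", "))
  miss <- setdiff(c(ingroup, outgroup), matrix$genomes)
  if (length(miss)) stop("unknown genome id: ", miss[1])
  occ <- matrix$occupancy
  sel <- rowSums(occ[, ingroup, drop = FALSE] > 0) == length(ingroup) &
    rowSums(occ[, outgroup, drop = FALSE]) == 0
  ids <- rownames(occ)[sel]
  cl <- if (!is.null(matrix$clusters)) matrix$clusters[sel] else NULL
  structure(ids, clusters = cl)
}

#' Presence/absence profile of pathway seed proteins across genomes
#'
#' Each seed is searched against every proteome; a genome scores 1 for a
#' seed when it has at least one protein at or above the pathway identity
#' floor (and covering at least `pathway_min_coverage` of the seed). A
#' pathway is complete in a genome iff all its seeds are present.
#'
#' @param seed_proteins List of protein [sequence_record()]s.
#' @param proteomes List of [proteome()] objects.
#' @param thresholds [similarity_thresholds()].
#' @return A 0/1 matrix (seeds x genomes) with attribute `complete`, a named
#'   logical over genomes.
#' @export
pathway_profile <- function(seed_proteins, proteomes,
                            thresholds = similarity_thresholds()) {
  if (length(seed_proteins) == 0) stop("need at least one seed protein")
  seed_ids <- record_ids(seed_proteins)
  genome_ids <- vapply(proteomes, `[[`, "", "genome_id")
  prof <- matrix(0L, length(seed_proteins), length(proteomes),
                 dimnames = list(seed_ids, genome_ids))
  for (i in seq_along(seed_proteins)) {
    seed <- seed_proteins[[i]]$sequence
    for (j in seq_along(proteomes)) {
      for (pr in proteomes[[j]]$proteins) {
        al <- align_protein_pair(seed, pr$sequence)
        if (!is.null(al) &&
            al$identity_pct >= thresholds$pathway_min_identity_pct &&
            al$span_a / nchar(seed) >= thresholds$pathway_min_coverage) {
          prof[i, j] <- 1L
          break
        }
      }
    }
  }
  structure(prof, complete = apply(prof == 1, 2, all))
}
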