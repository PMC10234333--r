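# Fragment-based average nucleotide identity (ANIb), genomospecies
# clustering at the 95 % threshold, and the ANI dendrogram.

#' ANIb parameters
#'
#' Defaults follow the canonical fragment-based ANIb definition: 1,020 bp
#' fragments, hits kept when they reach >= 30 % identity over >= 70 % of the
#' fragment length, and a 95 % species threshold. The aligner settings
#' (match +1, mismatch -1, gap open -5, gap extend -2) parameterize the
#' built-in seeded local aligner.
#'
#' @param fragment_length Fragment size in bp.
#' @param min_hit_identity_pct Minimum percent identity for a fragment hit.
#' @param min_alignable_fraction Minimum fraction of the fragment covered by
#'   its best alignment.
#' @param species_threshold_pct ANI threshold delimiting a genomospecies.
#' @param match,mismatch,gap_open,gap_extend Aligner scores (penalties
#'   positive).
#' @param kmer Seed k-mer length of the aligner.
#' @param band Diagonal half-band width for seeded alignment.
#' @param max_bins Number of top diagonal bins evaluated per fragment.
#' @param min_votes Minimum shared-k-mer votes a diagonal bin needs before
#'   it is aligned (suppresses chance seed matches).
#' @param full_sw_limit Subjects at most this long are aligned by full
#'   (unseeded) Smith-Waterman.
#' @return An object of class `anib_params`.
#' @export
anib_params <- function(fragment_length = 1020L, min_hit_identity_pct = 30,
                        min_alignable_fraction = 0.70,
                        species_threshold_pct = 95,
                        match = 1, mismatch = -1, gap_open = 5,
                        gap_extend = 2, kmer = 11L, band = 64L,
                        max_bins = 3L, min_votes = 3L,
                        full_sw_limit = 10000L) {
  stopifnot(min_hit_identity_pct > 0, min_hit_identity_pct <= 100,
            min_alignable_fraction > 0, min_alignable_fraction <= 1,
            species_threshold_pct > 0, species_threshold_pct <= 100,
            fragment_length >= 100, gap_open >= 0, gap_extend >= 0)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_hit_identity_pct = min_hit_identity_pct,
                 min_alignable_fraction = min_alignable_fraction,
                 species_threshold_pct = species_threshold_pct,
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, kmer = as.integer(kmer),
                 band = as.integer(band), max_bins = as.integer(max_bins),
                 min_votes = as.integer(min_votes),
                 full_sw_limit = as.integer(full_sw_limit)),
            class = "anib_params")
}

#' Best local alignment of one fragment against a genome
#'
#' Searches every contig of `subject` on both strands with the built-in
#' seeded Smith-Waterman aligner and returns the highest-scoring hit, or
#' `NULL` when nothing aligns with a positive score. Identity uses the
#' BLAST convention (identical columns / alignment columns, gap columns
#' included); the alignable fraction is the aligned span of the fragment
#' divided by its length. N bases never count as identities.
#'
#' @param fragment One row of [fragment_assembly()] output (or any list with
#'   a `sequence` element).
#' @param subject A [genome_assembly()].
#' @param params [anib_params()].
#' @return A list with `identity_pct`, `alignable_fraction`, `score`,
#'   `subject_contig`, `strand`, or `NULL`.
#' @export
best_fragment_hit <- function(fragment, subject, params = anib_params()) {
  seq <- if (is.data.frame(fragment)) fragment$sequence[1] else fragment$sequence
  q <- encode_seq(seq, NUC_ALPHABET)
  submat <- nuc_submat(params$match, params$mismatch)
  best <- NULL
  for (ct in subject$contigs) {
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") ct$sequence else revcomp(ct$sequence)
      hit <- .best_local_hit_cpp(q, encode_seq(sseq, NUC_ALPHABET), submat,
                                 params$gap_open, params$gap_extend,
                                 ambig = 4L, k = params$kmer,
                                 band = params$band,
                                 max_bins = params$max_bins,
                                 min_votes = params$min_votes,
                                 full_limit = params$full_sw_limit)
      if (isTRUE(hit$found) && (is.null(best) || hit$score > best$score)) {
        best <- hit
        best$subject_contig <- ct$id
        best$strand <- strand
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(identity_pct = 100 * best$matches / best$cols,
       alignable_fraction = (best$q_end - best$q_start + 1) / length(q),
       score = best$score, subject_contig = best$subject_contig,
       strand = best$strand, matches = best$matches, cols = best$cols)
}

#' One-way ANIb of a query genome against a subject genome
#'
#' The query is fragmented, each fragment's best hit in the subject is
#' computed, hits below 30 % identity or 70 % alignable fraction are
#' discarded, and the mean identity of the surviving fragments is returned.
#' When no fragment qualifies the result is `NA` (an explicit
#' "no alignable fraction" marker, never 0); attributes `n_fragments` and
#' `n_used` report how many fragments were cut and kept.
#'
#' @param query,subject [genome_assembly()] objects.
#' @param params [anib_params()].
#' @return Percent identity (scalar), or `NA_real_`.
#' @export
anib_oneway <- function(query, subject, params = anib_params()) {
  frags <- fragment_assembly(query, params$fragment_length)
  if (nrow(frags) == 0)
    return(structure(NA_real_, n_fragments = 0L, n_used = 0L))
  submat <- nuc_submat(params$match, params$mismatch)
  enc <- lapply(frags$sequence, encode_seq, alphabet = NUC_ALPHABET)
  frag_len <- nchar(frags$sequence)
  best_score <- rep(-Inf, nrow(frags))
  best_ident <- rep(NA_real_, nrow(frags))
  best_cov <- rep(NA_real_, nrow(frags))
  # one batch per contig strand: the subject k-mer index is built once
  for (ct in subject$contigs) {
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") ct$sequence else revcomp(ct$sequence)
      hits <- .best_local_hits_batch_cpp(
        enc, encode_seq(sseq, NUC_ALPHABET), submat, params$gap_open,
        params$gap_extend, ambig = 4L, k = params$kmer, band = params$band,
        max_bins = params$max_bins, min_votes = params$min_votes,
        full_limit = params$full_sw_limit)
      for (i in seq_along(hits)) {
        h <- hits[[i]]
        if (isTRUE(h$found) && h$score > best_score[i]) {
          best_score[i] <- h$score
          best_ident[i] <- 100 * h$matches / h$cols
          best_cov[i] <- (h$q_end - h$q_start + 1) / frag_len[i]
        }
      }
    }
  }
  ok <- !is.na(best_ident) &
    best_ident >= params$min_hit_identity_pct &
    best_cov >= params$min_alignable_fraction
  val <- if (any(ok)) mean(best_ident[ok]) else NA_real_
  structure(val, n_fragments = nrow(frags), n_used = sum(ok))
}

#' Bidirectional ANIb between two genomes
#'
#' Arithmetic mean of the two one-way ANIb values. If only one direction is
#' defined, that value is returned with attribute `one_way_only = TRUE`; if
#' neither is, `NA`.
#'
#' @param a,b [genome_assembly()] objects.
#' @param params [anib_params()].
#' @return Percent identity with attributes `ani_ab`, `ani_ba`.
#' @export
anib_pair <- function(a, b, params = anib_params()) {
  ab <- anib_oneway(a, b, params)
  ba <- anib_oneway(b, a, params)
  vals <- c(as.numeric(ab), as.numeric(ba))
  def <- !is.na(vals)
  val <- if (all(def)) mean(vals) else if (any(def)) vals[def] else NA_real_
  structure(val, ani_ab = as.numeric(ab), ani_ba = as.numeric(ba),
            one_way_only = xor(def[1], def[2]))
}

#' All-versus-all ANIb matrix
#'
#' @param assemblies List of [genome_assembly()] objects with unique ids.
#' @param params [anib_params()].
#' @return An `ani_matrix`: symmetric percent matrix with a 100 diagonal and
#'   the genome ids as dimnames. Undefined pairs are `NA`.
#' @export
build_ani_matrix <- function(assemblies, params = anib_params()) {
  if (length(assemblies) < 2) stop("need at least two assemblies")
  ids <- vapply(assemblies, `[[`, "", "genome_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate genome_id: ", dup[1])
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      v <- as.numeric(anib_pair(assemblies[[i]], assemblies[[j]], params))
      m[i, j] <- m[j, i] <- v
    }
  }
  ani_matrix(m)
}

#' Construct an ANI matrix object from a square percent matrix
#'
#' @param values Symmetric numeric matrix with dimnames; diagonal forced
#'   to 100.
#' @return An object of class `ani_matrix` (a numeric matrix).
#' @export
ani_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("g", seq_len(nrow(values)))
  ok <- is.na(values) | (values >= 0 & values <= 100)
  if (!all(ok)) stop("ANI values must lie in [0, 100]")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("ANI matrix must be symmetric")
  diag(values) <- 100
  structure(values, class = c("ani_matrix", "matrix", "array"))
}

#' @export
print.ani_matrix <- function(x, ...) {
  cat(sprintf("<ANI matrix: %d genomes>\n", nrow(x)))
  print(round(unclass(x), 2), ...)
  invisible(x)
}

#' Partition genomes into genomospecies at an ANI threshold
#'
#' Single-linkage partition: two genomes fall in the same genomospecies iff
#' they are connected by a chain of pairwise ANI values at or above the
#' threshold (the pairwise >= 95 % species rule read as transitive closure).
#'
#' @param matrix An [ani_matrix()].
#' @param threshold_pct Species threshold (default 95).
#' @return A list of character vectors (the clusters), ordered by first
#'   member; the `membership` attribute maps genome to cluster index.
#' @export
cluster_genomospecies <- function(matrix, threshold_pct = 95) {
  m <- unclass(matrix)
  adj <- !is.na(m) & m >= threshold_pct
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(rownames(m), comp)
  clusters <- clusters[order(vapply(clusters, function(x)
    match(x[1], rownames(m)), 0L))]
  names(clusters) <- NULL
  structure(clusters, membership = comp)
}

#' Average-linkage dendrogram of an ANI matrix on Pearson distance
#'
#' Genomes are clustered by average linkage (UPGMA-style) on the distance
#' 1 - r, where r is the Pearson correlation between the genomes' rows of
#' the ANI matrix.
#'
#' @param matrix An [ani_matrix()] over at least three genomes.
#' @return An [ape::as.phylo()] tree whose leaves are the genome ids.
#' @export
ani_dendrogram <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) < 3) stop("need at least three genomes for a dendrogram")
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    stop("constant ANI row (zero variance) for genome: ",
         rownames(m)[which(sds == 0)[1]])
  d <- as.dist(1 - cor(t(m)))
  ape::as.phylo(hclust(d, method = "average"))
}

#' Write pairwise ANI values in long format
#'
#' @param matrix An [ani_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ani_long <- function(matrix, path) {
  m <- unclass(matrix)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tab <- data.frame(genome_a = rownames(m)[idx[, 1]],
                    genome_b = colnames(m)[idx[, 2]],
                    ani_mean = m[idx])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
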