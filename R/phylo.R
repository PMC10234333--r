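# Distance-based phylogenetics: Jukes-Cantor distances, neighbor joining,
# column-bootstrap supports, and Gblocks-style alignment trimming.

#' Create a multiple alignment
#'
#' @param records List of [sequence_record()]s of equal length (gaps `-`
#'   allowed), or a named character vector of aligned sequences.
#' @param kind `"nucleotide"` or `"protein"`.
#' @return An object of class `multiple_alignment` with `ids`, `seqs`,
#'   `n_columns`, `kind`.
#' @export
multiple_alignment <- function(records, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (is.list(records)) {
    ids <- record_ids(records)
    seqs <- vapply(records, `[[`, "", "sequence")
  } else {
    ids <- names(records)
    if (is.null(ids)) stop("aligned sequences must be named")
    seqs <- toupper(unname(records))
  }
  if (length(seqs) < 2) stop("an alignment needs at least two sequences")
  if (anyDuplicated(ids)) stop("duplicate sequence id in alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must all have the same length")
  structure(list(ids = ids, seqs = setNames(seqs, ids),
                 n_columns = lens[1], kind = kind),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment: %d sequences x %d columns>\n", x$kind,
              length(x$ids), x$n_columns))
  invisible(x)
}

aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

#' Jukes-Cantor distance matrix from a nucleotide alignment
#'
#' d = -(3/4) ln(1 - (4/3) p), where p is the mismatch fraction over the
#' columns where neither sequence carries a gap or N (pairwise deletion).
#' For protein alignments the uncorrected p-distance is returned instead.
#'
#' @param aln A [multiple_alignment()].
#' @return A symmetric distance matrix with the sequence ids as dimnames.
#' @export
jc_distance <- function(aln) {
  stopifnot(inherits(aln, "multiple_alignment"))
  chars <- aln_char_matrix(aln)
  valid <- if (aln$kind == "nucleotide")
    matrix(chars %in% c("A", "C", "G", "T"), nrow = nrow(chars))
  else chars != "-" & chars != "X"
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      comp <- valid[i, ] & valid[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0)
        stop("no comparable columns between '", aln$ids[i], "' and '",
             aln$ids[j], "'")
      p <- sum(chars[i, comp] != chars[j, comp]) / ncomp
      if (aln$kind == "nucleotide") {
        if (p >= 0.75)
          stop("Jukes-Cantor distance undefined (p = ", signif(p, 3),
               " >= 0.75) between '", aln$ids[i], "' and '", aln$ids[j], "'")
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      } else {
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]. On additive distances the
#' tree's path-length matrix reproduces the input exactly. Negative branch
#' lengths (possible on non-additive input) are clamped to zero with a
#' warning.
#'
#' @param dm Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least three taxa")
  tree <- ape::nj(as.dist(dm))
  if (any(tree$edge.length < 0)) {
    warning("negative neighbor-joining branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap supports for the neighbor-joining tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Jukes-Cantor/NJ tree per replicate, and reports per-edge support as the
#' percentage of replicates containing the same bipartition, mapped onto
#' the full-data tree's internal nodes (`node.label`). Replicates whose
#' resampled distances are undefined (saturated or non-overlapping) are
#' redrawn, up to ten times the replicate count.
#'
#' @param aln A [multiple_alignment()].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed RNG seed (mandatory).
#' @return The full-data `phylo` tree with percent supports in
#'   `node.label`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(aln, "multiple_alignment"))
  n_replicates <- as.integer(n_replicates)
  main <- neighbor_joining(jc_distance(aln))
  chars <- aln_char_matrix(aln)
  trees <- vector("list", n_replicates)
  with_seed(seed, {
    done <- 0L; draws <- 0L
    while (done < n_replicates) {
      if (draws >= 10L * n_replicates)
        stop("too many bootstrap replicates with undefined distances")
      draws <- draws + 1L
      cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
      boot <- chars[, cols, drop = FALSE]
      baln <- multiple_alignment(
        setNames(apply(boot, 1, paste, collapse = ""), aln$ids),
        kind = aln$kind)
      t <- tryCatch(suppressWarnings(neighbor_joining(jc_distance(baln))),
                    error = function(e) NULL)
      if (is.null(t)) next
      done <- done + 1L
      trees[[done]] <- t
    }
  })
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(main, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / n_replicates, 1)
  main
}

#' Gblocks-style alignment trimming
#'
#' Keeps the columns whose non-gap fraction is at least
#' `min_nongap_fraction` and whose most frequent residue (gaps excluded)
#' reaches `min_conserved_fraction` of the sequences; runs of kept columns
#' shorter than `min_block_length` are then dropped. The retained column
#' indices are recorded in attribute `kept_columns` of the result.
#'
#' @param aln A [multiple_alignment()].
#' @param min_nongap_fraction Minimum fraction of non-gap residues.
#' @param min_conserved_fraction Minimum majority-residue fraction.
#' @param min_block_length Minimum kept-run length.
#' @return A trimmed [multiple_alignment()].
#' @export
trim_alignment <- function(aln, min_nongap_fraction = 0.5,
                           min_conserved_fraction = 0.5,
                           min_block_length = 5L) {
  stopifnot(inherits(aln, "multiple_alignment"))
  chars <- aln_char_matrix(aln)
  n <- nrow(chars)
  keep <- logical(ncol(chars))
  for (j in seq_len(ncol(chars))) {
    col <- chars[, j]
    nongap <- col != "-"
    if (sum(nongap) / n < min_nongap_fraction) next
    tab <- table(col[nongap])
    keep[j] <- max(tab) / n >= min_conserved_fraction
  }
  # drop kept runs shorter than min_block_length
  r <- rle(keep)
  short <- r$values & r$lengths < min_block_length
  r$values[short] <- FALSE
  keep <- inverse.rle(r)
  if (!any(keep)) stop("trimming removed every column")
  out <- multiple_alignment(
    setNames(apply(chars[, keep, drop = FALSE], 1, paste, collapse = ""),
             aln$ids),
    kind = aln$kind)
  attr(out, "kept_columns") <- which(keep)
  out
}

#' Concatenate alignments over a common taxon set
#'
#' @param alignments List of [multiple_alignment()]s sharing one taxon set.
#' @return A [multiple_alignment()] with attribute `partition_map`, a
#'   data.frame of the column range contributed by each part.
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  taxa <- sort(alignments[[1]]$ids)
  for (k in seq_along(alignments)) {
    miss <- setdiff(taxa, alignments[[k]]$ids)
    extra <- setdiff(alignments[[k]]$ids, taxa)
    if (length(miss) || length(extra))
      stop("alignment ", k, " taxon set mismatch: ",
           paste(c(miss, extra), collapse = ", "))
  }
  lens <- vapply(alignments, `[[`, 0L, "n_columns")
  seqs <- vapply(taxa, function(tx)
    paste(vapply(alignments, function(a) unname(a$seqs[tx]), ""),
          collapse = ""), "")
  out <- multiple_alignment(setNames(seqs, taxa), kind = alignments[[1]]$kind)
  ends <- cumsum(lens)
  attr(out, "partition_map") <- data.frame(
    part = seq_along(alignments), start = c(1L, head(ends, -1) + 1L),
    end = ends)
  out
}

#' Write a tree in Newick format (supports as internal-node labels)
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
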