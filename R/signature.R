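# 16S rRNA signature-nucleotide evaluation and the two-step screening
# classifier (sequence identity + full signature-state check).

#' Create a signature-position profile
#'
#' An ordered set of reference-numbered positions (e.g. E. coli SSU
#' numbering) with the base expected at each. The species profile this
#' package was built around comprises 37 positions within reference
#' positions 50-650, of which one is exclusive to the species.
#'
#' @param positions Strictly increasing 1-based reference positions.
#' @param expected_bases One of A/C/G/T per position.
#' @param reference_id Identifier of the reference 16S sequence the
#'   numbering refers to.
#' @param numbering_scheme Free-text description of the coordinate system.
#' @return An object of class `signature_profile`.
#' @export
signature_profile <- function(positions, expected_bases, reference_id,
                              numbering_scheme = "reference coordinates") {
  positions <- as.integer(positions)
  expected_bases <- toupper(expected_bases)
  if (length(positions) != length(expected_bases))
    stop("positions and expected_bases lengths differ")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (!all(expected_bases %in% c("A", "C", "G", "T")))
    stop("expected bases must be A, C, G or T")
  structure(list(positions = positions, expected_bases = expected_bases,
                 reference_id = reference_id,
                 numbering_scheme = numbering_scheme,
                 n_positions = length(positions)),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("<signature profile: %d positions on '%s' (%s)>\n",
              x$n_positions, x$reference_id, x$numbering_scheme))
  invisible(x)
}

#' Screening thresholds of the two-step classifier
#'
#' Step 1 of the screen requires at least `min_identity_pct` identity
#' (inclusive boundary) and `min_query_coverage` coverage against the
#' reference region `query_region` (which must encompass all profile
#' positions).
#'
#' @param min_identity_pct Identity threshold (default 99.6).
#' @param min_query_coverage Coverage threshold (default 0.90).
#' @param query_region Reference-coordinate `(start, end)` of the screened
#'   region (default `c(50, 650)`).
#' @return An object of class `screening_thresholds`.
#' @export
screening_thresholds <- function(min_identity_pct = 99.6,
                                 min_query_coverage = 0.90,
                                 query_region = c(50L, 650L)) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            min_query_coverage > 0, min_query_coverage <= 1,
            length(query_region) == 2, query_region[1] < query_region[2])
  structure(list(min_identity_pct = min_identity_pct,
                 min_query_coverage = min_query_coverage,
                 query_region = as.integer(query_region)),
            class = "screening_thresholds")
}

# Global pairwise alignment of two nucleotide records; returns the two
# gapped strings (equal length).
global_alignment_strings <- function(query, reference,
                                     type = "global") {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -2, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference),
    type = type, substitutionMatrix = submat,
    gapOpening = 10, gapExtension = 4)
  list(q = as.character(Biostrings::alignedPattern(pa)),
       r = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Map reference-numbered profile positions onto a query sequence
#'
#' Globally aligns the query to the reference and, for every profile
#' position, reports the 1-based query position aligned to it, the query
#' base found there, and whether the position is covered (a gap, sequence
#' end, or ambiguity code at the position counts as uncovered).
#'
#' @param query,reference Nucleotide [sequence_record()]s.
#' @param profile A [signature_profile()].
#' @return A data.frame (`reference_position`, `expected_base`,
#'   `query_position`, `query_base`, `covered`).
#' @export
map_reference_positions <- function(query, reference, profile) {
  stopifnot(inherits(profile, "signature_profile"))
  al <- global_alignment_strings(query$sequence, reference$sequence)
  qc <- strsplit(al$q, "", fixed = TRUE)[[1]]
  rc <- strsplit(al$r, "", fixed = TRUE)[[1]]
  rpos <- cumsum(rc != "-")
  qpos <- cumsum(qc != "-")
  cols <- match(profile$positions, rpos)
  if (anyNA(cols))
    stop("reference position ", profile$positions[which(is.na(cols))[1]],
         " is beyond the reference sequence")
  qbase <- qc[cols]
  covered <- qbase %in% c("A", "C", "G", "T")
  data.frame(reference_position = profile$positions,
             expected_base = profile$expected_bases,
             query_position = ifelse(covered, qpos[cols], NA_integer_),
             query_base = ifelse(qbase == "-", NA_character_, qbase),
             covered = covered, stringsAsFactors = FALSE)
}

#' Two-step signature screening of one 16S sequence
#'
#' Step 1 aligns the reference's screened region (by default positions
#' 50-650) to the query and computes percent identity (identical columns /
#' alignment columns) and coverage (region positions aligned to a query
#' base / region length). Identity below the threshold rejects the query as
#' a non-member; insufficient coverage makes it not classifiable. Step 2
#' maps every profile position onto the query: all positions covered and
#' matching their expected base makes the query a member; any covered
#' mismatch makes it a non-member; an uncovered position (with all covered
#' positions matching) leaves it not classifiable — the strict convention
#' that prefers missing true strains over accepting false ones. Queries
#' shorter than 200 bases are not classifiable.
#'
#' @param query A nucleotide [sequence_record()].
#' @param reference The reference 16S [sequence_record()].
#' @param profile A [signature_profile()].
#' @param thresholds A [screening_thresholds()].
#' @return An object of class `screening_verdict`.
#' @export
screen_sequence <- function(query, reference, profile,
                            thresholds = screening_thresholds()) {
  res <- list(sequence_id = query$id, step1 = NA_character_,
              identity_pct = NA_real_, coverage = NA_real_,
              positions_covered = 0L, positions_matched = 0L,
              detail = NULL, verdict = "not_classifiable")
  class(res) <- "screening_verdict"
  if (nchar(query$sequence) < 200) {
    res$step1 <- "fail_coverage"
    return(res)
  }
  region <- substring(reference$sequence, thresholds$query_region[1],
                      thresholds$query_region[2])
  al <- global_alignment_strings(region, query$sequence,
                                 type = "global-local")
  qc <- strsplit(al$q, "", fixed = TRUE)[[1]]  # region (pattern)
  sc <- strsplit(al$r, "", fixed = TRUE)[[1]]  # query (subject)
  identity <- 100 * sum(qc == sc & qc != "-") / length(qc)
  coverage <- sum(qc != "-" & sc != "-") / nchar(region)
  res$identity_pct <- identity
  res$coverage <- coverage
  if (coverage < thresholds$min_query_coverage) {
    res$step1 <- "fail_coverage"
    res$verdict <- "not_classifiable"
    return(res)
  }
  if (identity < thresholds$min_identity_pct) {
    res$step1 <- "fail_identity"
    res$verdict <- "non_member"
    return(res)
  }
  res$step1 <- "pass"
  map <- map_reference_positions(query, reference, profile)
  map$matched <- map$covered & map$query_base == map$expected_base
  res$detail <- map
  res$positions_covered <- sum(map$covered)
  res$positions_matched <- sum(map$matched, na.rm = TRUE)
  if (any(map$covered & !map$matched)) {
    res$verdict <- "non_member"
  } else if (all(map$covered)) {
    res$verdict <- "member"
  } else {
    res$verdict <- "not_classifiable"
  }
  res
}

#' @export
print.screening_verdict <- function(x, ...) {
  cat(sprintf("<screening verdict for '%s': %s (step1 %s, id %.2f%%, cov %.2f, %d/%d positions)>\n",
              x$sequence_id, x$verdict, x$step1,
              x$identity_pct %||% NA, x$coverage %||% NA,
              x$positions_matched, x$positions_covered))
  invisible(x)
}

#' Conservation and exclusivity of a signature-position set
#'
#' For every profile position, checks whether all in-group sequences carry
#' the expected base (conservation) and whether no out-group sequence does
#' (exclusivity; an uncovered position does not count as carrying the
#' base). Also reports whether any out-group sequence carries the full
#' combination of all positions.
#'
#' @param ingroup,outgroup Lists of nucleotide [sequence_record()]s.
#' @param reference The reference 16S [sequence_record()].
#' @param profile A [signature_profile()].
#' @return A list with `per_position` (data.frame), `n_conserved`,
#'   `n_exclusive`, `combination_exclusive`.
#' @export
evaluate_signature_set <- function(ingroup, outgroup, reference, profile) {
  if (!length(ingroup) || !length(outgroup))
    stop("both panels must be non-empty")
  state_matrix <- function(panel) {
    do.call(rbind, lapply(panel, function(rec) {
      map <- map_reference_positions(rec, reference, profile)
      ifelse(map$covered, map$query_base, NA_character_)
    }))
  }
  in_states <- state_matrix(ingroup)
  out_states <- state_matrix(outgroup)
  exp <- profile$expected_bases
  conserved <- vapply(seq_along(exp), function(k)
    all(!is.na(in_states[, k]) & in_states[, k] == exp[k]), TRUE)
  carried_out <- sweep(out_states, 2, exp, function(a, b)
    !is.na(a) & a == b)
  exclusive <- colSums(carried_out) == 0
  per_position <- data.frame(
    reference_position = profile$positions, expected_base = exp,
    conserved_in_ingroup = conserved, exclusive = exclusive,
    n_outgroup_carrying = colSums(carried_out))
  list(per_position = per_position,
       n_conserved = sum(conserved), n_exclusive = sum(exclusive),
       combination_exclusive = !any(rowSums(carried_out) == length(exp)))
}

#' Pairwise global-alignment identity matrix
#'
#' Percent identity (identical columns over all alignment columns) from
#' global pairwise alignments of every sequence pair; the diagonal is 100.
#'
#' @param seqs List of nucleotide [sequence_record()]s (>= 2).
#' @return A symmetric percent matrix.
#' @export
pairwise_identity_matrix <- function(seqs) {
  if (length(seqs) < 2) stop("need at least two sequences")
  ids <- record_ids(seqs)
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      al <- global_alignment_strings(seqs[[i]]$sequence, seqs[[j]]$sequence)
      qc <- strsplit(al$q, "", fixed = TRUE)[[1]]
      sc <- strsplit(al$r, "", fixed = TRUE)[[1]]
      m[i, j] <- m[j, i] <- 100 * sum(qc == sc & qc != "-") / length(qc)
    }
  }
  m
}

#' Read a signature profile from a TSV file
#'
#' The format is a tab-separated table (`reference_position`,
#' `expected_base`) preceded by `# key: value` header lines carrying
#' `reference_id` and `numbering_scheme`.
#'
#' @param path Path to the profile file.
#' @return A [signature_profile()].
#' @export
read_signature_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
    else "unspecified"
  }
  tab <- read.delim(text = lines[!grepl("^#", lines)],
                    stringsAsFactors = FALSE)
  signature_profile(tab$reference_position, tab$expected_base,
                    reference_id = get_field("reference_id"),
                    numbering_scheme = get_field("numbering_scheme"))
}

#' Write a signature profile to a TSV file
#'
#' @param profile A [signature_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# reference_id: ", profile$reference_id),
               paste0("# numbering_scheme: ", profile$numbering_scheme),
               "reference_position\texpected_base",
               paste(profile$positions, profile$expected_bases, sep = "\t")),
             con)
  invisible(path)
}
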