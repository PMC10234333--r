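# Sequence containers and FASTA / metadata IO.
#
# A SequenceRecord is a plain list (id, description, sequence, kind); sets of
# records are kept as unnamed lists so duplicate-id detection stays explicit.

#' Create a sequence record
#'
#' The elementary container used throughout the package: an identifier, an
#' optional free-text description, and an upper-case sequence over the
#' nucleotide alphabet (A, C, G, T, N) or the 20 amino acids plus X.
#'
#' @param id Record identifier; must be non-empty and contain no whitespace.
#' @param sequence Sequence string; lower-case input is normalized.
#' @param kind `"nucleotide"` or `"protein"`.
#' @param description Optional free-text description.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, sequence, kind = c("nucleotide", "protein"),
                            description = "") {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("record id must be a non-empty string")
  if (grepl("\\s", id)) stop("record id must not contain whitespace: ", id)
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("record '", id, "' has an empty sequence")
  sequence <- toupper(sequence)
  alphabet <- if (kind == "nucleotide") NUC_ALPHABET else AA_ALPHABET
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, alphabet)
  if (length(bad) && kind == "nucleotide") {
    # IUPAC ambiguity codes are accepted on input but collapsed to N: the
    # screening rules treat any ambiguity as an uncovered state anyway
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
    if (all(bad %in% iupac)) {
      sequence <- chartr(paste(iupac, collapse = ""),
                         strrep("N", length(iupac)), sequence)
      sequence <- gsub("U", "T", sequence, fixed = TRUE)
      bad <- character()
    }
  }
  if (length(bad))
    stop("record '", id, "' contains invalid ", kind, " characters: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, description = description, sequence = sequence,
                 kind = kind),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<%s record '%s': %d residues>\n", x$kind, x$id,
              nchar(x$sequence)))
  invisible(x)
}

seq_lengths <- function(records) vapply(records, function(r) nchar(r$sequence), 0L)
record_ids <- function(records) vapply(records, `[[`, "", "id")

#' Read a FASTA file into a list of sequence records
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that enforces the
#' package's record invariants: unique non-empty ids, non-empty sequences,
#' upper-cased residues, and an alphabet consistent with `kind`.
#'
#' @param path Path to a FASTA file.
#' @param kind `"nucleotide"` or `"protein"`.
#' @return A list of [sequence_record()] objects, in file order.
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file has no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("malformed FASTA header (empty id) at record ",
         which(!nzchar(ids))[1], " in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id in ", path, ": ", dup[1])
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("record '", ids[which(empty)[1]], "' in ", path,
         " has an empty sequence")
  mapply(function(i, s, d) sequence_record(i, s, kind = kind, description = d),
         ids, seqs, desc, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' Sequences are wrapped at 60 columns; ids and descriptions are written
#' unmodified. Writing then reading back is the identity on ids and
#' sequences.
#'
#' @param records Non-empty list of [sequence_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0) stop("refusing to write an empty FASTA file")
  if (inherits(records, "sequence_record")) records <- list(records)
  ids <- record_ids(records)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate record id: ", dup[1])
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  desc <- vapply(records, `[[`, "", "description")
  names(set) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Create a genome assembly
#'
#' @param genome_id Unique genome identifier.
#' @param contigs List of nucleotide [sequence_record()]s (or a named
#'   character vector of sequences) with unique ids.
#' @param source_tag Optional free text (e.g. `"isolate"` or `"MAG"`).
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(genome_id, contigs, source_tag = NULL) {
  if (!is.character(genome_id) || !nzchar(genome_id))
    stop("genome_id must be a non-empty string")
  if (is.character(contigs)) {
    ids <- names(contigs) %||% paste0(genome_id, "_c", seq_along(contigs))
    contigs <- mapply(sequence_record, ids, contigs,
                      MoreArgs = list(kind = "nucleotide"), SIMPLIFY = FALSE,
                      USE.NAMES = FALSE)
  }
  if (length(contigs) == 0) stop("assembly '", genome_id, "' has no contigs")
  kinds <- vapply(contigs, `[[`, "", "kind")
  if (any(kinds != "nucleotide"))
    stop("assembly contigs must be nucleotide records")
  ids <- record_ids(contigs)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate contig id in '", genome_id, "': ", dup[1])
  structure(list(genome_id = genome_id, contigs = contigs,
                 source_tag = source_tag),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome assembly '%s': %d contig(s), %s bp%s>\n", x$genome_id,
              length(x$contigs),
              format(sum(seq_lengths(x$contigs)), big.mark = ","),
              if (is.null(x$source_tag)) "" else paste0(", ", x$source_tag)))
  invisible(x)
}

#' Create a proteome
#'
#' @param genome_id Genome identifier the proteins belong to.
#' @param proteins List of protein [sequence_record()]s (or a named character
#'   vector) with unique ids.
#' @return An object of class `proteome`.
#' @export
proteome <- function(genome_id, proteins) {
  if (!is.character(genome_id) || !nzchar(genome_id))
    stop("genome_id must be a non-empty string")
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0(genome_id, "_p", seq_along(proteins))
    proteins <- mapply(sequence_record, ids, proteins,
                       MoreArgs = list(kind = "protein"), SIMPLIFY = FALSE,
                       USE.NAMES = FALSE)
  }
  if (length(proteins) == 0) stop("proteome '", genome_id, "' is empty")
  kinds <- vapply(proteins, `[[`, "", "kind")
  if (any(kinds != "protein")) stop("proteome entries must be protein records")
  ids <- record_ids(proteins)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate protein id in '", genome_id, "': ", dup[1])
  structure(list(genome_id = genome_id, proteins = proteins),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome '%s': %d proteins>\n", x$genome_id,
              length(x$proteins)))
  invisible(x)
}

#' Cut a genome assembly into consecutive ANIb fragments
#'
#' Each contig is cut left to right into non-overlapping windows of
#' `fragment_length` (1,020 bp by default, the canonical ANIb fragment
#' scheme). A terminal remainder shorter than the fragment length is kept if
#' it is at least 100 bp, otherwise dropped. Coordinates are 0-based
#' half-open and recorded on every fragment, so concatenating a contig's
#' fragments (plus any dropped tail) reconstructs the contig exactly.
#'
#' @param assembly A [genome_assembly()].
#' @param fragment_length Window size in bp (>= 100).
#' @return A data.frame with columns `fragment_id`, `parent_contig`, `start`,
#'   `end` (0-based half-open) and `sequence`.
#' @export
fragment_assembly <- function(assembly, fragment_length = 1020L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  fragment_length <- as.integer(fragment_length)
  if (fragment_length < 100) stop("fragment_length must be >= 100")
  out <- lapply(assembly$contigs, function(ct) {
    len <- nchar(ct$sequence)
    starts <- seq.int(0L, by = fragment_length,
                      length.out = max(1L, ceiling(len / fragment_length)))
    ends <- pmin(starts + fragment_length, len)
    keep <- (ends - starts) >= 100L
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    data.frame(
      fragment_id = sprintf("%s:%d-%d", ct$id, starts, ends),
      parent_contig = ct$id, start = starts, end = ends,
      sequence = substring(ct$sequence, starts + 1L, ends),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(fragment_id = character(), parent_contig = character(),
                      start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a strain metadata table
#'
#' Tab-separated table with columns `strain_id`, `label`, `source_tags`
#' (comma-separated, may be empty) and `geography`; extra columns are kept.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with `source_tags` parsed into a list column.
#' @export
read_strain_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("strain_id", "label", "source_tags", "geography")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("strain metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$strain_id))
    stop("duplicate strain_id in ", path)
  tab$source_tags <- lapply(strsplit(tab$source_tags, ","),
                            function(x) trimws(x[nzchar(trimws(x))]))
  tab
}
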