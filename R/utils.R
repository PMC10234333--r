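# Internal helpers shared across modules.

.datatable.aware <- TRUE

# data.table non-standard-evaluation symbols
utils::globalVariables(c("kmer", "prot", "i.prot", "N", "a", "b", "query_id",
                         "subject_id", "query_genome", "subject_genome",
                         "score", "identity_pct", "genome_a", "genome_b",
                         ".SD"))

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Run an expression with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive an independent sub-stream seed from a master seed and a scenario tag
#'
#' FNV-1a over the tag, folded with the master seed and reduced below 2^31 so
#' each named scenario gets its own reproducible stream.
#' @noRd
scenario_seed <- function(seed, tag) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(tag)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629 + 1)
}

#' Short stable hash of an R object (FNV-1a over its serialization)
#' @noRd
object_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261 %% 2147483647
  # fold in 1024-byte strides so large objects stay cheap to hash
  idx <- unique(c(seq(1, length(raw), by = max(1L, length(raw) %/% 1024L)),
                  length(raw)))
  for (b in as.integer(raw[idx])) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h %% 4294967291 %% 2^31))
}

#' Encode a sequence string as 0-based integer codes over an alphabet
#' @noRd
encode_seq <- function(seq, alphabet) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], alphabet) - 1L
  if (anyNA(codes)) {
    bad <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
    bad <- setdiff(bad, alphabet)
    stop("sequence contains characters outside the alphabet: ",
         paste(bad, collapse = ", "))
  }
  codes
}

#' Nucleotide scoring matrix for the built-in local aligner
#'
#' match +1, mismatch -1; N never matches anything (scored as mismatch).
#' @noRd
nuc_submat <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 5, 5, dimnames = list(NUC_ALPHABET, NUC_ALPHABET))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch
  m
}

#' BLOSUM62 reordered to the package's amino-acid code order, X as ambiguity
#' @noRd
aa_submat <- function() {
  b62 <- get_blosum62()
  m <- b62[AA_ALPHABET, AA_ALPHABET]
  m["X", ] <- -1
  m[, "X"] <- -1
  m
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Reverse complement of an upper-case nucleotide string (N-safe)
#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_nuc <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET[1:20], n, replace = TRUE), collapse = "")
}

#' Round half up to the nearest integer (the convention used for reported
#' percentages, so 60.5 prints as 61)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
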