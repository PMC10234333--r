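# Synthetic-data generators with serialized ground truth. Every generator
# is a pure function of its arguments (seed included); independent named
# RNG streams are derived from the master seed so adding a scenario never
# perturbs another.

#' Simulate a genome pair at a controlled substitution rate
#'
#' Draws an ancestor uniformly over A/C/G/T and copies it with i.i.d.
#' substitutions (always to a different base) at the given rate. No indels
#' are introduced, so per-fragment mismatch counts are exact and the
#' expected ANIb is 100 (1 - rate).
#'
#' @param length Genome length in bp.
#' @param substitution_rate Per-site substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param fragment_length Fragment size used for the per-fragment truth.
#' @return A list of class `sim_genome_pair`: `a`, `b`
#'   ([genome_assembly()]s) and `truth` (realized mismatch positions and
#'   per-fragment counts).
#' @export
simulate_genome_pair <- function(length, substitution_rate, seed,
                                 fragment_length = 1020L) {
  stopifnot(length >= 200, substitution_rate >= 0, substitution_rate <= 1)
  if (substitution_rate > 0.5)
    warning("substitution rates above 0.5 will make ANIb hit filters ",
            "discard most fragments")
  bases <- c("A", "C", "G", "T")
  sim <- with_seed(scenario_seed(seed, "genome_pair"), {
    anc <- sample(bases, length, replace = TRUE)
    mut_at <- which(runif(length) < substitution_rate)
    der <- anc
    for (i in mut_at) der[i] <- sample(setdiff(bases, anc[i]), 1)
    list(anc = anc, der = der, mut_at = mut_at)
  })
  a <- genome_assembly("simA", setNames(paste(sim$anc, collapse = ""),
                                        "simA_c1"), source_tag = "isolate")
  b <- genome_assembly("simB", setNames(paste(sim$der, collapse = ""),
                                        "simB_c1"), source_tag = "isolate")
  frag <- fragment_assembly(a, fragment_length)
  per_frag <- vapply(seq_len(nrow(frag)), function(i)
    sum(sim$mut_at > frag$start[i] & sim$mut_at <= frag$end[i]), 0L)
  structure(list(a = a, b = b,
                 truth = list(scenario = "genome_pair", seed = seed,
                              substitution_rate = substitution_rate,
                              n_substitutions = length(sim$mut_at),
                              mutated_positions = sim$mut_at,
                              fragment_mismatches = setNames(
                                per_frag, frag$fragment_id))),
            class = "sim_genome_pair")
}

#' Simulate a pan-genome occupancy matrix with known asymptotics
#'
#' Every genome carries all `omega_true` core clusters. The g-th genome
#' (in creation order) additionally founds `round(kappa_true *
#' exp(-g / tau_true))` epoch clusters, each propagated to every later
#' genome independently with probability `retention`, plus `theta_true`
#' strictly private clusters (occupancy one). Under random genome
#' orderings the expected asymptotic new-gene discovery rate of this
#' process equals `theta_true`, and the core size at the full genome count
#' is exactly `omega_true` — the two quantities the exponential fits
#' estimate.
#'
#' @param n_genomes Number of genomes (>= 5).
#' @param omega_true Core-genome size.
#' @param theta_true New (private) gene clusters per genome.
#' @param kappa_true,tau_true Amplitude and decay constant of the epoch
#'   (shared accessory) cluster process.
#' @param retention Propagation probability of an epoch cluster into each
#'   later genome.
#' @param seed RNG seed.
#' @return A list of class `sim_pangenome`: `matrix` (a
#'   [pangenome_matrix()]) and `truth`.
#' @export
simulate_pangenome <- function(n_genomes, omega_true = 3000,
                               theta_true = 25, kappa_true = 2000,
                               tau_true = 3, retention = 0.5, seed) {
  stopifnot(n_genomes >= 5, omega_true >= 0, theta_true >= 0,
            kappa_true >= 0, tau_true > 0, retention >= 0, retention <= 1)
  occ <- with_seed(scenario_seed(seed, "pangenome"), {
    blocks <- list(matrix(1L, nrow = omega_true, ncol = n_genomes))
    for (g in seq_len(n_genomes)) {
      n_epoch <- round(kappa_true * exp(-g / tau_true))
      if (n_epoch > 0) {
        m <- matrix(0L, nrow = n_epoch, ncol = n_genomes)
        m[, g] <- 1L
        if (g < n_genomes) {
          later <- seq.int(g + 1L, n_genomes)
          m[, later] <- matrix(
            as.integer(runif(n_epoch * length(later)) < retention),
            nrow = n_epoch)
        }
        blocks[[length(blocks) + 1]] <- m
      }
      if (theta_true > 0) {
        m <- matrix(0L, nrow = theta_true, ncol = n_genomes)
        m[, g] <- 1L
        blocks[[length(blocks) + 1]] <- m
      }
    }
    do.call(rbind, blocks)
  })
  rownames(occ) <- sprintf("clu_%05d", seq_len(nrow(occ)))
  colnames(occ) <- sprintf("g%03d", seq_len(n_genomes))
  structure(list(matrix = pangenome_matrix(occ),
                 truth = list(scenario = "pangenome", seed = seed,
                              omega = omega_true, theta = theta_true,
                              kappa = kappa_true, tau = tau_true,
                              retention = retention,
                              n_clusters = nrow(occ))),
            class = "sim_pangenome")
}

mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA_ALPHABET[1:20], chars[i]), 1)
  paste(chars, collapse = "")
}

#' Simulate proteomes built from protein families with controlled identity
#'
#' Each family has a random ancestor; every copy mutates the ancestor at a
#' per-residue rate of `(1 - within_identity) / 2`, so the expected
#' pairwise identity between two family members is about
#' `within_identity`. Between-family identity is that of independent
#' random sequences (far below any clustering threshold). Presence of
#' families in genomes is controlled by a 0/1 `presence` matrix (all
#' present by default) and `copy_number` per family.
#'
#' @param n_genomes Number of genomes.
#' @param n_families Number of protein families.
#' @param within_identity Target within-family pairwise identity (0-1).
#' @param presence Optional `n_families x n_genomes` 0/1 matrix.
#' @param copy_number Integer vector (length `n_families`) of copies per
#'   genome where present; default 1.
#' @param length_range Range of ancestor lengths.
#' @param seed RNG seed.
#' @return A list of class `sim_proteomes`: `proteomes` (list of
#'   [proteome()]) and `truth` (family of every protein).
#' @export
simulate_proteomes <- function(n_genomes, n_families, within_identity = 0.9,
                               presence = NULL, copy_number = NULL,
                               length_range = c(180L, 300L), seed) {
  stopifnot(n_genomes >= 2, n_families >= 1,
            within_identity > 0, within_identity <= 1)
  # random-sequence background identity is ~0.05-0.25 locally; require the
  # separation gap the clustering tests rely on
  if (within_identity < 0.6)
    stop("within_identity must stay well above the random background ",
         "(need within > between + 0.2)")
  if (is.null(presence))
    presence <- matrix(1L, n_families, n_genomes)
  stopifnot(nrow(presence) == n_families, ncol(presence) == n_genomes)
  if (is.null(copy_number)) copy_number <- rep(1L, n_families)
  rate <- (1 - within_identity) / 2
  genome_ids <- sprintf("g%02d", seq_len(n_genomes))
  out <- with_seed(scenario_seed(seed, "proteomes"), {
    anc <- vapply(seq_len(n_families), function(f)
      random_aa(sample(seq.int(length_range[1], length_range[2]), 1)), "")
    prots <- vector("list", n_genomes)
    fam_of <- character()
    for (g in seq_len(n_genomes)) {
      seqs <- character(); ids <- character()
      for (f in seq_len(n_families)) {
        if (presence[f, g] == 0) next
        for (cp in seq_len(copy_number[f])) {
          id <- sprintf("%s_f%03d_c%d", genome_ids[g], f, cp)
          ids <- c(ids, id)
          seqs <- c(seqs, mutate_protein(anc[f], rate))
          fam_of[id] <- sprintf("fam%03d", f)
        }
      }
      prots[[g]] <- proteome(genome_ids[g], setNames(seqs, ids))
    }
    list(proteomes = prots, fam_of = fam_of, ancestors = anc)
  })
  structure(list(proteomes = out$proteomes,
                 truth = list(scenario = "proteomes", seed = seed,
                              family_of = out$fam_of,
                              presence = presence,
                              copy_number = copy_number,
                              within_identity = within_identity,
                              genome_ids = genome_ids)),
            class = "sim_proteomes")
}

#' Simulate a 16S panel with planted signature structure
#'
#' Generates a reference sequence, plants `n_positions` signature
#' positions inside the screening region, and draws an in-group whose
#' members keep every signature state (mutating only a handful of
#' non-signature sites, so they stay above the 99.6 % screening identity)
#' and an out-group whose members each miss at least one signature state.
#' One designated position (the planted analogue of the single exclusive
#' site) is mutated in every out-group sequence; every other position is
#' guaranteed to be carried by at least one out-group sequence, so exactly
#' one position is exclusive. Half of the out-group carries only signature
#' mutations (and therefore passes the identity step before failing the
#' signature check); the other half additionally diverges at
#' `background_rate` across non-signature sites.
#'
#' @param n_ingroup,n_outgroup Panel sizes (>= 2 each).
#' @param n_positions Number of signature positions (default 37).
#' @param region Reference region containing the positions (default
#'   `c(50, 650)`).
#' @param seq_length Reference length (default 1540).
#' @param background_rate Non-signature substitution rate of the divergent
#'   out-group half.
#' @param seed RNG seed.
#' @return A list of class `sim_16s_panel`: `reference`, `profile`,
#'   `ingroup`, `outgroup`, `truth`.
#' @export
simulate_16s_panel <- function(n_ingroup = 8L, n_outgroup = 12L,
                               n_positions = 37L, region = c(50L, 650L),
                               seq_length = 1540L, background_rate = 0.02,
                               seed) {
  stopifnot(n_ingroup >= 2, n_outgroup >= 2, n_positions >= 2,
            region[2] - region[1] + 1 >= 3 * n_positions)
  bases <- c("A", "C", "G", "T")
  res <- with_seed(scenario_seed(seed, "panel16s"), {
    ref <- sample(bases, seq_length, replace = TRUE)
    positions <- sort(sample(seq.int(region[1], region[2]), n_positions))
    expected <- ref[positions]
    exclusive_idx <- sample.int(n_positions, 1)
    mutate_site <- function(chars, at) {
      for (i in at) chars[i] <- sample(setdiff(bases, chars[i]), 1)
      chars
    }
    non_sig <- setdiff(seq_len(seq_length), positions)
    non_sig_in_region <- intersect(non_sig, seq.int(region[1], region[2]))
    ingroup <- lapply(seq_len(n_ingroup), function(i) {
      chars <- ref
      n_in <- sample(0:2, 1)
      n_out <- sample(0:5, 1)
      at <- c(sample(non_sig_in_region, n_in),
              sample(setdiff(non_sig, non_sig_in_region), n_out))
      sequence_record(sprintf("in_%02d", i), paste(mutate_site(ref, at),
                                                   collapse = ""))
    })
    # decide which signature positions each out-group sequence loses;
    # the exclusive one is lost by all
    lost <- matrix(FALSE, n_outgroup, n_positions)
    lost[, exclusive_idx] <- TRUE
    for (s in seq_len(n_outgroup)) {
      k <- sample(0:min(4, n_positions - 1), 1)
      lost[s, sample(setdiff(seq_len(n_positions), exclusive_idx),
                     k)] <- TRUE
    }
    # repair: every non-exclusive position must be kept by someone
    for (p in setdiff(seq_len(n_positions), exclusive_idx)) {
      if (all(lost[, p])) lost[1, p] <- FALSE
    }
    outgroup <- lapply(seq_len(n_outgroup), function(s) {
      chars <- mutate_site(ref, positions[lost[s, ]])
      if (s > n_outgroup %/% 2) {
        at <- non_sig[runif(length(non_sig)) < background_rate]
        chars <- mutate_site(chars, at)
      }
      sequence_record(sprintf("out_%02d", s), paste(chars, collapse = ""))
    })
    list(ref = ref, positions = positions, expected = expected,
         exclusive_idx = exclusive_idx, lost = lost,
         ingroup = ingroup, outgroup = outgroup)
  })
  reference <- sequence_record("ref_16s", paste(res$ref, collapse = ""))
  profile <- signature_profile(res$positions, res$expected,
                               reference_id = reference$id,
                               numbering_scheme = "reference coordinates")
  structure(list(reference = reference, profile = profile,
                 ingroup = res$ingroup, outgroup = res$outgroup,
                 truth = list(scenario = "panel16s", seed = seed,
                              exclusive_position =
                                res$positions[res$exclusive_idx],
                              lost_positions = res$lost,
                              n_positions = n_positions)),
            class = "sim_16s_panel")
}

#' Write a simulated scenario's inputs and ground truth to a directory
#'
#' FASTA/TSV inputs plus a `ground_truth.json` (seed included) sufficient
#' to score the downstream modules without rerunning the generator.
#'
#' @param sim A result of one of the `simulate_*` generators.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim$truth
  if (inherits(sim, "sim_genome_pair")) {
    write_fasta(sim$a$contigs, file.path(dir, "genome_a.fasta"))
    write_fasta(sim$b$contigs, file.path(dir, "genome_b.fasta"))
  } else if (inherits(sim, "sim_pangenome")) {
    write.table(sim$matrix$occupancy, file.path(dir, "occupancy.tsv"),
                sep = "\t", quote = FALSE)
  } else if (inherits(sim, "sim_proteomes")) {
    for (p in sim$proteomes)
      write_fasta(p$proteins, file.path(dir, paste0(p$genome_id, ".faa")))
  } else if (inherits(sim, "sim_16s_panel")) {
    write_fasta(c(list(sim$reference), sim$ingroup, sim$outgroup),
                file.path(dir, "panel.fasta"))
    write_signature_profile(sim$profile, file.path(dir, "profile.tsv"))
  } else stop("not a simulated scenario object")
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
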