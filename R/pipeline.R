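# End-to-end orchestration over synthetic inputs, plus the strain-collection
# bookkeeping: evidence merging and per-source-tag summaries.

#' Configuration for an end-to-end synthetic run
#'
#' Validates and freezes every stage's parameters; all stochastic stages
#' derive their streams from the single `seed`. The defaults describe a
#' compact desk-scale demonstration (a few small genomes per planted
#' species, a 10-family proteome set, a 20-genome occupancy process, a
#' standard 16S panel).
#'
#' @param seed Master RNG seed (mandatory).
#' @param output_dir Directory all artifacts are written into.
#' @param stages Character subset of
#'   `c("anib", "pangenome", "curves", "phylo", "signature")`.
#' @param anib_params [anib_params()] for the ANI stage.
#' @param thresholds [similarity_thresholds()] for the proteome stage.
#' @param screening [screening_thresholds()] for the signature stage.
#' @param anib_n_species,anib_genomes_per_species Number of planted species
#'   and genomes per species in the ANI stage.
#' @param anib_genome_length Simulated genome length (bp) in the ANI stage.
#' @param anib_within_rate,anib_between_rate Within- and between-species
#'   substitution rates of the ANI-stage scenario.
#' @param prot_n_genomes,prot_n_families Proteome-stage scenario sizes.
#' @param curve_n_genomes,curve_n_permutations Curve-stage sizes.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, output_dir = tempfile("stutzpan_run_"),
                            stages = c("anib", "pangenome", "curves",
                                       "phylo", "signature"),
                            anib_params = stutzpan::anib_params(),
                            thresholds = similarity_thresholds(),
                            screening = screening_thresholds(),
                            anib_n_species = 3L,
                            anib_genomes_per_species = 2L,
                            anib_genome_length = 20400L,
                            anib_within_rate = 0.01,
                            anib_between_rate = 0.12,
                            prot_n_genomes = 5L, prot_n_families = 10L,
                            curve_n_genomes = 20L,
                            curve_n_permutations = 30L) {
  if (missing(seed)) stop("a seed is required")
  stages <- match.arg(stages, c("anib", "pangenome", "curves", "phylo",
                                "signature"), several.ok = TRUE)
  cfg <- list(seed = as.integer(seed), output_dir = output_dir,
              stages = stages, anib_params = anib_params,
              thresholds = thresholds, screening = screening,
              anib_n_species = anib_n_species,
              anib_genomes_per_species = anib_genomes_per_species,
              anib_genome_length = anib_genome_length,
              anib_within_rate = anib_within_rate,
              anib_between_rate = anib_between_rate,
              prot_n_genomes = prot_n_genomes,
              prot_n_families = prot_n_families,
              curve_n_genomes = curve_n_genomes,
              curve_n_permutations = curve_n_permutations)
  class(cfg) <- "pipeline_config"
  cfg
}

# Simulate a small multi-species genome set for the ANI stage: one grand
# ancestor, species ancestors at `between_rate` from it, genomes at
# `within_rate` from their species ancestor.
simulate_species_set <- function(n_species, genomes_per_species, length,
                                 within_rate, between_rate, seed) {
  bases <- c("A", "C", "G", "T")
  with_seed(scenario_seed(seed, "species_set"), {
    mutate <- function(chars, rate) {
      at <- which(runif(length(chars)) < rate)
      for (i in at) chars[i] <- sample(setdiff(bases, chars[i]), 1)
      chars
    }
    grand <- sample(bases, length, replace = TRUE)
    assemblies <- list()
    truth <- character()
    for (sp in seq_len(n_species)) {
      anc <- mutate(grand, between_rate)
      for (g in seq_len(genomes_per_species)) {
        gid <- sprintf("sp%02d_g%02d", sp, g)
        assemblies[[gid]] <- genome_assembly(
          gid, setNames(paste(mutate(anc, within_rate), collapse = ""),
                        paste0(gid, "_c1")))
        truth[gid] <- sprintf("sp%02d", sp)
      }
    }
    list(assemblies = unname(assemblies), species_of = truth)
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order on freshly generated
#' synthetic inputs, writes every artifact under the configured output
#' directory, and returns a run report. Reruns with the same configuration
#' reproduce all artifacts.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`: per-stage artifact paths, the
#'   seed, a reproducible configuration hash, and per-stage wall-clock
#'   seconds.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list(); timings <- numeric(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  opath <- function(...) file.path(config$output_dir, ...)

  if ("anib" %in% config$stages) {
    stage("anib", {
      set <- simulate_species_set(
        config$anib_n_species, config$anib_genomes_per_species,
        config$anib_genome_length, config$anib_within_rate,
        config$anib_between_rate, config$seed)
      m <- build_ani_matrix(set$assemblies, config$anib_params)
      cl <- cluster_genomospecies(m, config$anib_params$species_threshold_pct)
      write.table(round(unclass(m), 3), opath("ani_matrix.tsv"), sep = "\t",
                  quote = FALSE)
      write_ani_long(m, opath("ani_pairs.tsv"))
      writeLines(vapply(cl, paste, "", collapse = "\t"),
                 opath("ani_clusters.tsv"))
      dnd <- ani_dendrogram(m)
      write_newick(dnd, opath("ani_dendrogram.nwk"))
      list(matrix = m, clusters = cl)
    })
    artifacts$anib <- c(opath("ani_matrix.tsv"), opath("ani_pairs.tsv"),
                        opath("ani_clusters.tsv"),
                        opath("ani_dendrogram.nwk"))
  }

  if ("pangenome" %in% config$stages) {
    stage("pangenome", {
      sim <- simulate_proteomes(config$prot_n_genomes,
                                config$prot_n_families, seed = config$seed)
      hits <- all_vs_all_hits(sim$proteomes, config$thresholds)
      genome_ids <- vapply(sim$proteomes, `[[`, "", "genome_id")
      bd <- bdbh_cluster(hits, sim$proteomes, genome_ids[1])
      ct <- cog_triangles_cluster(hits)
      om <- omcl_cluster(hits)
      core <- consensus_core(bd, ct, om, genome_ids)
      pan <- pan_genome_clusters(om, ct, sim$proteomes)
      pm <- compartmentalize(pan, genome_ids)
      write.table(pm$occupancy, opath("pangenome_matrix.tsv"), sep = "\t",
                  quote = FALSE)
      writeLines(vapply(core, `[[`, "", "cluster_id"),
                 opath("consensus_core.txt"))
      list(matrix = pm, core = core)
    })
    artifacts$pangenome <- c(opath("pangenome_matrix.tsv"),
                             opath("consensus_core.txt"))
  }

  if ("curves" %in% config$stages) {
    stage("curves", {
      sim <- simulate_pangenome(config$curve_n_genomes, seed = config$seed)
      curve <- sample_gene_discovery(sim$matrix,
                                     config$curve_n_permutations,
                                     seed = config$seed)
      cf <- fit_core(curve, "tettelin")
      pf <- fit_pan(curve, "tettelin")
      write_curve_tsv(curve, opath("discovery_curve.tsv"))
      jsonlite::write_json(
        list(core = c(as.list(coef(cf)), rss = cf$rss, model = cf$model),
             pan = c(as.list(coef(pf)), rss = pf$rss, model = pf$model),
             truth = sim$truth[c("omega", "theta")]),
        opath("fits.json"), auto_unbox = TRUE, digits = NA)
      list(core_fit = cf, pan_fit = pf, truth = sim$truth)
    })
    artifacts$curves <- c(opath("discovery_curve.tsv"), opath("fits.json"))
  }

  if ("signature" %in% config$stages || "phylo" %in% config$stages) {
    panel <- simulate_16s_panel(seed = config$seed)
  }

  if ("phylo" %in% config$stages) {
    stage("phylo", {
      aln <- multiple_alignment(c(list(panel$reference), panel$ingroup,
                                  panel$outgroup))
      tree <- bootstrap_support(aln, n_replicates = 100,
                                seed = config$seed)
      write_newick(tree, opath("panel_nj.nwk"))
    })
    artifacts$phylo <- opath("panel_nj.nwk")
  }

  if ("signature" %in% config$stages) {
    stage("signature", {
      verdicts <- lapply(c(panel$ingroup, panel$outgroup), screen_sequence,
                         reference = panel$reference,
                         profile = panel$profile,
                         thresholds = config$screening)
      tab <- do.call(rbind, lapply(verdicts, function(v)
        data.frame(sequence_id = v$sequence_id, step1 = v$step1,
                   identity_pct = round(v$identity_pct, 3),
                   coverage = round(v$coverage, 4),
                   positions_matched = v$positions_matched,
                   verdict = v$verdict)))
      write.table(tab, opath("screening_report.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_signature_profile(panel$profile, opath("profile.tsv"))
    })
    artifacts$signature <- c(opath("screening_report.tsv"),
                             opath("profile.tsv"))
  }

  report <- structure(
    list(artifacts = artifacts, seed = config$seed,
         config_hash = object_hash(unclass(config)), timings = timings,
         output_dir = config$output_dir),
    class = "run_report")
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash,
         timings = as.list(report$timings),
         artifacts = lapply(artifacts, basename)),
    opath("run_manifest.json"), auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<pipeline run (seed %d, config %s) in %s>\n", x$seed,
              x$config_hash, x$output_dir))
  for (s in names(x$artifacts))
    cat(sprintf("  %-10s %s\n", s,
                paste(basename(x$artifacts[[s]]), collapse = ", ")))
  invisible(x)
}

#' Merge genome- and screening-confirmed strain lists
#'
#' Union of the two evidence routes; a strain present in both is kept once
#' with evidence `"both"`. Conflicting metadata (same strain, same column,
#' different non-missing values) is an error.
#'
#' @param genome_confirmed,screening_confirmed Data frames with a unique
#'   `strain_id` column plus optional metadata columns.
#' @return A data.frame with an `evidence` column
#'   (`"genome"`/`"screening"`/`"both"`).
#' @export
merge_strain_evidence <- function(genome_confirmed, screening_confirmed) {
  check <- function(df, nm) {
    if (nrow(df) && anyDuplicated(df$strain_id))
      stop("duplicate strain_id in ", nm, " list")
    df
  }
  g <- check(genome_confirmed, "genome")
  s <- check(screening_confirmed, "screening")
  shared <- intersect(g$strain_id, s$strain_id)
  meta_cols <- intersect(setdiff(names(g), "strain_id"),
                         setdiff(names(s), "strain_id"))
  for (id in shared) {
    for (cc in meta_cols) {
      gv <- g[[cc]][g$strain_id == id]
      sv <- s[[cc]][s$strain_id == id]
      if (!is.na(gv) && !is.na(sv) && !identical(gv, sv))
        stop("conflicting metadata for strain '", id, "' column '", cc, "'")
    }
  }
  g$evidence <- ifelse(g$strain_id %in% shared, "both", "genome")
  s_only <- s[!(s$strain_id %in% shared), , drop = FALSE]
  if (nrow(s_only)) s_only$evidence <- "screening"
  all_cols <- union(names(g), names(s_only))
  pad <- function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- rep(NA, nrow(df))
    df[all_cols]
  }
  out <- rbind(pad(g), pad(s_only))
  rownames(out) <- NULL
  out
}

#' Summarize strain counts and percentages per source tag
#'
#' For every tag: the strain count, the denominator (strains carrying any
#' source information), and the percentage rounded half-up to the nearest
#' integer. Conditional requests (e.g. marine among aquatic) are computed
#' within the parent tag's strains. Strains may carry several tags, so
#' percentages need not sum to 100.
#'
#' @param table Data frame with `strain_id` and a `source_tags` list
#'   column.
#' @param conditional Named character vector `child = parent` of
#'   conditional percentages to add.
#' @return A data.frame (`tag`, `count`, `denominator`, `pct`).
#' @export
summarize_strain_sources <- function(table, conditional = c()) {
  if (!nrow(table)) stop("empty strain table")
  tags <- table$source_tags
  has_info <- lengths(tags) > 0
  denom <- sum(has_info)
  all_tags <- sort(unique(unlist(tags)))
  rows <- lapply(all_tags, function(tg) {
    cnt <- sum(vapply(tags, function(x) tg %in% x, TRUE))
    data.frame(tag = tg, count = cnt, denominator = denom,
               pct = round_half_up(100 * cnt / denom))
  })
  out <- do.call(rbind, rows)
  for (child in names(conditional)) {
    parent <- conditional[[child]]
    if (!(parent %in% all_tags) || !(child %in% all_tags))
      stop("unknown tag in conditional request: ", child, " within ", parent)
    in_parent <- vapply(tags, function(x) parent %in% x, TRUE)
    cnt <- sum(vapply(tags[in_parent], function(x) child %in% x, TRUE))
    out <- rbind(out, data.frame(
      tag = paste0(child, "|", parent), count = cnt,
      denominator = sum(in_parent),
      pct = round_half_up(100 * cnt / sum(in_parent))))
  }
  rownames(out) <- NULL
  out
}

#' The known strain collection of Stutzerimonas balearica
#'
#' A compact reconstruction of the species' strain collection as a strain
#' table: 176 strains (18 confirmed by genome sequence, 158 by two-step 16S
#' screening), of which 164 carry source information distributed over
#' overlapping environment tags (polluted/anthropogenic, wastewater or
#' sludge, petroleum-related, aquatic with a marine subset, plants, fungal,
#' animals, human). Individual strain identities are placeholders; the
#' per-tag margins are the collection's documented totals, which is what
#' the summary arithmetic consumes.
#'
#' @return A data.frame with `strain_id`, `evidence` and a `source_tags`
#'   list column.
#' @export
balearica_strain_sources <- function() {
  n <- 176L
  tags <- replicate(n, character(), simplify = FALSE)
  add <- function(tags, idx, tag) {
    for (i in idx) tags[[i]] <- c(tags[[i]], tag)
    tags
  }
  tags <- add(tags, 1:89, "aquatic")
  tags <- add(tags, 1:49, "marine")
  tags <- add(tags, 41:140, "polluted_anthropogenic")
  tags <- add(tags, 57:78, "wastewater_sludge")
  tags <- add(tags, 79:140, "petroleum")
  tags <- add(tags, 141:153, "plants")
  tags <- add(tags, 154:160, "animals")
  tags <- add(tags, 161:163, "human")
  tags <- add(tags, 164, "fungal")
  data.frame(strain_id = sprintf("SB%03d", seq_len(n)),
             evidence = rep(c("genome", "screening"), c(18L, 158L)),
             source_tags = I(tags))
}
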