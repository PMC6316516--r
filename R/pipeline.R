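# Configuration and the simulate -> analyze -> report pipeline.

#' Pipeline configuration
#'
#' Bundles the thresholds and simulation parameters of the whole pipeline
#' with full defaulting. Thresholds: quality/length for read filtering, the
#' 5% mapping-error rule, the p < 0.001 reciprocal-merge rule, and a warning
#' floor on mapped pairs per individual (the study reports every individual
#' above 40,000 mapped reads; at simulated desk-scale coverages the warning
#' is informative only).
#'
#' @param seed Integer seed driving every random draw.
#' @param coverage Mean fragments per individual and region.
#' @param conversion,protection,seq_error,read_length See [sim_params()].
#' @param min_quality,min_length See [quality_filter()].
#' @param max_mismatch See [assign_reads()].
#' @param error_threshold Mapping-error rule threshold.
#' @param reciprocal_alpha Merge threshold of [reciprocal_comparison()].
#' @param min_mapped_warn Mapped-pair count below which an individual is
#'   flagged in the log.
#' @return A list of class `methcross_config`.
#' @export
pipeline_config <- function(seed = 1, coverage = 500, conversion = 0.99,
                            protection = 1, seq_error = 0.001,
                            read_length = 150L, min_quality = 20,
                            min_length = 100, max_mismatch = 5,
                            error_threshold = 0.05, reciprocal_alpha = 0.001,
                            min_mapped_warn = 40000) {
  stopifnot(error_threshold >= 0, error_threshold <= 1,
            reciprocal_alpha > 0, reciprocal_alpha < 1,
            min_quality >= 0, min_length >= 1, max_mismatch >= 0)
  params <- sim_params(coverage = coverage, conversion = conversion,
                       protection = protection, seq_error = seq_error,
                       read_length = read_length)
  structure(
    c(list(seed = as.integer(seed)), unclass(params),
      list(min_quality = min_quality, min_length = min_length,
           max_mismatch = max_mismatch, error_threshold = error_threshold,
           reciprocal_alpha = reciprocal_alpha,
           min_mapped_warn = min_mapped_warn)),
    class = "methcross_config"
  )
}

config_params <- function(config) {
  sim_params(coverage = config$coverage, conversion = config$conversion,
             protection = config$protection, seq_error = config$seq_error,
             read_length = config$read_length)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config A [pipeline_config()] list.
#' @return `read_config()` returns a `methcross_config`; `write_config()`
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate the full cross in memory
#'
#' Runs pedigree, profile and read simulation for a design and returns the
#' reads together with the ground truth.
#'
#' @param config A [pipeline_config()].
#' @param design Cross design, default [cross_design()].
#' @param refs Allele references, default [synthetic_references()].
#' @param hyperparams Methylation hyperparameters,
#'   default [default_hyperparams()].
#' @return List with `pedigree`, `profiles` (truth levels), `reads`.
#' @export
simulate_cross <- function(config = pipeline_config(), design = cross_design(),
                           refs = synthetic_references(),
                           hyperparams = default_hyperparams()) {
  pedigree <- simulate_pedigree(design, seed = config$seed)
  profiles <- draw_individual_profiles(pedigree, hyperparams,
                                       seed = config$seed + 1L)
  reads <- simulate_reads(profiles, refs, config_params(config),
                          seed = config$seed + 2L)
  list(pedigree = pedigree, profiles = profiles, reads = reads)
}

#' Simulate the full cross onto disk
#'
#' Writes per-individual paired FASTQ files, the ground-truth table
#' (`sim_truth.tsv`: genotype and true per-allele, per-motif levels), the
#' design, the configuration and a run manifest with the config hash and
#' per-file MD5 checksums, enabling exact replay.
#'
#' @inheritParams simulate_cross
#' @param dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
simulate_dataset <- function(config = pipeline_config(), dir,
                             design = cross_design(),
                             refs = synthetic_references(),
                             hyperparams = default_hyperparams()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cross(config, design, refs, hyperparams)
  write_fastq_pairs(sim$reads, dir)
  readr::write_tsv(sim$profiles, file.path(dir, "sim_truth.tsv"))
  readr::write_tsv(design, file.path(dir, "design.tsv"))
  write_config(config, file.path(dir, "config.yaml"))
  write_manifest(config, dir)
}

write_manifest <- function(config, dir, extra = list()) {
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- c(list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    files = as.list(tools::md5sum(file.path(dir, files)) |>
                      setNames(files))
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

population_of <- function(individual) sub("_[0-9]+$", "", individual)

generation_of <- function(population) {
  dplyr::case_when(
    startsWith(population, "P-") ~ "P",
    startsWith(population, "F1-") ~ "F1",
    startsWith(population, "F2-") ~ "F2",
    TRUE ~ NA_character_
  )
}

#' Analyse a table of read pairs end to end
#'
#' Runs quality filtering, allele assignment, the mapping-error rule,
#' genotype calling, per-site extraction at shared cytosines, weighted
#' methylation, segregation tests (F2), reciprocal-cross comparisons (F1 and
#' F2 by cross direction) and the heterozygote trans-allelic correlation.
#' Population and generation are parsed from the individual IDs
#' (`<population>_<number>`, populations prefixed `P-`/`F1-`/`F2-`).
#'
#' @param pairs Tibble of read pairs with an `individual` column
#'   ([simulate_reads()] output or FASTQ pairs bound per individual).
#' @param config A [pipeline_config()].
#' @param refs Allele references.
#' @return A list of class `methcross_analysis` with elements `mapping`,
#'   `genotypes`, `levels`, `summary`, `segregation`, `reciprocal`,
#'   `correlation` (per region with >= 3 heterozygotes), `shared_sites`,
#'   `snps` and `log` (reconciliation counts).
#' @export
analyze_reads <- function(pairs, config = pipeline_config(),
                          refs = synthetic_references()) {
  if (!nrow(pairs)) abort("no input reads")
  sites <- classify_contexts(refs)
  snps <- find_snps(refs)
  shared <- shared_cytosines(sites, snps)

  kept <- quality_filter(pairs, config$min_quality, config$min_length)
  n_quality_dropped <- attr(kept, "n_dropped")
  assigned <- assign_reads(kept, refs, snps, config$max_mismatch)
  mapping <- summarize_mapping(assigned) |>
    filter_mapping_error(config$error_threshold)
  genotyped <- call_genotypes(mapping, config$error_threshold) |>
    mutate(population = population_of(.data$individual),
           generation = generation_of(.data$population))

  # drop mapping-error pairs of the discarded minor allele
  discard <- genotyped |>
    filter(!is.na(.data$discarded_allele)) |>
    select("individual", "region_id", allele = "discarded_allele")
  scored <- assigned |> anti_join(discard, by = c("individual", "region_id", "allele"))

  counts <- extract_calls(scored, shared)
  levels <- weighted_methylation(counts) |>
    left_join(genotyped |>
                select("individual", "region_id", "population",
                       "generation", "genotype"),
              by = c("individual", "region_id"))

  segregation <- genotyped |>
    filter(.data$generation == "F2") |>
    segregation_test()

  reciprocal <- bind_rows(
    reciprocal_levels(levels, "F1", c("F1-ColxLer", "F1-LerxCol"),
                      config$reciprocal_alpha),
    reciprocal_levels(levels |>
                        mutate(population = sub("-[0-9]+$", "", .data$population)),
                      "F2", c("F2-ColxLer", "F2-LerxCol"),
                      config$reciprocal_alpha)
  )

  # trans-allelic coupling is assessed in the segregating generation only:
  # F2 heterozygotes, not the uniformly heterozygous F1
  f2_levels <- levels |> filter(.data$generation == "F2")
  correlation <- list()
  for (r in unique(shared$region_id)) {
    n_het <- f2_levels |>
      filter(.data$region_id == r, .data$genotype == "CL",
             !is.na(.data$level)) |>
      distinct(.data$individual) |> nrow()
    if (n_het >= 3) correlation[[r]] <- allele_correlation(f2_levels, region = r)
  }

  low <- mapping |> filter(.data$n_mapped < config$min_mapped_warn)
  log <- list(
    n_pairs_in = nrow(pairs),
    n_quality_dropped = n_quality_dropped,
    n_col = sum(mapping$n_col), n_ler = sum(mapping$n_ler),
    n_ambiguous = sum(mapping$n_ambiguous),
    n_unmapped = sum(mapping$n_unmapped),
    n_mapping_error_discarded = sum(mapping$n_discarded),
    n_low_coverage_individuals = nrow(low)
  )

  structure(list(
    mapping = genotyped, genotypes = genotyped |>
      select("individual", "population", "generation", "region_id", "genotype"),
    levels = levels, summary = summarize_population(levels),
    segregation = segregation, reciprocal = reciprocal,
    correlation = correlation, shared_sites = shared, snps = snps,
    log = log
  ), class = "methcross_analysis")
}

reciprocal_levels <- function(levels, generation, pops, alpha) {
  sub <- levels |>
    filter(.data$generation == !!generation, .data$population %in% pops,
           .data$genotype == "CL")
  if (length(unique(sub$population)) != 2) return(tibble())
  reciprocal_comparison(sub, alpha) |>
    mutate(generation = !!generation, .before = 1)
}

#' @export
print.methcross_analysis <- function(x, ...) {
  cat("methcross analysis:",
      length(unique(x$mapping$individual)), "individuals,",
      x$log$n_pairs_in, "read pairs\n")
  cat("  mapped Col/Ler:", x$log$n_col, "/", x$log$n_ler,
      "; ambiguous:", x$log$n_ambiguous,
      "; unmapped:", x$log$n_unmapped,
      "; mapping-error discarded:", x$log$n_mapping_error_discarded, "\n")
  invisible(x)
}

#' Analyse a directory of per-individual FASTQ pairs
#'
#' Expects `<population>_<individual>_R1.fastq` / `_R2.fastq` naming as
#' written by [simulate_dataset()]. Writes every result table as TSV plus a
#' run manifest to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param fastq_dir Directory of paired FASTQ files.
#' @param out_dir Output directory for the result tables.
#' @param refs Allele references.
#' @return The [analyze_reads()] result, invisibly.
#' @export
analyze_dataset <- function(config, fastq_dir, out_dir,
                            refs = synthetic_references()) {
  r1 <- sort(list.files(fastq_dir, pattern = "_R1\\.fastq$", full.names = TRUE))
  if (!length(r1)) {
    abort(sprintf("no paired FASTQ input found in '%s'", fastq_dir),
          class = "methcross_user_error")
  }
  pairs <- purrr::map(r1, function(f1) {
    f2 <- sub("_R1\\.fastq$", "_R2.fastq", f1)
    ind <- sub("_R1\\.fastq$", "", basename(f1))
    if (!file.exists(f2)) {
      abort(sprintf("missing mate file for individual '%s'", ind),
            class = "methcross_user_error")
    }
    read_fastq_pairs(f1, f2) |> mutate(individual = ind)
  }) |> bind_rows()

  res <- analyze_reads(pairs, config, refs)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("mapping", "genotypes", "levels", "summary", "segregation",
              "reciprocal", "shared_sites", "snps")
  for (tb in tables) {
    readr::write_tsv(res[[tb]], file.path(out_dir, paste0(tb, ".tsv")))
  }
  for (r in names(res$correlation)) {
    readr::write_tsv(tidy(res$correlation[[r]]),
                     file.path(out_dir, paste0("correlation_", r, ".tsv")))
  }
  readr::write_tsv(tibble(key = names(res$log),
                          value = unlist(res$log)),
                   file.path(out_dir, "log.tsv"))
  write_manifest(config, out_dir)
  invisible(res)
}

#' Region-level mutant methylation table
#'
#' Fractional methylation per region, strain and motif from an ingested
#' per-site table: the wild-type-versus-mutant comparison surface. Region x
#' motif cells with no covered site are flagged `NA`.
#'
#' @param site_counts Tibble from [ingest_sitetable()].
#' @return Tibble: `region_id`, `strain`, one column per motif.
#' @export
mutant_table <- function(site_counts) {
  frac <- fractional_methylation(site_counts)
  grid <- tidyr::expand_grid(
    distinct(site_counts, .data$region_id, .data$strain),
    motif = MOTIFS
  )
  grid |>
    left_join(frac, by = c("region_id", "strain", "motif")) |>
    select("region_id", "strain", "motif", "level") |>
    tidyr::pivot_wider(names_from = "motif", values_from = "level")
}
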