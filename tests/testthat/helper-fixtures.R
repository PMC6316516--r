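# Small in-code fixtures shared across test files.

toy_refs <- function() {
  # 21 bp toy amplicon pair, identical except two informative A/G SNPs at
  # positions 13 and 18; shared sites: CpG at 1, CpHpG at 4, CpHpH at
  # 7/10/14
  allele_refs(
    region_id = "toy",
    allele_id = c("Col", "Ler"),
    sequence = c("CGTCAGCTTCTTACATGATAT",
                 "CGTCAGCTTCTTGCATGGTAT"),
    flank5 = "TA", flank3 = "AT"
  )
}

small_design <- function(n_f1 = 2L, n_f2 = 4L) {
  cross_design() |>
    dplyr::mutate(n = dplyr::case_when(
      generation == "P" ~ 1L,
      generation == "F1" ~ n_f1,
      TRUE ~ n_f2
    ))
}

# deterministic pair tibble straight from the simulator at tiny coverage
sim_small <- function(coverage = 60, seq_error = 0.001, seed = 7,
                      design = small_design()) {
  config <- pipeline_config(seed = seed, coverage = coverage,
                            seq_error = seq_error)
  suppressWarnings(simulate_cross(config, design = design))
}
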