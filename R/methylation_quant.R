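# Per-site methylation calls and the two level estimators.
#
# The weighted methylation level, sum(C_i) / sum(C_i + T_i) over the sites
# of a motif, is the per-individual, per-allele statistic of the cross
# analysis; the fractional level, the unweighted mean of per-site ratios
# C_i/(C_i+T_i), is used only for the region-level mutant comparison.
# Motif assignment always comes from the reference context, never from the
# (conversion-distorted) read.

#' Extract per-site methylation calls from assigned read pairs
#'
#' Only shared cytosine sites are scored. At each site covered by a pair,
#' the observed base is taken from mate 1 where it covers the site and from
#' mate 2 otherwise, so an overlapping fragment middle is counted once. An
#' observed C increments the methylated count `n_meth`, a T the unmethylated
#' count `n_unmeth`; A or G observations (sequencing error) are skipped and
#' tallied in `n_other`. Sites outside both mates contribute nothing.
#'
#' @param assigned Tibble from [assign_reads()], already restricted to the
#'   pairs that survived the mapping-error filter; only `Col`/`Ler` pairs
#'   are scored.
#' @param shared Tibble from [shared_cytosines()].
#' @return Tibble with `individual`, `region_id`, `allele`, `position`,
#'   `context`, `n_meth`, `n_unmeth`, `n_other`.
#' @export
extract_calls <- function(assigned, shared) {
  reads <- assigned |> filter(.data$allele %in% ALLELES)
  out <- vector("list", 0L)
  for (r in unique(reads$region_id)) {
    g <- reads |> filter(.data$region_id == r)
    st <- shared |> filter(.data$region_id == r)
    if (!nrow(st) || !nrow(g)) next
    end1 <- g$off_1 + nchar(g$seq_1r) - 1L
    end2 <- g$off_2 + nchar(g$seq_2r) - 1L
    for (j in seq_len(nrow(st))) {
      p <- st$position[j]
      in1 <- g$off_1 <= p & p <= end1
      in2 <- g$off_2 <= p & p <= end2
      base <- rep(NA_character_, nrow(g))
      base[in2] <- substr(g$seq_2r[in2], p - g$off_2[in2] + 1L,
                          p - g$off_2[in2] + 1L)
      base[in1] <- substr(g$seq_1r[in1], p - g$off_1[in1] + 1L,
                          p - g$off_1[in1] + 1L)
      cov <- !is.na(base)
      tab <- tibble(individual = g$individual[cov], allele = g$allele[cov],
                    base = base[cov]) |>
        count(.data$individual, .data$allele, .data$base) |>
        tidyr::pivot_wider(names_from = "base", values_from = "n",
                           values_fill = 0L)
      for (col in c("A", "C", "G", "T")) {
        if (!col %in% names(tab)) tab[[col]] <- 0L
      }
      out[[length(out) + 1L]] <- tab |>
        transmute(.data$individual, region_id = r, .data$allele,
                  position = p, context = st$context[j],
                  n_meth = .data$C, n_unmeth = .data$T,
                  n_other = .data$A + .data$G)
    }
  }
  if (!length(out)) {
    return(tibble(individual = character(), region_id = character(),
                  allele = character(), position = integer(),
                  context = character(), n_meth = integer(),
                  n_unmeth = integer(), n_other = integer()))
  }
  bind_rows(out) |>
    arrange(.data$individual, .data$region_id, .data$allele, .data$position)
}

#' Weighted methylation level per individual, allele and motif
#'
#' Computes `sum(n_meth) / sum(n_meth + n_unmeth)` over the sites of each
#' motif: the coverage-weighted estimator. Cells with zero total coverage
#' get `level = NA` and `defined = FALSE` and are excluded from population
#' summaries downstream.
#'
#' @param counts Tibble from [extract_calls()] (columns `n_meth`,
#'   `n_unmeth`, `context`, plus any grouping columns among `individual`,
#'   `region_id`, `allele`).
#' @return Tibble with the grouping columns plus `motif`, `level`,
#'   `n_sites` (covered sites), `coverage` and `defined`.
#' @export
#' @examples
#' weighted_methylation(tibble::tibble(
#'   context = "CpG", n_meth = c(9, 1), n_unmeth = c(1, 1)
#' ))  # 10/12
weighted_methylation <- function(counts) {
  grp <- intersect(c("individual", "region_id", "allele"), names(counts))
  counts |>
    group_by(across(all_of(grp)), motif = .data$context) |>
    summarise(
      n_sites = sum(.data$n_meth + .data$n_unmeth > 0),
      coverage = sum(.data$n_meth + .data$n_unmeth),
      level = ifelse(.data$coverage > 0,
                     sum(.data$n_meth) / .data$coverage, NA_real_),
      .groups = "drop"
    ) |>
    mutate(defined = !is.na(.data$level)) |>
    relocate("level", .after = "motif")
}

#' Fractional methylation level over a region
#'
#' The unweighted mean of per-site methylation ratios
#' `n_meth / (n_meth + n_unmeth)`; sites with zero coverage are excluded
#' from the mean. Grouping columns present in the input (e.g. `region_id`,
#' `strain`) are preserved; levels are computed per group x motif.
#'
#' @param counts Tibble with `context`, `n_meth`, `n_unmeth` and optional
#'   grouping columns (`region_id`, `strain`, `individual`, `allele`).
#' @return Tibble with the grouping columns plus `motif`, `level`,
#'   `n_sites`, `defined`.
#' @export
fractional_methylation <- function(counts) {
  grp <- intersect(c("region_id", "strain", "individual", "allele"),
                   names(counts))
  counts |>
    mutate(total = .data$n_meth + .data$n_unmeth) |>
    filter(.data$total > 0) |>
    group_by(across(all_of(grp)), motif = .data$context) |>
    summarise(level = mean(.data$n_meth / .data$total),
              n_sites = n(), .groups = "drop") |>
    mutate(defined = TRUE)
}

normalize_context <- function(x) {
  up <- toupper(x)
  dplyr::case_when(
    up %in% c("CPG", "CG") ~ "CpG",
    up %in% c("CPHPG", "CHG") ~ "CpHpG",
    up %in% c("CPHPH", "CHH") ~ "CpHpH",
    TRUE ~ NA_character_
  )
}

#' Ingest a per-site methylation table
#'
#' Reads a TSV of single-base methylation calls (columns `chrom`, `pos`
#' (1-based), `context`, `n_meth`, `n_total`, optional `strain`) such as a
#' published mutant methylome export, intersects it with the 1-based
#' inclusive genomic spans of the given regions, and returns per-site counts
#' ready for [fractional_methylation()]. Context labels `CG`/`CHG`/`CHH`
#' are accepted as synonyms of `CpG`/`CpHpG`/`CpHpH`. Malformed rows are
#' skipped with a warning; duplicated positions keep the last occurrence
#' (with a warning).
#'
#' @param path TSV file.
#' @param refs Allele references carrying `chrom`, `start`, `end` (one span
#'   per region; the Col row is used).
#' @return Tibble with `region_id`, `strain`, `position` (genomic),
#'   `context`, `n_meth`, `n_unmeth`.
#' @export
ingest_sitetable <- function(path, refs) {
  spans <- refs |>
    filter(.data$allele_id == "Col") |>
    select("region_id", "chrom", "start", "end")
  if (any(is.na(spans$start)) || any(spans$end < spans$start)) {
    abort("region coordinate span is empty or unset")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "context", "n_meth", "n_total")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("site table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  if (!"strain" %in% names(tbl)) tbl$strain <- "sample"
  bad <- is.na(suppressWarnings(as.numeric(tbl$pos))) |
    is.na(suppressWarnings(as.numeric(tbl$n_meth))) |
    is.na(suppressWarnings(as.numeric(tbl$n_total))) |
    is.na(normalize_context(tbl$context))
  if (any(bad)) {
    warn(sprintf("skipping %d malformed site-table row(s)", sum(bad)))
    tbl <- tbl[!bad, ]
  }
  tbl <- tbl |>
    mutate(pos = as.integer(.data$pos),
           n_meth = as.integer(.data$n_meth),
           n_total = as.integer(.data$n_total),
           context = normalize_context(.data$context))
  out <- tbl |>
    inner_join(spans, by = "chrom", relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end)
  dup <- out |>
    count(.data$region_id, .data$strain, .data$pos, .data$context) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    warn(sprintf("%d duplicated site(s); keeping the last occurrence",
                 nrow(dup)))
    out <- out |>
      group_by(.data$region_id, .data$strain, .data$pos, .data$context) |>
      slice_tail(n = 1) |>
      ungroup()
  }
  out |>
    transmute(.data$region_id, .data$strain, position = .data$pos,
              .data$context, .data$n_meth,
              n_unmeth = .data$n_total - .data$n_meth) |>
    arrange(.data$region_id, .data$strain, .data$position)
}
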