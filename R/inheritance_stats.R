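# Genotype calling, Mendelian segregation, reciprocal-cross comparison,
# population summaries and the trans-allelic correlation in F2
# heterozygotes.

#' Call genotypes from filtered mapping summaries
#'
#' With mapped pairs cleaned by [filter_mapping_error()], an individual is
#' heterozygous (CL) in a region when both alleles carry at least
#' `threshold` of its mapped pairs, and otherwise homozygous for the
#' majority allele (CC or LL). QC-failed individuals get `NA` and are
#' excluded downstream.
#'
#' @param summary Tibble from [filter_mapping_error()].
#' @param threshold Minimum minor-allele fraction for a heterozygous call.
#' @return The summary with a `genotype` column added.
#' @export
call_genotypes <- function(summary, threshold = 0.05) {
  summary |>
    mutate(
      frac_col = ifelse(.data$n_mapped > 0,
                        .data$n_col_kept / (.data$n_col_kept + .data$n_ler_kept),
                        NA_real_),
      genotype = dplyr::case_when(
        .data$qc_failed ~ NA_character_,
        .data$frac_col >= threshold & (1 - .data$frac_col) >= threshold ~ "CL",
        .data$frac_col > 0.5 ~ "CC",
        TRUE ~ "LL"
      )
    ) |>
    select(-"frac_col")
}

#' Pearson chi-square test of 1:2:1 segregation
#'
#' Tests observed CC/CL/LL counts against the Mendelian expectation
#' (0.25, 0.5, 0.25) with 2 degrees of freedom, no continuity correction.
#'
#' @param n_cc,n_cl,n_ll Genotype counts.
#' @return Tibble with `n`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' segregation_chisq(20, 10, 10)  # statistic 15
segregation_chisq <- function(n_cc, n_cl, n_ll) {
  n <- n_cc + n_cl + n_ll
  if (any(n == 0)) abort("no genotyped individuals")
  expected <- cbind(0.25 * n, 0.5 * n, 0.25 * n)
  observed <- cbind(n_cc, n_cl, n_ll)
  statistic <- rowSums((observed - expected)^2 / expected)
  tibble(n = as.integer(n), statistic = statistic, df = 2,
         p_value = stats::pchisq(statistic, df = 2, lower.tail = FALSE))
}

#' Segregation test per F2 population and region
#'
#' @param genotypes Tibble with `population`, `region_id`, `genotype`
#'   (typically the F2 rows of [call_genotypes()] output).
#' @return Tibble with genotype counts and the chi-square test per
#'   population x region.
#' @export
segregation_test <- function(genotypes) {
  genotypes |>
    filter(!is.na(.data$genotype)) |>
    group_by(.data$population, .data$region_id) |>
    summarise(n_cc = sum(.data$genotype == "CC"),
              n_cl = sum(.data$genotype == "CL"),
              n_ll = sum(.data$genotype == "LL"),
              .groups = "drop") |>
    mutate(segregation_chisq(.data$n_cc, .data$n_cl, .data$n_ll))
}

#' Compare methylation-level distributions between reciprocal crosses
#'
#' Two-sided rank-sum (Wilcoxon/Mann-Whitney, midranks for ties, normal
#' approximation) comparison of the per-individual levels of the two
#' reciprocal populations, per region x allele x motif. The `merged` flag is
#' `TRUE` when `p >= alpha`, i.e. no strong evidence of a distributional
#' difference, in which case the reciprocal populations are pooled
#' downstream. Cells with fewer than two individuals on either side are
#' undefined and merged by default with a warning. No multiplicity
#' correction is applied across cells; reports carry the raw p-values.
#'
#' @param levels Tibble with `population`, `region_id`, `allele`, `motif`,
#'   `level` covering exactly two populations.
#' @param alpha Significance threshold for keeping populations separate.
#' @return Tibble per region x allele x motif with `n_a`, `n_b`,
#'   `statistic`, `p_value`, `merged`.
#' @export
reciprocal_comparison <- function(levels, alpha = 0.001) {
  pops <- sort(unique(levels$population))
  if (length(pops) != 2) {
    abort("reciprocal_comparison needs exactly two populations")
  }
  levels |>
    filter(!is.na(.data$level)) |>
    group_by(.data$region_id, .data$allele, .data$motif) |>
    group_map(function(g, key) {
      a <- g$level[g$population == pops[1]]
      b <- g$level[g$population == pops[2]]
      if (length(a) < 2 || length(b) < 2) {
        warn(sprintf("%s/%s/%s: fewer than 2 individuals on one side; merged by default",
                     key$region_id, key$allele, key$motif))
        return(bind_cols(key, tibble(n_a = length(a), n_b = length(b),
                      statistic = NA_real_, p_value = NA_real_,
                      merged = TRUE)))
      }
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      bind_cols(key, tibble(n_a = length(a), n_b = length(b),
             statistic = unname(wt$statistic), p_value = wt$p.value,
             merged = wt$p.value >= alpha))
    }) |>
    bind_rows()
}

#' Population summaries of methylation levels
#'
#' Median, mean, sample standard deviation (n - 1 denominator) and n of the
#' defined levels, grouped by every grouping column present among
#' `population`, `generation`, `genotype` plus `region_id`, `allele`,
#' `motif`. Single-individual groups report `sd = NA`. Groups with no
#' defined level are omitted.
#'
#' @param levels Tibble of per-individual methylation levels.
#' @return Tibble of summary rows.
#' @export
summarize_population <- function(levels) {
  grp <- intersect(c("population", "generation", "genotype",
                     "region_id", "allele", "motif"), names(levels))
  levels |>
    filter(!is.na(.data$level)) |>
    group_by(across(all_of(grp))) |>
    summarise(n = n(), median = median(.data$level),
              mean = mean(.data$level),
              sd = ifelse(n() > 1, sd(.data$level), NA_real_),
              .groups = "drop")
}

#' Trans-allelic methylation correlation in heterozygotes
#'
#' For the heterozygous (CL) individuals of a region, computes per motif the
#' Spearman correlation between the Col-allele and Ler-allele levels
#' (midranks for ties, asymptotic p-value) and an ordinary least-squares
#' regression of the Ler level on the Col level with pointwise 95%
#' confidence bounds of the fitted line. At least 3 heterozygotes with
#' defined levels on both alleles are required per motif; motifs with a
#' constant vector are flagged (`rho = NA`).
#'
#' @param levels Tibble with `individual`, `genotype`, `region_id`,
#'   `allele`, `motif`, `level` (e.g. [weighted_methylation()] output joined
#'   to genotypes, or simulator truth).
#' @param region Region to analyse.
#' @return An object of class `allele_correlation`: see
#'   [tidy.allele_correlation()], [glance.allele_correlation()] and
#'   [autoplot.allele_correlation()].
#' @export
allele_correlation <- function(levels, region = "region1") {
  het <- levels |>
    filter(.data$genotype == "CL", .data$region_id == region,
           !is.na(.data$level)) |>
    select("individual", "allele", "motif", "level") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "level") |>
    filter(!is.na(.data$Col), !is.na(.data$Ler))

  ests <- het |>
    group_by(.data$motif) |>
    group_map(function(g, key) {
      n <- nrow(g)
      if (n < 3) {
        abort(sprintf("motif %s: fewer than 3 heterozygotes with defined levels",
                      key$motif))
      }
      if (sd(g$Col) == 0 || sd(g$Ler) == 0) {
        warn(sprintf("motif %s: constant levels; correlation undefined", key$motif))
        return(bind_cols(key, tibble(n_het = n, rho = NA_real_, p_value = NA_real_,
                      slope = NA_real_, intercept = NA_real_,
                      slope_low = NA_real_, slope_high = NA_real_)))
      }
      ct <- suppressWarnings(cor.test(g$Col, g$Ler, method = "spearman",
                                      exact = FALSE))
      fit <- lm(Ler ~ Col, data = g)
      ci <- confint(fit, "Col", level = 0.95)
      bind_cols(key, tibble(n_het = n, rho = unname(ct$estimate),
             p_value = ct$p.value,
             slope = unname(coef(fit)["Col"]),
             intercept = unname(coef(fit)["(Intercept)"]),
             slope_low = ci[1], slope_high = ci[2]))
    }) |>
    bind_rows()

  data <- het |>
    group_by(.data$motif) |>
    group_modify(function(g, key) {
      if (sd(g$Col) == 0 || sd(g$Ler) == 0) {
        return(mutate(g, fit = NA_real_, lower = NA_real_, upper = NA_real_))
      }
      fit <- lm(Ler ~ Col, data = g)
      pr <- predict(fit, interval = "confidence", level = 0.95)
      mutate(g, fit = pr[, "fit"], lower = pr[, "lwr"], upper = pr[, "upr"])
    }) |>
    ungroup()

  structure(list(estimates = ests, data = data, region = region),
            class = "allele_correlation")
}

#' @export
print.allele_correlation <- function(x, ...) {
  cat("Trans-allelic methylation correlation (", x$region, ", ",
      length(unique(x$data$individual)), " heterozygotes)\n\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Tidy the per-motif estimates of an allele correlation
#'
#' @param x An `allele_correlation` object.
#' @param ... Unused.
#' @return Tibble with one row per motif: `n_het`, Spearman `rho`,
#'   `p_value`, OLS `slope`, `intercept` and the 95% slope interval.
#' @method tidy allele_correlation
#' @export
tidy.allele_correlation <- function(x, ...) {
  x$estimates
}

#' One-row summary of an allele correlation
#'
#' @param x An `allele_correlation` object.
#' @param ... Unused.
#' @return Tibble with `region_id`, `n_het`, `n_motifs`, `min_p`.
#' @method glance allele_correlation
#' @export
glance.allele_correlation <- function(x, ...) {
  tibble(region_id = x$region,
         n_het = length(unique(x$data$individual)),
         n_motifs = nrow(x$estimates),
         min_p = suppressWarnings(min(x$estimates$p_value, na.rm = TRUE)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
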