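counts_tbl <- function(meth, unmeth, context = "CpG") {
  tibble::tibble(individual = "i1", region_id = "r", allele = "Col",
                 position = seq_along(meth), context = context,
                 n_meth = meth, n_unmeth = unmeth)
}

test_that("weighted methylation is the coverage-weighted ratio", {
  expect_equal(weighted_methylation(counts_tbl(c(3, 1), c(1, 3)))$level, 0.5)
  expect_equal(weighted_methylation(counts_tbl(c(0, 0), c(5, 7)))$level, 0)
  # coverage-weighted, distinct from the per-site mean 0.7
  expect_equal(weighted_methylation(counts_tbl(c(9, 1), c(1, 1)))$level, 10 / 12)
  # zero coverage is flagged undefined
  zero <- weighted_methylation(counts_tbl(0, 0))
  expect_true(is.na(zero$level))
  expect_false(zero$defined)
})

test_that("fractional methylation is the unweighted per-site mean", {
  expect_equal(fractional_methylation(counts_tbl(c(4, 0), c(0, 4)))$level, 0.5)
  expect_equal(fractional_methylation(counts_tbl(c(9, 1), c(1, 1)))$level, 0.7)
  expect_equal(fractional_methylation(counts_tbl(4, 0))$level, 1.0)
  # zero-coverage sites are excluded from the mean
  expect_equal(
    fractional_methylation(counts_tbl(c(9, 1, 0), c(1, 1, 0)))$level, 0.7
  )
})

test_that("the two estimators agree exactly under uniform coverage", {
  set.seed(51)
  for (i in 1:10) {
    cov <- sample(5:20, 1)
    meth <- rbinom(8, cov, runif(1))
    tbl <- counts_tbl(meth, cov - meth)
    expect_equal(weighted_methylation(tbl)$level,
                 fractional_methylation(tbl)$level)
  }
})

test_that("per-site calls score C as methylated, T as unmethylated, A/G as skips", {
  refs <- toy_refs()
  shared <- shared_cytosines(classify_contexts(refs), find_snps(refs))
  # hand-built 21 bp pair over the toy Col allele with known bases at the
  # shared sites 1 (CpG), 4 (CpHpG), 7, 10, 14 (CpHpH)
  base_seq <- "TGTTAGTTTTTTACATGATAT"   # all sites converted (T)
  seqs <- c(
    "CGTCAGCTTCTTACATGATAT",            # all sites methylated (C)
    base_seq,                           # all sites T
    "GGTTAGTTTTTTACATGATAT"             # site 1 G: sequencing-error skip
  )
  pairs <- tibble::tibble(
    individual = "i1", read_id = paste0("r", 1:3),
    seq_1 = seqs, qual_1 = strrep("F", 21),
    seq_2 = vapply(seqs, function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))), ""),
    qual_2 = strrep("F", 21)
  )
  assigned <- assign_reads(pairs, refs, find_snps(refs))
  calls <- extract_calls(assigned, shared)

  site1 <- calls |> dplyr::filter(position == 1)
  expect_equal(site1$n_meth, 1L)
  expect_equal(site1$n_unmeth, 1L)
  expect_equal(site1$n_other, 1L)
  site4 <- calls |> dplyr::filter(position == 4)
  expect_equal(site4$n_meth, 1L)
  expect_equal(site4$n_unmeth, 2L)
  # conservation: every covered read-site observation lands in one tally
  tot <- calls |> dplyr::summarise(s = sum(n_meth + n_unmeth + n_other))
  expect_equal(tot$s, 3L * nrow(shared))
})

test_that("read-pair overlap is counted once and partial coverage is honoured", {
  refs <- toy_refs()
  shared <- shared_cytosines(classify_contexts(refs), find_snps(refs))
  # 12 bp mates: mate 1 covers 1-12, mate 2 covers 10-21; overlap 10-12
  s <- refs$sequence[refs$allele_id == "Col"]
  pairs <- tibble::tibble(
    individual = "i1", read_id = "p1",
    seq_1 = substr(s, 1, 12), qual_1 = strrep("F", 12),
    seq_2 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(s, 10, 21)))),
    qual_2 = strrep("F", 12)
  )
  calls <- extract_calls(assign_reads(pairs, refs, find_snps(refs)), shared)
  # site 10 is covered by both mates but contributes exactly one call
  expect_equal(sum(calls$n_meth + calls$n_unmeth + calls$n_other), nrow(shared))
})

test_that("site tables are ingested, filtered to regions and deduplicated", {
  refs <- synthetic_references()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  tbl <- tibble::tibble(
    chrom = c("Chr3", "Chr3", "Chr3", "Chr1", "Chr3"),
    pos = c(16574335, 16574340, 16574350, 100, 20000000),
    context = c("CG", "CG", "CHG", "CG", "CG"),
    n_meth = c(2, 1, 3, 9, 9), n_total = c(4, 4, 3, 9, 9),
    strain = "WT"
  )
  readr::write_tsv(tbl, tsv)
  site <- ingest_sitetable(tsv, refs)
  expect_equal(nrow(site), 3L)            # 2 rows outside regions dropped
  expect_equal(unique(site$region_id), "region1")
  expect_equal(site$context, c("CpG", "CpG", "CpHpG"))

  # toy fractional level: positions at 2/4 and 1/4 -> (0.5 + 0.25)/2
  cpg <- fractional_methylation(site |> dplyr::filter(context == "CpG"))
  expect_equal(cpg$level, 0.375)

  # zero-coverage rows are excluded from the mean
  readr::write_tsv(tbl |> dplyr::mutate(n_total = c(4, 0, 3, 9, 9)), tsv)
  site0 <- ingest_sitetable(tsv, refs)
  cpg0 <- fractional_methylation(site0 |> dplyr::filter(context == "CpG"))
  expect_equal(cpg0$level, 0.5)

  # duplicate positions: last occurrence wins, with a warning
  readr::write_tsv(dplyr::bind_rows(tbl, tbl[1, ] |> dplyr::mutate(n_meth = 4)), tsv)
  expect_warning(dup <- ingest_sitetable(tsv, refs), "duplicated")
  expect_equal(dup$n_meth[dup$position == 16574335], 4L)

  # malformed rows are skipped with a warning
  readr::write_tsv(tbl |> dplyr::mutate(context = replace(context, 2, "XX")), tsv)
  expect_warning(skipped <- ingest_sitetable(tsv, refs), "malformed")
  expect_equal(nrow(skipped), 2L)
})

test_that("mutant tables report fractional levels per region, strain and motif", {
  refs <- synthetic_references()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = c("Chr3", "Chr3", "Chr4", "Chr4", "Chr3"),
    pos = c(16574335, 16574340, 6341088, 6341090, 16574360),
    context = c("CG", "CG", "CG", "CHH", "CG"),
    n_meth = c(2, 1, 1, 1, 0), n_total = c(4, 4, 2, 4, 5),
    strain = c("WT", "WT", "WT", "WT", "met1")
  ), tsv)
  mt <- mutant_table(ingest_sitetable(tsv, refs))
  wt1 <- mt |> dplyr::filter(region_id == "region1", strain == "WT")
  expect_equal(wt1$CpG, 0.375)
  expect_true(is.na(wt1$CpHpH))           # motif with no covered site flagged
  wt2 <- mt |> dplyr::filter(region_id == "region2", strain == "WT")
  expect_equal(wt2$CpG, 0.5)
  expect_equal(wt2$CpHpH, 0.25)
  m1 <- mt |> dplyr::filter(region_id == "region1", strain == "met1")
  expect_equal(m1$CpG, 0)
})
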