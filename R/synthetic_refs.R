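# Deterministic builders for the bundled synthetic amplicon references.
#
# The study's amplicon haplotype sequences are published only in its
# supplementary material and its raw reads are not deposited, so the package
# ships synthetic stand-ins: two amplicons whose top strands are assembled
# from short motif tokens so that the shared-cytosine context counts (region
# 1: 2 CpG / 5 CpHpG / 23 CpHpH; region 2: 10 CpG / 6 CpHpG / 33 CpHpH), the
# informative SNP counts (4 and 2, all A/G), the amplicon lengths (133 and
# 201 bp) and the genomic windows match the study design. The sequences
# themselves are NOT the genomic sequences at those coordinates.

# tokens start with their single C and contain no other C, so contexts are
# fixed within a token and concatenation cannot create or change a context
TOK_CPG <- "CGT"
TOK_CHG <- c("CAG", "CTG")
TOK_CHH <- c("CTT", "CAT", "CAA", "CTA")

build_amplicon <- function(plan, length_out) {
  n_chg <- 0L
  n_chh <- 0L
  col <- character(0)
  ler <- character(0)
  for (tok in plan) {
    piece_col <- switch(tok,
      cpg = TOK_CPG,
      chg = TOK_CHG[(n_chg <- n_chg + 1L) %% length(TOK_CHG) + 1L],
      chh = TOK_CHH[(n_chh <- n_chh + 1L) %% length(TOK_CHH) + 1L],
      snp = "A"
    )
    piece_ler <- if (tok == "snp") "G" else piece_col
    col <- c(col, piece_col)
    ler <- c(ler, piece_ler)
  }
  col <- paste(col, collapse = "")
  ler <- paste(ler, collapse = "")
  pad <- substr(strrep("AT", ceiling(length_out / 2)), 1,
                length_out - nchar(col))
  list(col = paste0(col, pad), ler = paste0(ler, pad))
}

region1_plan <- function() {
  c(rep("chh", 8), "cpg", rep("chh", 4), "snp",
    rep("chg", 3), rep("chh", 6), "snp",
    "cpg", rep("chh", 3), "snp",
    rep("chg", 2), rep("chh", 2), "snp")
}

region2_plan <- function() {
  # both SNPs sit in the middle third so that either 150 bp mate of the
  # 201 bp amplicon covers at least one of them
  c(rep("cpg", 4), rep("chg", 2), rep("chh", 13), "snp",
    rep("cpg", 3), rep("chg", 2), rep("chh", 10), "snp",
    rep("cpg", 3), rep("chg", 2), rep("chh", 10))
}

#' Bundled synthetic amplicon allele references
#'
#' Returns the package's two synthetic NUMT amplicons (Col and Ler haplotypes
#' each). They are deterministic stand-ins for the study amplicons, designed
#' so that region 1 (Chr3:16574335..16574467, 133 bp) carries 2 CpG, 5 CpHpG
#' and 23 CpHpH shared cytosines and 4 informative SNPs, and region 2
#' (Chr4:6341088..6341288, 201 bp) carries 10 CpG, 6 CpHpG and 33 CpHpH
#' shared cytosines and 2 informative SNPs. The same records ship as plain
#' text in `inst/extdata/synthetic_amplicons.fasta`.
#'
#' @return A tibble as from [allele_refs()], four rows.
#' @export
#' @examples
#' refs <- synthetic_references()
#' context_counts(shared_cytosines(classify_contexts(refs), find_snps(refs)))
synthetic_references <- function() {
  r1 <- build_amplicon(region1_plan(), 133L)
  r2 <- build_amplicon(region2_plan(), 201L)
  allele_refs(
    region_id = rep(c("region1", "region2"), each = 2),
    allele_id = rep(c("Col", "Ler"), 2),
    sequence = c(r1$col, r1$ler, r2$col, r2$ler),
    chrom = rep(c("Chr3", "Chr4"), each = 2),
    start = rep(c(16574335L, 6341088L), each = 2),
    end = rep(c(16574467L, 6341288L), each = 2),
    flank5 = "TA", flank3 = "AT"
  )
}
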