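# Quality filtering and bisulfite-space allele assignment.
#
# Amplicons are primer-defined, so reads are matched ungapped at a fixed
# offset instead of being aligned: mate 1 is anchored at the amplicon 5' end,
# mate 2 (reverse-complemented back to the reference strand) at the 3' end.
# A reference C matched by a read C or T is never a mismatch (bisulfite
# space); any other disagreement counts one mismatch.

#' Read paired FASTQ files into a pair table
#'
#' @param r1,r2 Paths to the mate FASTQ files (Phred+33). Records are paired
#'   by order; mate counts must agree.
#' @return Tibble with `read_id`, `seq_1`, `qual_1`, `seq_2`, `qual_2`
#'   (mate 2 as sequenced, i.e. not yet reverse-complemented).
#' @export
read_fastq_pairs <- function(r1, r2) {
  parse <- function(path) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) abort(sprintf("malformed FASTQ '%s': %s",
                                        path, conditionMessage(e)))
    )
    tibble(read_id = sub(" .*", "", names(x)),
           seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- parse(r1)
  b <- parse(r2)
  if (nrow(a) != nrow(b)) {
    abort(sprintf("mate files %s / %s have %d vs %d records",
                  r1, r2, nrow(a), nrow(b)))
  }
  tibble(read_id = a$read_id,
         seq_1 = a$seq, qual_1 = a$qual,
         seq_2 = b$seq, qual_2 = b$qual)
}

phred_trim_length <- function(qual, min_quality) {
  vapply(qual, function(q) {
    qs <- utf8ToInt(q) - 33L
    keep <- which(qs >= min_quality)
    if (!length(keep)) 0L else max(keep)
  }, integer(1), USE.NAMES = FALSE)
}

#' Quality-filter read pairs
#'
#' Trailing bases below `min_quality` are trimmed from the 3' (as-sequenced)
#' end of each mate; a pair is dropped when either trimmed mate is shorter
#' than `min_length`.
#'
#' @param pairs Tibble from [read_fastq_pairs()] or [simulate_reads()].
#' @param min_quality Phred threshold for trailing-base trimming.
#' @param min_length Minimum surviving mate length.
#' @return The filtered pair tibble; the number of dropped pairs is attached
#'   as attribute `n_dropped`.
#' @export
quality_filter <- function(pairs, min_quality = 20, min_length = 100) {
  l1 <- phred_trim_length(pairs$qual_1, min_quality)
  l2 <- phred_trim_length(pairs$qual_2, min_quality)
  out <- pairs |>
    mutate(seq_1 = substr(.data$seq_1, 1, l1),
           qual_1 = substr(.data$qual_1, 1, l1),
           seq_2 = substr(.data$seq_2, 1, l2),
           qual_2 = substr(.data$qual_2, 1, l2)) |>
    filter(l1 >= min_length, l2 >= min_length)
  attr(out, "n_dropped") <- nrow(pairs) - nrow(out)
  out
}

# vectorised bisulfite-space mismatch counts of reads placed ungapped at
# per-read offsets on one reference; reads that do not fit return Inf
bis_mismatch_counts <- function(seqs, offsets, ref_seq) {
  refint <- utf8ToInt(ref_seq)
  L <- length(refint)
  lens <- nchar(seqs)
  out <- rep(Inf, length(seqs))
  valid <- lens > 0 & offsets >= 1 & (offsets + lens - 1) <= L
  if (any(valid)) {
    ln <- lens[valid]
    readint <- utf8ToInt(paste(seqs[valid], collapse = ""))
    refi <- refint[sequence(ln, from = offsets[valid])]
    Cint <- 67L; Tint <- 84L
    mism <- readint != refi & !(refi == Cint & readint == Tint)
    out[valid] <- as.vector(rowsum(as.numeric(mism), rep.int(seq_along(ln), ln)))
  }
  out
}

#' Count bisulfite-space mismatches of reads against a reference
#'
#' Ungapped comparison at a fixed offset in reference orientation. A
#' reference C matched by a read C or T is not a mismatch (it is the
#' methylated/converted state); any other disagreement is one mismatch.
#'
#' @param reads Character vector of read sequences, reference orientation.
#' @param ref_seq Reference sequence (character scalar).
#' @param offset 1-based offset of the first read base on the reference.
#' @return Integer mismatch counts.
#' @export
#' @examples
#' bisulfite_mismatches(c("ATGA", "ACAA"), "ACGA")  # 0, 1
bisulfite_mismatches <- function(reads, ref_seq, offset = 1) {
  offsets <- rep_len(offset, length(reads))
  if (any(offsets + nchar(reads) - 1 > nchar(ref_seq)) || any(offsets < 1)) {
    abort("read extends beyond the reference span")
  }
  as.integer(bis_mismatch_counts(reads, offsets, ref_seq))
}

#' Assign read pairs to the Col or Ler allele
#'
#' Each mate is compared ungapped against every allele of every region
#' (mate 1 anchored at the 5' end, mate 2 reverse-complemented and anchored
#' at the 3' end); the pair's region is the one with the smallest combined
#' best mismatch count. Within that region each mate is called for the
#' allele with the strictly smaller bisulfite mismatch count, provided that
#' count is `<= max_mismatch` and the mate covers at least one informative
#' SNP; ties or no informative SNP give `ambiguous`, both counts above the
#' threshold give `unmapped`. Mate calls are combined per pair: conflicting
#' allele calls give `ambiguous`; otherwise any allele call wins over
#' `ambiguous`, which wins over `unmapped`.
#'
#' @param pairs Tibble of read pairs (`quality_filter()` output; mate 2 as
#'   sequenced). Extra columns such as `individual` or `allele_true` are
#'   carried through.
#' @param refs Allele references covering all candidate regions.
#' @param snps Tibble from [find_snps()].
#' @param max_mismatch Maximum allowed mismatches per mate (default 5 per
#'   150-mer, about 3%).
#' @return Tibble with the carried columns plus `region_id`, `allele`
#'   (`Col`/`Ler`/`ambiguous`/`unmapped`), `mm_col`, `mm_ler`, `n_info`,
#'   and the reference-oriented mate sequences/offsets (`seq_1r`, `off_1`,
#'   `seq_2r`, `off_2`) used downstream for methylation extraction.
#' @export
assign_reads <- function(pairs, refs, snps, max_mismatch = 5) {
  stopifnot(nrow(pairs) > 0)
  reg <- refs |> distinct(.data$region_id) |> pull()
  seq2r <- revcomp_chr(pairs$seq_2)
  n <- nrow(pairs)
  len1 <- nchar(pairs$seq_1)
  len2 <- nchar(seq2r)

  # mismatch matrices [pair x region] per allele and mate
  mm <- list()
  off2 <- matrix(NA_integer_, n, length(reg), dimnames = list(NULL, reg))
  for (r in reg) {
    L <- nchar(refs$sequence[refs$region_id == r][1])
    off2[, r] <- L - len2 + 1L
    for (a in ALLELES) {
      rs <- refs$sequence[refs$region_id == r & refs$allele_id == a]
      mm[[paste(r, a, "1")]] <- bis_mismatch_counts(pairs$seq_1, rep(1L, n), rs)
      mm[[paste(r, a, "2")]] <- bis_mismatch_counts(seq2r, off2[, r], rs)
    }
  }

  # best combined mismatch per region decides the region
  tot <- vapply(reg, function(r) {
    pmin(mm[[paste(r, "Col", "1")]], mm[[paste(r, "Ler", "1")]]) +
      pmin(mm[[paste(r, "Col", "2")]], mm[[paste(r, "Ler", "2")]])
  }, numeric(n))
  if (is.null(dim(tot))) tot <- matrix(tot, nrow = n)
  region_idx <- max.col(-tot, ties.method = "first")
  region <- reg[region_idx]

  pick <- function(allele, mate) {
    m <- vapply(reg, function(r) mm[[paste(r, allele, mate)]], numeric(n))
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    m[cbind(seq_len(n), region_idx)]
  }
  mc1 <- pick("Col", "1"); ml1 <- pick("Ler", "1")
  mc2 <- pick("Col", "2"); ml2 <- pick("Ler", "2")
  o2 <- off2[cbind(seq_len(n), region_idx)]

  info <- snps |> filter(.data$informative)
  covers_info <- function(off, len) {
    out <- numeric(n)
    for (r in reg) {
      idx <- region == r
      if (!any(idx)) next
      p <- info$position[info$region_id == r]
      for (pp in p) {
        out[idx] <- out[idx] +
          (pp >= off[idx] & pp <= off[idx] + len[idx] - 1L)
      }
    }
    out
  }
  ni1 <- covers_info(rep(1L, n), len1)
  ni2 <- covers_info(o2, len2)

  mate_call <- function(mc, ml, ni) {
    best <- pmin(mc, ml)
    dplyr::case_when(
      best > max_mismatch ~ "unmapped",
      mc == ml | ni == 0 ~ "ambiguous",
      mc < ml ~ "Col",
      TRUE ~ "Ler"
    )
  }
  c1 <- mate_call(mc1, ml1, ni1)
  c2 <- mate_call(mc2, ml2, ni2)
  allele <- dplyr::case_when(
    (c1 == "Col" & c2 == "Ler") | (c1 == "Ler" & c2 == "Col") ~ "ambiguous",
    c1 %in% ALLELES ~ c1,
    c2 %in% ALLELES ~ c2,
    c1 == "ambiguous" | c2 == "ambiguous" ~ "ambiguous",
    TRUE ~ "unmapped"
  )

  pairs |>
    mutate(region_id = region, allele = allele,
           mm_col = mc1 + mc2, mm_ler = ml1 + ml2,
           n_info = ni1 + ni2,
           seq_1r = .data$seq_1, off_1 = 1L,
           seq_2r = seq2r, off_2 = o2)
}

#' Summarize allele assignment per individual and region
#'
#' @param assigned Tibble from [assign_reads()] carrying an `individual`
#'   column.
#' @return Tibble with per individual x region pair counts: total pairs,
#'   `n_col`, `n_ler`, `n_ambiguous`, `n_unmapped`, `n_mapped`
#'   (= n_col + n_ler) and the minor-allele fraction of mapped pairs.
#' @export
summarize_mapping <- function(assigned) {
  assigned |>
    group_by(.data$individual, .data$region_id) |>
    summarise(
      n_pairs = n(),
      n_col = sum(.data$allele == "Col"),
      n_ler = sum(.data$allele == "Ler"),
      n_ambiguous = sum(.data$allele == "ambiguous"),
      n_unmapped = sum(.data$allele == "unmapped"),
      .groups = "drop"
    ) |>
    mutate(n_mapped = .data$n_col + .data$n_ler,
           minor_fraction = ifelse(.data$n_mapped > 0,
                                   pmin(.data$n_col, .data$n_ler) / .data$n_mapped,
                                   NA_real_))
}

#' Apply the 5% mapping-error rule
#'
#' When the minor allele carries strictly fewer than `threshold` of an
#' individual's mapped pairs in a region, those pairs are regarded as
#' mapping error and discarded from genotyping and methylation
#' quantification. A fraction of exactly `threshold` is retained.
#' Individuals with zero mapped pairs are flagged `qc_failed`.
#'
#' @param summary Tibble from [summarize_mapping()].
#' @param threshold Minor-allele fraction below which reads are discarded.
#' @return The summary with `discarded_allele`, `n_discarded`,
#'   `n_col_kept`, `n_ler_kept`, `qc_failed` columns added.
#' @export
filter_mapping_error <- function(summary, threshold = 0.05) {
  summary |>
    mutate(
      qc_failed = .data$n_mapped == 0,
      discard = !.data$qc_failed & .data$minor_fraction < threshold &
        pmin(.data$n_col, .data$n_ler) > 0,
      discarded_allele = ifelse(.data$discard,
                                ifelse(.data$n_col < .data$n_ler, "Col", "Ler"),
                                NA_character_),
      n_discarded = ifelse(.data$discard,
                           pmin(.data$n_col, .data$n_ler), 0L),
      n_col_kept = ifelse(!is.na(.data$discarded_allele) &
                            .data$discarded_allele == "Col", 0L, .data$n_col),
      n_ler_kept = ifelse(!is.na(.data$discarded_allele) &
                            .data$discarded_allele == "Ler", 0L, .data$n_ler)
    ) |>
    select(-"discard")
}
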