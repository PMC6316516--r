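#' Build a table of amplicon allele references
#'
#' An allele reference is one haplotype sequence of one amplicon region. The
#' amplicon is analysed on the top strand only: cytosines on the opposite
#' strand (G positions here) are deliberately ignored, so that the simulator
#' and the caller share one strand convention. Coordinates are 1-based
#' inclusive.
#'
#' @param region_id Character, region identifiers (recycled).
#' @param allele_id Character, `"Col"` or `"Ler"`.
#' @param sequence Uppercase DNA (A/C/G/T only).
#' @param chrom,start,end Optional genomic coordinates, 1-based inclusive.
#'   When set, `end - start + 1` must equal `nchar(sequence)`.
#' @param flank5,flank3 Optional flanking DNA used to resolve sequence contexts
#'   at the amplicon edges; `flank3` needs at least 2 bases to resolve a
#'   cytosine at the last position.
#'
#' @return A tibble with one row per allele reference.
#' @export
#' @examples
#' allele_refs("r1", c("Col", "Ler"), c("ACGT", "ATGT"))
allele_refs <- function(region_id, allele_id, sequence,
                        chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, flank5 = "", flank3 = "") {
  refs <- tibble(
    region_id = as.character(region_id),
    allele_id = as.character(allele_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    sequence = toupper(as.character(sequence)),
    flank5 = toupper(as.character(flank5)),
    flank3 = toupper(as.character(flank3))
  )
  validate_refs(refs)
  refs
}

validate_refs <- function(refs) {
  bad <- grepl("[^ACGT]", refs$sequence)
  if (any(bad)) {
    abort(sprintf(
      "invalid sequence: non-ACGT character in %s/%s",
      refs$region_id[bad][1], refs$allele_id[bad][1]
    ), class = "methcross_invalid_sequence")
  }
  if (any(grepl("[^ACGT]", refs$flank5)) || any(grepl("[^ACGT]", refs$flank3))) {
    abort("invalid sequence: non-ACGT character in flank",
          class = "methcross_invalid_sequence")
  }
  has_coord <- !is.na(refs$start) & !is.na(refs$end)
  off <- has_coord & (refs$end - refs$start + 1L) != nchar(refs$sequence)
  if (any(off)) {
    abort(sprintf("coordinates of %s/%s do not match sequence length",
                  refs$region_id[off][1], refs$allele_id[off][1]))
  }
  invisible(refs)
}

#' Read allele references from a FASTA file
#'
#' Record IDs must follow the `"<region_id>|<allele_id>"` convention, one
#' record per allele.
#'
#' @param path FASTA file.
#' @param coords Optional tibble with `region_id`, `chrom`, `start`, `end`.
#' @param flank5,flank3 Flanking bases applied to every record.
#' @return A tibble as from [allele_refs()].
#' @export
read_allele_fasta <- function(path, coords = NULL, flank5 = "", flank3 = "") {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(ids) != 2)) {
    abort("FASTA record IDs must be of the form '<region_id>|<allele_id>'")
  }
  refs <- allele_refs(
    region_id = vapply(ids, `[[`, "", 1),
    allele_id = vapply(ids, `[[`, "", 2),
    sequence = as.character(seqs),
    flank5 = flank5, flank3 = flank3
  )
  if (!is.null(coords)) {
    refs <- refs |>
      select(-"chrom", -"start", -"end") |>
      left_join(coords, by = "region_id") |>
      select(all_of(names(refs)))
    validate_refs(refs)
  }
  refs
}

#' Classify cytosine sequence contexts on the top strand
#'
#' Every cytosine on the analysed (top) strand is assigned a context from the
#' two downstream bases: `G` at +1 gives CpG; otherwise `G` at +2 gives CpHpG,
#' else CpHpH (H being A, T or C). Cytosines within two bases of the 3' end
#' use `flank3`; if the context cannot be resolved the site is dropped with a
#' warning.
#'
#' @param refs Tibble from [allele_refs()].
#' @return Tibble with `region_id`, `allele_id`, `position` (1-based within
#'   the amplicon) and `context`.
#' @export
#' @examples
#' classify_contexts(allele_refs("r", "Col", "TACGT"))
classify_contexts <- function(refs) {
  validate_refs(refs)
  out <- purrr::pmap(refs, function(region_id, allele_id, sequence, flank3, ...) {
    ext <- paste0(sequence, flank3)
    chars <- strsplit(ext, "")[[1]]
    len <- nchar(sequence)
    pos <- which(chars[seq_len(len)] == "C")
    if (!length(pos)) {
      return(tibble(region_id = character(), allele_id = character(),
                    position = integer(), context = character()))
    }
    n1 <- chars[pos + 1L]
    n2 <- chars[pos + 2L]
    context <- dplyr::case_when(
      !is.na(n1) & n1 == "G" ~ "CpG",
      !is.na(n2) & n2 == "G" ~ "CpHpG",
      !is.na(n1) & !is.na(n2) ~ "CpHpH",
      TRUE ~ NA_character_
    )
    if (anyNA(context)) {
      warn(sprintf(
        "%s/%s: %d cytosine(s) at the 3' edge dropped (context unresolvable without flank3)",
        region_id, allele_id, sum(is.na(context))
      ))
    }
    tibble(region_id = region_id, allele_id = allele_id,
           position = as.integer(pos), context = context) |>
      filter(!is.na(.data$context))
  })
  bind_rows(out)
}

# possible observed bases of a reference base after bisulfite conversion on
# the top strand: a C may be read as C (methylated / unconverted) or T
# (converted); every other base only as itself
read_base_set <- function(base) {
  if (base == "C") c("C", "T") else base
}

#' Find SNPs between the Col and Ler alleles of each region
#'
#' Alleles must be indel-free (equal length); every differing position is
#' returned. A SNP is `informative` when the two alleles remain
#' distinguishable after bisulfite conversion under every methylation state,
#' i.e. when the possible read-base sets (a reference C may be read as C or
#' T, any other base only as itself) do not intersect. A C/T SNP is therefore
#' not informative.
#'
#' @param refs Tibble holding both alleles of each region.
#' @return Tibble with `region_id`, `position`, `col_base`, `ler_base`,
#'   `informative`.
#' @export
#' @examples
#' find_snps(allele_refs("r", c("Col", "Ler"), c("AAGA", "AACA")))
find_snps <- function(refs) {
  validate_refs(refs)
  out <- refs |>
    group_by(.data$region_id) |>
    group_map(function(g, key) {
      col <- g$sequence[g$allele_id == "Col"]
      ler <- g$sequence[g$allele_id == "Ler"]
      if (length(col) != 1 || length(ler) != 1) {
        abort(sprintf("region %s must have exactly one Col and one Ler allele",
                      key$region_id))
      }
      if (nchar(col) != nchar(ler)) {
        abort(sprintf(
          "region %s: alleles differ in length; alignment required (indels unsupported)",
          key$region_id
        ), class = "methcross_alignment_required")
      }
      cc <- strsplit(col, "")[[1]]
      lc <- strsplit(ler, "")[[1]]
      pos <- which(cc != lc)
      informative <- vapply(pos, function(p) {
        !length(intersect(read_base_set(cc[p]), read_base_set(lc[p])))
      }, logical(1))
      tibble(region_id = key$region_id, position = as.integer(pos),
             col_base = cc[pos], ler_base = lc[pos],
             informative = informative)
    }) |>
    bind_rows()
  out
}

#' Select cytosine sites shared by both alleles
#'
#' A shared site is a position that is a cytosine with identical context in
#' both alleles. Positions overlapping any SNP are excluded, so that
#' methylation is only quantified where the two haplotypes are locally
#' identical.
#'
#' @param sites Tibble from [classify_contexts()] covering both alleles.
#' @param snps Tibble from [find_snps()].
#' @return Tibble with `region_id`, `position`, `context`.
#' @export
shared_cytosines <- function(sites, snps) {
  col <- sites |> filter(.data$allele_id == "Col") |>
    select("region_id", "position", "context")
  ler <- sites |> filter(.data$allele_id == "Ler") |>
    select("region_id", "position", "context")
  shared <- inner_join(col, ler, by = c("region_id", "position", "context"))
  if (nrow(snps)) {
    shared <- anti_join(shared, snps, by = c("region_id", "position"))
  }
  arrange(shared, .data$region_id, .data$position)
}

#' Count shared sites per context
#'
#' Convenience summary of the [shared_cytosines()] table, the per-region
#' analogue of the study-design table of usable CpG/CpHpG/CpHpH sites.
#'
#' @param shared Tibble from [shared_cytosines()].
#' @return Tibble with `region_id`, `context`, `n_sites`.
#' @export
context_counts <- function(shared) {
  shared |>
    mutate(context = motif_factor(.data$context)) |>
    count(.data$region_id, .data$context, name = "n_sites", .drop = FALSE) |>
    mutate(context = as.character(.data$context))
}
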