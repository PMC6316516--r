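# Seeded bisulfite amplicon read generator for the full cross design.

#' Cross design of the amplicon sequencing study
#'
#' Default sample sizes follow the study design: two individuals per parental
#' strain, reciprocal F1 populations (n = 18 and 19), and four selfed F2
#' populations (n = 30, 28, 30, 30) each founded by one F1 individual.
#'
#' @return Tibble with `population`, `generation` (P/F1/F2), `mother` (seed
#'   parent strain of the founding cross), `founder` (F1 founder population
#'   for F2), `n`.
#' @export
cross_design <- function() {
  tibble(
    population = c("P-Col", "P-Ler", "F1-ColxLer", "F1-LerxCol",
                   "F2-ColxLer-2", "F2-ColxLer-4",
                   "F2-LerxCol-3", "F2-LerxCol-4"),
    generation = c("P", "P", "F1", "F1", "F2", "F2", "F2", "F2"),
    mother = c("Col", "Ler", "Col", "Ler", "Col", "Col", "Ler", "Ler"),
    founder = c(NA, NA, NA, NA, "F1-ColxLer", "F1-ColxLer",
                "F1-LerxCol", "F1-LerxCol"),
    n = c(2L, 2L, 18L, 19L, 30L, 28L, 30L, 30L)
  )
}

#' Simulation parameters of the read generator
#'
#' @param coverage Mean number of fragments (read pairs) per individual and
#'   region; Poisson-distributed per individual. The default mirrors the
#'   study's per-individual mapped-read depth; tests and examples use a few
#'   hundred.
#' @param conversion Bisulfite conversion efficiency: probability that an
#'   unmethylated C is read as T.
#' @param protection Probability that a methylated C is read as C (incomplete
#'   protection converts methylated C to T).
#' @param seq_error Per-base substitution error rate; an erroneous base is
#'   replaced by one of the three other bases uniformly.
#' @param read_length Length of each mate (paired 150 x 2 geometry). Reads
#'   longer than the amplicon are truncated to the amplicon with a warning.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(coverage = 50000, conversion = 0.99, protection = 1,
                       seq_error = 0.001, read_length = 150L) {
  stopifnot(coverage > 0, conversion >= 0, conversion <= 1,
            protection >= 0, protection <= 1,
            seq_error >= 0, seq_error <= 1, read_length >= 1)
  structure(list(coverage = coverage, conversion = conversion,
                 protection = protection, seq_error = seq_error,
                 read_length = as.integer(read_length)),
            class = "sim_params")
}

#' Default per-population methylation hyperparameters
#'
#' Beta-distribution mean/s.d. of the per-individual, per-allele, per-motif
#' methylation level for every population class of the cross, taken from the
#' study's population summaries: parents, F1 hybrids, and F2 split by
#' genotype. Parental dispersions are not reported (n = 2), so a small
#' within-strain spread is assumed (s.d. 0.02; 0.005 where the mean is 0.01).
#' `rho` is the target Spearman correlation between the Col and Ler allele
#' levels of a heterozygote; region 1 uses the reported per-motif values
#' (0.57, 0.75, 0.97), region 2 (unreported) a moderate 0.5.
#'
#' @return Tibble with `region_id`, `generation`, `genotype`, `allele`,
#'   `motif`, `mean`, `sd`, `rho`.
#' @export
default_hyperparams <- function() {
  row <- function(region, gen, geno, allele, means, sds, rho = NA_real_) {
    tibble(region_id = region, generation = gen, genotype = geno,
           allele = allele, motif = MOTIFS, mean = means, sd = sds, rho = rho)
  }
  rho1 <- c(0.57, 0.75, 0.97)
  rho2 <- c(0.5, 0.5, 0.5)
  bind_rows(
    # region 1
    row("region1", "P",  "CC", "Col", c(0.67, 0.38, 0.18), c(0.02, 0.02, 0.02)),
    row("region1", "P",  "LL", "Ler", c(0.01, 0.01, 0.01), c(0.005, 0.005, 0.005)),
    row("region1", "F1", "CL", "Col", c(0.42, 0.12, 0.02), c(0.070, 0.043, 0.007), rho1),
    row("region1", "F1", "CL", "Ler", c(0.05, 0.02, 0.01), c(0.031, 0.014, 0.003), rho1),
    row("region1", "F2", "CC", "Col", c(0.80, 0.45, 0.28), c(0.080, 0.110, 0.110)),
    row("region1", "F2", "CL", "Col", c(0.61, 0.24, 0.11), c(0.150, 0.130, 0.097), rho1),
    row("region1", "F2", "CL", "Ler", c(0.28, 0.16, 0.10), c(0.200, 0.130, 0.100), rho1),
    row("region1", "F2", "LL", "Ler", c(0.21, 0.13, 0.11), c(0.240, 0.170, 0.140)),
    # region 2
    row("region2", "P",  "CC", "Col", c(0.86, 0.51, 0.08), c(0.02, 0.02, 0.01)),
    row("region2", "P",  "LL", "Ler", c(0.61, 0.24, 0.02), c(0.02, 0.02, 0.01)),
    row("region2", "F1", "CL", "Col", c(0.90, 0.52, 0.07), c(0.014, 0.011, 0.007), rho2),
    row("region2", "F1", "CL", "Ler", c(0.79, 0.41, 0.04), c(0.048, 0.036, 0.009), rho2),
    row("region2", "F2", "CC", "Col", c(0.92, 0.51, 0.06), c(0.013, 0.032, 0.008)),
    row("region2", "F2", "CL", "Col", c(0.92, 0.50, 0.07), c(0.014, 0.034, 0.009), rho2),
    row("region2", "F2", "CL", "Ler", c(0.90, 0.47, 0.06), c(0.029, 0.038, 0.008), rho2),
    row("region2", "F2", "LL", "Ler", c(0.91, 0.47, 0.06), c(0.022, 0.040, 0.011))
  )
}

# method-of-moments beta shapes; sd = 0 marks a point mass
beta_shapes <- function(mean, sd) {
  stopifnot(all(mean >= 0 & mean <= 1), all(sd >= 0))
  v <- sd^2
  lim <- mean * (1 - mean)
  if (any(sd > 0 & v >= lim)) {
    abort("invalid beta hyperparameters: sd^2 must be < mean*(1-mean)",
          class = "methcross_config_error")
  }
  k <- ifelse(sd > 0, lim / v - 1, NA_real_)
  list(alpha = mean * k, beta = (1 - mean) * k)
}

#' Simulate genotypes for a cross design
#'
#' Parents are homozygous (Col parents CC, Ler parents LL), all F1
#' individuals are CL, and each F2 individual is drawn i.i.d. from the
#' Mendelian (0.25, 0.5, 0.25) segregation ratio for CC/CL/LL.
#'
#' @param design Tibble as from [cross_design()].
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return Tibble with `individual`, `population`, `generation`, `genotype`.
#' @export
simulate_pedigree <- function(design = cross_design(), seed = 1) {
  stopifnot(all(design$n >= 1))
  set.seed(seed)
  design |>
    rowwise() |>
    reframe(
      population = .data$population,
      generation = .data$generation,
      individual = sprintf("%s_%02d", .data$population, seq_len(.data$n)),
      genotype = switch(.data$generation,
        P = if (.data$mother == "Col") rep("CC", .data$n) else rep("LL", .data$n),
        F1 = rep("CL", .data$n),
        F2 = sample(c("CC", "CL", "LL"), .data$n, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25))
      )
    ) |>
    select("individual", "population", "generation", "genotype")
}

alleles_of <- function(genotype) {
  switch(genotype, CC = "Col", LL = "Ler", CL = c("Col", "Ler"))
}

#' Draw per-individual methylation profiles
#'
#' For every individual and each allele it carries, a methylation level per
#' region and motif is drawn from the beta law of its population class. For
#' heterozygotes the Col and Ler draws are coupled through a Gaussian copula
#' whose latent correlation is `2*sin(pi*rho/6)`, so that the Spearman
#' correlation of the two allele levels equals `rho` (beta quantile
#' transforms are monotone and preserve Spearman correlation).
#'
#' @param pedigree Tibble from [simulate_pedigree()].
#' @param hyperparams Tibble as from [default_hyperparams()].
#' @param seed Integer seed.
#' @return Tibble with `individual`, `population`, `generation`, `genotype`,
#'   `region_id`, `allele`, `motif`, `level` (the true per-site methylation
#'   probability of that allele and motif).
#' @export
draw_individual_profiles <- function(pedigree, hyperparams = default_hyperparams(),
                                     seed = 1) {
  set.seed(seed)
  cells <- hyperparams |> distinct(.data$region_id, .data$motif) |>
    arrange(.data$region_id, motif_factor(.data$motif))
  ped <- pedigree |> arrange(.data$individual)
  classes <- ped |>
    group_by(.data$generation, .data$genotype) |>
    group_split()

  hp_key <- function(region, motif, gen, geno, allele) {
    r <- hyperparams |>
      filter(.data$region_id == !!region, .data$motif == !!motif,
             .data$generation == !!gen, .data$genotype == !!geno,
             .data$allele == !!allele)
    if (nrow(r) != 1) {
      abort(sprintf("missing hyperparameters for %s/%s %s %s %s",
                    region, motif, gen, geno, allele),
            class = "methcross_config_error")
    }
    r
  }

  draw_cell <- function(region, motif) {
    purrr::map(classes, function(cl) {
      gen <- cl$generation[1]
      geno <- cl$genotype[1]
      n <- nrow(cl)
      if (geno == "CL") {
        hc <- hp_key(region, motif, gen, geno, "Col")
        hl <- hp_key(region, motif, gen, geno, "Ler")
        rho <- hc$rho
        r <- if (is.na(rho)) 0 else 2 * sin(pi * rho / 6)
        z1 <- rnorm(n)
        z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
        tibble(
          individual = rep(cl$individual, 2),
          population = rep(cl$population, 2),
          generation = gen, genotype = geno, region_id = region,
          allele = rep(c("Col", "Ler"), each = n),
          motif = motif,
          level = c(beta_quantile(pnorm(z1), hc$mean, hc$sd),
                    beta_quantile(pnorm(z2), hl$mean, hl$sd))
        )
      } else {
        allele <- alleles_of(geno)
        h <- hp_key(region, motif, gen, geno, allele)
        tibble(
          individual = cl$individual, population = cl$population,
          generation = gen, genotype = geno, region_id = region,
          allele = allele, motif = motif,
          level = beta_quantile(runif(n), h$mean, h$sd)
        )
      }
    }) |> bind_rows()
  }

  purrr::pmap(list(cells$region_id, cells$motif), draw_cell) |>
    bind_rows() |>
    arrange(.data$individual, .data$region_id,
            motif_factor(.data$motif), .data$allele)
}

beta_quantile <- function(u, mean, sd) {
  if (sd == 0) return(rep(mean, length(u)))
  sh <- beta_shapes(mean, sd)
  qbeta(u, sh$alpha, sh$beta)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired bisulfite reads for a set of individuals
#'
#' Per fragment the template allele is drawn uniformly for heterozygotes (or
#' fixed for homozygotes); each cytosine of that allele is methylated with
#' its site probability (the profile level of its motif), independently per
#' fragment. An unmethylated C is emitted as T with probability `conversion`
#' (else C); a methylated C as C with probability `protection` (else T).
#' Uniform substitution errors are added at rate `seq_error`. Mate 1 covers
#' the amplicon 5' end, mate 2 the 3' end (stored reverse-complemented, as
#' sequenced). Base qualities are Q37 except error-injected bases (Q12).
#'
#' @param profiles Tibble from [draw_individual_profiles()].
#' @param refs Allele references, default [synthetic_references()].
#' @param params [sim_params()].
#' @param seed Integer seed; the full path to FASTQ is deterministic.
#' @return Tibble with one row per read pair: `individual`, `region_id`,
#'   `read_id`, `allele_true`, `seq_1`, `qual_1`, `seq_2`, `qual_2`.
#' @export
simulate_reads <- function(profiles, refs = synthetic_references(),
                           params = sim_params(), seed = 1) {
  set.seed(seed)
  sites <- classify_contexts(refs)
  regions <- refs |> distinct(.data$region_id) |> pull()
  lens <- refs |> distinct(.data$region_id, len = nchar(.data$sequence))
  short <- lens$region_id[params$read_length > lens$len]
  if (length(short)) {
    warn(sprintf("read_length %d exceeds amplicon length; reads truncated to the amplicon in: %s",
                 params$read_length, paste(short, collapse = ", ")))
  }

  ped <- profiles |>
    distinct(.data$individual, .data$genotype) |>
    arrange(.data$individual)

  out <- vector("list", 0L)
  for (region in regions) {
    for (i in seq_len(nrow(ped))) {
      ind <- ped$individual[i]
      n_frag <- rpois(1, params$coverage)
      if (n_frag == 0) next
      al <- alleles_of(ped$genotype[i])
      frag_allele <- if (length(al) == 2) {
        al[rbinom(n_frag, 1, 0.5) + 1L]
      } else rep(al, n_frag)
      pieces <- vector("list", length(al))
      for (k in seq_along(al)) {
        idx <- which(frag_allele == al[k])
        if (!length(idx)) next
        lv <- profiles |>
          filter(.data$individual == ind, .data$region_id == region,
                 .data$allele == al[k]) |>
          select("motif", "level")
        st <- sites |>
          filter(.data$region_id == region, .data$allele_id == al[k]) |>
          left_join(lv, by = c(context = "motif"))
        ref_seq <- refs$sequence[refs$region_id == region &
                                   refs$allele_id == al[k]]
        pieces[[k]] <- simulate_fragments(length(idx), ref_seq, st, params) |>
          mutate(allele_true = al[k])
      }
      reads <- bind_rows(pieces)
      reads$individual <- ind
      reads$region_id <- region
      reads$read_id <- sprintf("%s:%s:%05d", ind, region, seq_len(nrow(reads)))
      out[[length(out) + 1L]] <- reads
    }
  }
  bind_rows(out) |>
    select("individual", "region_id", "read_id", "allele_true",
           "seq_1", "qual_1", "seq_2", "qual_2")
}

# vectorised fragment construction for one individual x region x allele batch
simulate_fragments <- function(n, ref_seq, site_tbl, params) {
  L <- nchar(ref_seq)
  chars <- strsplit(ref_seq, "")[[1]]
  m <- matrix(rep(chars, each = n), nrow = n)
  q <- matrix("F", nrow = n, ncol = L)  # Q37

  for (j in seq_len(nrow(site_tbl))) {
    p <- site_tbl$position[j]
    meth <- runif(n) < site_tbl$level[j]
    obs_c <- runif(n) < ifelse(meth, params$protection, 1 - params$conversion)
    m[, p] <- ifelse(obs_c, "C", "T")
  }
  # cytosines outside the site table (unresolvable-context edge cases) are
  # converted as unmethylated
  missing_c <- setdiff(which(chars == "C"), site_tbl$position)
  for (p in missing_c) {
    m[, p] <- ifelse(runif(n) < 1 - params$conversion, "C", "T")
  }

  if (params$seq_error > 0) {
    err <- which(matrix(runif(n * L) < params$seq_error, nrow = n))
    if (length(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- m[err]
      m[err] <- vapply(cur, function(b) sample(setdiff(bases, b), 1), "")
      q[err] <- "-"  # Q12
    }
  }

  rl <- min(params$read_length, L)
  frag <- apply(m, 1, paste, collapse = "")
  fq <- apply(q, 1, paste, collapse = "")
  seq_1 <- substr(frag, 1, rl)
  qual_1 <- substr(fq, 1, rl)
  tail_seq <- substr(frag, L - rl + 1, L)
  tail_q <- substr(fq, L - rl + 1, L)
  tibble(
    seq_1 = seq_1, qual_1 = qual_1,
    seq_2 = revcomp_chr(tail_seq),
    qual_2 = vapply(strsplit(tail_q, ""), function(x)
      paste(rev(x), collapse = ""), "")
  )
}

#' Write simulated read pairs as per-individual FASTQ files
#'
#' Files follow the `<population>_<individual>_R1.fastq` /
#' `..._R2.fastq` convention (Phred+33); the population label is everything
#' before the final underscore-delimited individual number.
#'
#' @param reads Tibble from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble of the files written.
#' @export
write_fastq_pairs <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- reads |>
    group_by(.data$individual) |>
    group_map(function(g, key) {
      base <- file.path(dir, key$individual)
      write_fastq(g$seq_1, g$qual_1, g$read_id, paste0(base, "_R1.fastq"))
      write_fastq(g$seq_2, g$qual_2, g$read_id, paste0(base, "_R2.fastq"))
      tibble(individual = key$individual,
             r1 = paste0(base, "_R1.fastq"), r2 = paste0(base, "_R2.fastq"))
    }) |>
    bind_rows()
  invisible(files)
}

write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
}
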