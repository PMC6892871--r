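#' Configuration of the synthetic trio simulation
#'
#' The simulator generates a small reference genome plus a father / mother /
#' offspring family with fully known ground truth, emulating the statistical
#' structure the audit assumes: independent parental heterozygosity,
#' Mendelian inheritance, planted germline and mosaic DNMs, Mendelian-
#' violation artifacts whose alleles are present in the parents (the dominant
#' real-data noise class), sibling-shared artifacts, caller-specific dropout
#' and false calls, genome masks, planted off-target sites and trio SV sets.
#'
#' Defaults describe the validation scenario: a 1-Mb genome, two offspring
#' against shared parents, 20 planted DNMs and 200 parental-allele artifacts
#' plus 5 sibling-shared artifacts per offspring, with error-free annotations
#' (noise knobs exist to exercise robustness, and all rates are
#' configuration, never hard-coded truths).
#'
#' @param genome_length Total genome size in bp (split evenly over chroms).
#' @param n_chroms Number of chromosomes.
#' @param seed Master seed; every stochastic step derives a purpose-local
#'   stream from it, so outputs are byte-identical per seed.
#' @param parental_het_rate Parental variants per bp (each parent).
#' @param parental_hom_fraction Fraction of parental variants that are
#'   homozygous alt rather than het.
#' @param n_offspring Offspring sharing the two parents.
#' @param dnm_count True DNMs planted per offspring.
#' @param mosaic_fraction_options Allele fractions assigned to planted DNMs
#'   (0.5 = single-cell stage, 0.25 = two-cell stage).
#' @param artifact_rate Parental-allele violation artifacts per offspring, as
#'   a fraction of the total parental variant count.
#' @param other_violation_rate Fraction of those artifacts built on a het
#'   parent instead of opposite homozygotes (still a parental-allele class).
#' @param shared_artifact_count Novel-allele artifacts duplicated across all
#'   offspring (removed only by cross filtering).
#' @param n_callers Number of simulated caller views.
#' @param caller_dropout Per-caller, per-site probability of missing a record.
#' @param caller_fp_rate Per-caller false calls per bp.
#' @param anno_error_fraction Fraction of sites given threshold-violating
#'   QD/MQ/GQ/strand annotations.
#' @param known_db_fraction Fraction of parental variants entered in the
#'   known-variant database.
#' @param mask_fraction Genome fraction covered by the random mask components.
#' @param depth_mean Mean sequencing depth.
#' @param depth_fixed Use exactly `depth_mean` (otherwise Poisson).
#' @param gq_high,gq_low Two-point genotype-quality distribution.
#' @param min_call_af Caller minimum allele frequency: a planted DNM is
#'   emitted as a het genotype iff its sampled alt reads reach
#'   `ceiling(min_call_af * DP)`.
#' @param sgRNA 20-nt protospacer planted once (with an NGG PAM) as the
#'   on-target site.
#' @param planted_offtarget_mismatches One off-target site is planted per
#'   entry, with exactly that many mismatches to the protospacer.
#' @param on_target_ratio Fraction of simulated target-region reads carrying
#'   a deletion at the cut site.
#' @param n_target_reads Simulated reads over the target window.
#' @param sv_inherited_count,sv_shared_count,sv_known_count,sv_denovo_count
#'   Planted SVs per class (de novo default 0).
#' @param sv_caller_specific_count Extra per-caller SVs (removed by the
#'   two-caller consensus).
#' @return A `trio_sim_config` list.
#' @export
trio_sim_config <- function(genome_length = 1e6,
                            n_chroms = 2,
                            seed = 1,
                            parental_het_rate = 1e-3,
                            parental_hom_fraction = 0.3,
                            n_offspring = 2,
                            dnm_count = 20,
                            mosaic_fraction_options = c(0.5, 0.25),
                            artifact_rate = 0.1,
                            other_violation_rate = 0.05,
                            shared_artifact_count = 5,
                            n_callers = 4,
                            caller_dropout = 0,
                            caller_fp_rate = 0,
                            anno_error_fraction = 0,
                            known_db_fraction = 0.5,
                            mask_fraction = 0.05,
                            depth_mean = 46,
                            depth_fixed = FALSE,
                            gq_high = 99,
                            gq_low = 10,
                            min_call_af = 0.10,
                            sgRNA = "CCTATGTTGAAGTGTGGTCA",
                            planted_offtarget_mismatches = c(1, 2, 3, 5, 7),
                            on_target_ratio = 0.435,
                            n_target_reads = 1000,
                            sv_inherited_count = 6,
                            sv_shared_count = 2,
                            sv_known_count = 3,
                            sv_denovo_count = 0,
                            sv_caller_specific_count = 2) {
  rates <- c(parental_het_rate, parental_hom_fraction, artifact_rate,
             other_violation_rate, caller_dropout, caller_fp_rate,
             anno_error_fraction, known_db_fraction, mask_fraction,
             min_call_af, on_target_ratio, other_violation_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1].")
  if (any(mosaic_fraction_options <= 0 | mosaic_fraction_options > 0.5)) {
    abort("`mosaic_fraction_options` must lie in (0, 0.5].")
  }
  if (!is_count(seed)) abort("`seed` must be a non-negative integer.")
  cfg <- as.list(environment())
  cfg$sgRNA <- toupper(sgRNA)
  if (nchar(cfg$sgRNA) == 23L) cfg$sgRNA <- substr(cfg$sgRNA, 1L, 20L)
  if (nchar(cfg$sgRNA) != 20L || grepl("[^ACGT]", cfg$sgRNA)) {
    abort("`sgRNA` must be a 20-nt A/C/G/T protospacer.")
  }
  structure(cfg, class = "trio_sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Write `insert` into `seqstr` so it occupies 0-based [at, at + nchar(insert)).
splice_in <- function(seqstr, at, insert) {
  paste0(substr(seqstr, 1L, at), insert,
         substr(seqstr, at + nchar(insert) + 1L, nchar(seqstr)))
}

#' Simulate a uniform-random reference genome with the on-target site planted
#'
#' The protospacer plus an NGG PAM is written once into the first chromosome
#' at a seeded position; its coordinates (and the registry of occupied
#' footprints) travel with the reference as attributes.
#'
#' @param config A [trio_sim_config()].
#' @return Named character vector of chromosome sequences, with attributes
#'   `on_target` (a one-row site tibble) and `occupied` (footprint registry).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "trio_sim_config"))
  per_chrom <- floor(config$genome_length / config$n_chroms)
  if (per_chrom < 1000L) {
    abort("genome too small: need >= 1 kb per chromosome to host planted sites")
  }
  with_purpose_seed(config$seed, "reference", {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    ref <- setNames(vapply(chroms, function(x) random_dna(per_chrom),
                           character(1)), chroms)
    a <- sample(100:(per_chrom - 130L), 1L) # 0-based footprint start
    cassette <- paste0(config$sgRNA, "CGG")
    ref[1] <- splice_in(ref[1], a, cassette)
    on_target <- tibble(chrom = chroms[1], start = a, strand = "+",
                        mismatches = 0L, pam = "CGG", is_on_target = TRUE,
                        fp_start = a, fp_end = a + 23L)
    attr(ref, "on_target") <- on_target
    attr(ref, "occupied") <- tibble(chrom = chroms[1], start = a,
                                    end = a + 23L)
    ref
  })
}

#' Plant off-target sites with controlled mismatch counts
#'
#' For each entry of `k_list`, one 23-bp site (protospacer copy with exactly
#' `k` substitutions plus a random NGG/NAG PAM) is written into the genome at
#' a seeded position on a random strand; positions colliding with previously
#' planted features are re-drawn.
#'
#' @param reference Reference from [simulate_reference()].
#' @param sgRNA 20-nt protospacer.
#' @param k_list Mismatch counts, one planted site each.
#' @param seed Seed for the purpose-local stream.
#' @return List with `reference` (edited genome, registry updated) and
#'   `sites` (tibble in [scan_offtargets()] layout).
#' @export
plant_offtargets <- function(reference, sgRNA, k_list, seed = 1) {
  occupied <- attr(reference, "occupied") %||%
    tibble(chrom = character(), start = integer(), end = integer())
  on_target <- attr(reference, "on_target")
  bases <- c("A", "C", "G", "T")
  with_purpose_seed(seed, "plant_offtargets", {
    sites <- list()
    for (k in k_list) {
      ps <- strsplit(sgRNA, "")[[1]]
      if (k > 0L) {
        idx <- sample(20L, k)
        for (i in idx) ps[i] <- sample(setdiff(bases, ps[i]), 1L)
      }
      pam <- paste0(sample(bases, 1L), sample(c("GG", "AG"), 1L))
      cassette <- paste0(paste(ps, collapse = ""), pam)
      strand <- sample(c("+", "-"), 1L)
      repeat {
        chrom <- sample(names(reference), 1L)
        L <- nchar(reference[[chrom]])
        a <- sample(50:(L - 80L), 1L)
        occ <- occupied[occupied$chrom == chrom, ]
        if (!any(a < occ$end + 10L & a + 23L > occ$start - 10L)) break
      }
      insert <- if (strand == "+") cassette else revcomp_str(cassette)
      reference[chrom] <- splice_in(reference[[chrom]], a, insert)
      occupied <- bind_rows(occupied,
                            tibble(chrom = chrom, start = a, end = a + 23L))
      sites[[length(sites) + 1L]] <- tibble(
        chrom = chrom,
        start = if (strand == "+") a else a + 22L,
        strand = strand, mismatches = as.integer(k),
        pam = pam, is_on_target = k == 0L, fp_start = a, fp_end = a + 23L)
    }
    attr(reference, "occupied") <- occupied
    attr(reference, "on_target") <- on_target
    list(reference = reference, sites = bind_rows(sites))
  })
}

#' Simulate the universal-mask components
#'
#' Random "mappability" and "repeat" intervals are placed until each covers
#' half of `mask_fraction` of the genome (so the merged random components hit
#' the target fraction closely), and every homopolymer run of 10 bp or more
#' is added as a "low-complexity" interval. Planted feature footprints are
#' never masked.
#'
#' @param config A [trio_sim_config()].
#' @param reference Reference genome (character vector).
#' @return Mask tibble (`chrom`, `start`, `end`, `component`).
#' @export
simulate_masks <- function(config, reference) {
  occupied <- attr(reference, "occupied") %||%
    tibble(chrom = character(), start = integer(), end = integer())
  with_purpose_seed(config$seed, "masks", {
    random_component <- function(label, target_bp) {
      out <- list()
      placed <- 0L
      guard <- 0L
      while (placed < target_bp && guard < 1e5) {
        guard <- guard + 1L
        chrom <- sample(names(reference), 1L)
        L <- nchar(reference[[chrom]])
        len <- min(sample(80:300, 1L), target_bp - placed + 79L)
        a <- sample(0:(L - len), 1L)
        occ <- occupied[occupied$chrom == chrom, ]
        if (any(a < occ$end + 45L & a + len > occ$start - 45L)) next
        out[[length(out) + 1L]] <- tibble(chrom = chrom, start = a,
                                          end = a + len)
        placed <- placed + len
      }
      if (length(out) == 0L) {
        return(tibble(chrom = character(), start = integer(),
                      end = integer(), component = character()))
      }
      merge_intervals(bind_rows(out)) |> mutate(component = label)
    }
    target <- floor(config$mask_fraction * config$genome_length / 2)
    homopolymers <- purrr::imap(reference, function(seqstr, chrom) {
      m <- gregexpr("A{10,}|C{10,}|G{10,}|T{10,}", seqstr)[[1]]
      if (m[1] == -1L) {
        return(tibble(chrom = character(), start = integer(),
                      end = integer()))
      }
      tibble(chrom = chrom, start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
    }) |> bind_rows()
    if (nrow(homopolymers) > 0L) {
      homopolymers <- homopolymers |> mutate(component = "low-complexity")
    } else {
      homopolymers <- tibble(chrom = character(), start = integer(),
                             end = integer(), component = character())
    }
    bind_rows(random_component("mappability", target),
              random_component("repeat", target),
              homopolymers) |>
      arrange(.data$chrom, .data$start)
  })
}

# positions (1-based) usable for planting a variant: outside masks, outside
# planted footprints, not already taken
sample_free_positions <- function(n, reference, masks, occupied, taken) {
  chrom_len <- vapply(reference, nchar, integer(1))
  pool_chrom <- sample(names(reference), 4L * n + 200L, replace = TRUE,
                       prob = chrom_len / sum(chrom_len))
  pool_pos <- floor(runif(length(pool_chrom)) *
                      (chrom_len[pool_chrom] - 4L)) + 2L
  keep <- rep(TRUE, length(pool_pos))
  for (cm in unique(pool_chrom)) {
    idx <- which(pool_chrom == cm)
    p0 <- pool_pos[idx] - 1L
    bad <- rep(FALSE, length(idx))
    m <- masks[masks$chrom == cm, ]
    if (nrow(m) > 0L) {
      bad <- bad | purrr::map_lgl(p0, function(p) any(p >= m$start &
                                                        p < m$end))
    }
    occ <- occupied[occupied$chrom == cm, ]
    if (nrow(occ) > 0L) {
      bad <- bad | purrr::map_lgl(p0, function(p)
        any(p >= occ$start - 1L & p < occ$end + 1L))
    }
    keep[idx] <- !bad
  }
  pool <- tibble(chrom = pool_chrom, pos = pool_pos)[keep, ] |>
    distinct() |>
    anti_join(taken, by = c("chrom", "pos"))
  if (nrow(pool) < n) {
    abort("not enough free genome positions to plant the requested variants")
  }
  pool[seq_len(n), ]
}

base_at <- function(reference, chrom, pos) {
  substr(reference[[chrom]], pos, pos)
}

alt_base <- function(ref_base) {
  vapply(ref_base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
         character(1))
}

#' Simulate the trio's true genotypes, DNMs, artifacts and known-variant set
#'
#' Parents carry independent variants at `parental_het_rate`; each offspring
#' inherits one allele per parent per site. Exactly `dnm_count` true DNMs per
#' offspring are planted at positions free of parental variants, masks and
#' planted features, each with an allele fraction drawn from
#' `mosaic_fraction_options`. Parental-allele violation artifacts (offspring
#' homozygous for an allele present in the parents) and sibling-shared
#' novel-allele artifacts are injected with class labels, so each artifact
#' class maps to exactly one cascade stage.
#'
#' @param config A [trio_sim_config()].
#' @param reference Reference from [simulate_reference()] (optionally after
#'   [plant_offtargets()]).
#' @return A `trio_truth` object: list with `genotypes` (long site-by-sample
#'   truth with sampling allele fractions), `true_dnms`, `artifacts`,
#'   `known_db`, `pedigree`, `samples`, `masks`, `config`.
#' @export
simulate_trio <- function(config, reference) {
  stopifnot(inherits(config, "trio_sim_config"))
  masks <- simulate_masks(config, reference)
  occupied <- attr(reference, "occupied") %||%
    tibble(chrom = character(), start = integer(), end = integer())
  offspring_ids <- paste0("O", seq_len(config$n_offspring))
  samples <- c("F", "M", offspring_ids)
  pedigree <- tibble(father = "F", mother = "M", offspring = offspring_ids)

  with_purpose_seed(config$seed, "trio", {
    taken <- tibble(chrom = character(), pos = integer())
    n_par <- round(config$genome_length * config$parental_het_rate)

    new_sites <- function(n) {
      sites <- sample_free_positions(n, reference, masks, occupied, taken)
      taken <<- bind_rows(taken, sites)
      sites |>
        mutate(ref = purrr::map2_chr(.data$chrom, .data$pos,
                                     function(c, p) base_at(reference, c, p)),
               alt = alt_base(.data$ref))
    }

    # -- parental variants, offspring inheritance ---------------------------
    parental <- list()
    for (parent in c("F", "M")) {
      sites <- new_sites(n_par)
      hom <- runif(n_par) < config$parental_hom_fraction
      g <- sites |>
        mutate(parent = parent, hom = hom,
               origin = paste0("parental_", parent))
      parental[[parent]] <- g
    }
    parental <- bind_rows(parental)

    geno <- list()
    for (i in seq_len(nrow(parental))) {
      s <- parental[i, ]
      carrier_a <- if (s$hom) c(s$alt, s$alt) else c(s$ref, s$alt)
      other <- c(s$ref, s$ref)
      rows <- tibble(
        chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
        sample = samples, origin = s$origin,
        a1 = NA_character_, a2 = NA_character_)
      for (j in seq_along(samples)) {
        sm <- samples[j]
        if (sm == s$parent) {
          rows$a1[j] <- carrier_a[1]; rows$a2[j] <- carrier_a[2]
        } else if (sm %in% c("F", "M")) {
          rows$a1[j] <- other[1]; rows$a2[j] <- other[2]
        } else {
          from_carrier <- if (s$hom) s$alt else sample(c(s$ref, s$alt), 1L)
          rows$a1[j] <- from_carrier; rows$a2[j] <- s$ref
        }
      }
      geno[[length(geno) + 1L]] <- rows
    }

    # -- true DNMs ----------------------------------------------------------
    true_dnms <- list()
    for (off in offspring_ids) {
      if (config$dnm_count == 0L) break
      sites <- new_sites(config$dnm_count)
      fr <- sample(config$mosaic_fraction_options, config$dnm_count,
                   replace = TRUE)
      true_dnms[[off]] <- sites |>
        mutate(offspring = off, fraction = fr)
      rows <- tidyr::expand_grid(i = seq_len(nrow(sites)), sample = samples) |>
        mutate(chrom = sites$chrom[.data$i], pos = sites$pos[.data$i],
               ref = sites$ref[.data$i], alt = sites$alt[.data$i],
               origin = "dnm",
               a1 = ifelse(.data$sample == off, sites$ref[.data$i],
                           sites$ref[.data$i]),
               a2 = ifelse(.data$sample == off, sites$alt[.data$i],
                           sites$ref[.data$i]),
               fraction = ifelse(.data$sample == off, fr[.data$i], 0)) |>
        select(-"i")
      geno[[length(geno) + 1L]] <- rows
    }
    true_dnms <- bind_rows(true_dnms)
    if (nrow(true_dnms) == 0L) {
      true_dnms <- tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          offspring = character(), fraction = double())
    }

    # -- parental-allele violation artifacts --------------------------------
    n_art <- round(config$artifact_rate * 2 * n_par)
    artifacts <- list()
    for (off in offspring_ids) {
      if (n_art == 0L) break
      sites <- new_sites(n_art)
      carrier <- sample(c("F", "M"), n_art, replace = TRUE)
      carrier_het <- runif(n_art) < config$other_violation_rate
      off_hom_alt <- runif(n_art) < 0.5
      for (i in seq_len(n_art)) {
        s <- sites[i, ]
        rows <- tibble(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                       sample = samples, origin = "artifact_parental",
                       a1 = s$ref, a2 = s$ref, fraction = 0)
        ci <- which(samples == carrier[i])
        if (carrier_het[i]) {
          rows$a1[ci] <- s$ref; rows$a2[ci] <- s$alt
          rows$fraction[ci] <- 0.5
        } else {
          rows$a1[ci] <- s$alt; rows$a2[ci] <- s$alt
          rows$fraction[ci] <- 1
        }
        # siblings not targeted by this artifact inherit consistently
        for (other in setdiff(offspring_ids, off)) {
          xi <- which(samples == other)
          if (!carrier_het[i]) {
            rows$a1[xi] <- s$ref; rows$a2[xi] <- s$alt
            rows$fraction[xi] <- 0.5
          }
        }
        oi <- which(samples == off)
        # offspring homozygous for one parental allele: a Mendelian violation
        # whose alleles all exist in the parents
        if (off_hom_alt[i] || carrier_het[i]) {
          rows$a1[oi] <- s$alt; rows$a2[oi] <- s$alt
          rows$fraction[oi] <- 1
        } else {
          # opposite-homozygote parents, offspring called ref/ref
          rows$a1[oi] <- s$ref; rows$a2[oi] <- s$ref
          rows$fraction[oi] <- 0
        }
        geno[[length(geno) + 1L]] <- rows
      }
      artifacts[[off]] <- sites |>
        mutate(offspring = off, class = "parental_allele")
    }

    # -- sibling-shared novel-allele artifacts ------------------------------
    if (config$shared_artifact_count > 0L) {
      sites <- new_sites(config$shared_artifact_count)
      for (i in seq_len(nrow(sites))) {
        s <- sites[i, ]
        rows <- tibble(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                       sample = samples, origin = "artifact_shared",
                       a1 = s$ref, a2 = s$ref, fraction = 0)
        for (off in offspring_ids) {
          oi <- which(samples == off)
          rows$a1[oi] <- s$ref; rows$a2[oi] <- s$alt
          rows$fraction[oi] <- 0.5
        }
        geno[[length(geno) + 1L]] <- rows
      }
      for (off in offspring_ids) {
        artifacts[[paste0(off, "_shared")]] <- sites |>
          mutate(offspring = off, class = "shared")
      }
    }
    artifacts <- bind_rows(artifacts)
    if (nrow(artifacts) == 0L) {
      artifacts <- tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          offspring = character(), class = character())
    }

    genotypes <- bind_rows(geno)
    if (!"fraction" %in% names(genotypes)) genotypes$fraction <- NA_real_
    genotypes <- genotypes |>
      mutate(fraction = dplyr::coalesce(
        .data$fraction,
        ifelse(.data$a1 == .data$alt & .data$a2 == .data$alt, 1,
               ifelse(.data$a1 == .data$alt | .data$a2 == .data$alt, 0.5, 0))))

    known_db <- parental |>
      filter(runif(dplyr::n()) < config$known_db_fraction) |>
      select("chrom", "pos", "alt")

    structure(
      list(genotypes = genotypes, true_dnms = true_dnms,
           artifacts = artifacts, known_db = known_db, pedigree = pedigree,
           samples = samples, masks = masks, config = config),
      class = "trio_truth")
  })
}

#' @export
print.trio_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic trio truth: %d samples, %d sites, %d true DNMs, %d artifacts\n",
    length(x$samples),
    nrow(distinct(x$genotypes, .data$chrom, .data$pos, .data$alt)),
    nrow(x$true_dnms), nrow(x$artifacts)))
  invisible(x)
}
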