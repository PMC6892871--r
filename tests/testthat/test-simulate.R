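test_that("reference simulation is deterministic and hosts the target site", {
  cfg <- small_sim_config(seed = 3)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(unclass(r1), unclass(r2))
  ot <- attr(r1, "on_target")
  win <- substr(r1[[ot$chrom]], ot$fp_start + 1L, ot$fp_end)
  expect_equal(win, paste0(cfg$sgRNA, "CGG"))
  expect_error(simulate_reference(small_sim_config(genome_length = 1500)),
               "1 kb")
})

test_that("simulated genome base composition is near-uniform", {
  cfg <- trio_sim_config(genome_length = 1e5, n_chroms = 1, seed = 5)
  r <- simulate_reference(cfg)
  gc <- sum(strsplit(r[[1]], "")[[1]] %in% c("G", "C")) / nchar(r[[1]])
  # binomial 3-sigma bound around 0.5
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5) + 1e-3)
})

test_that("trio truth respects Mendelian inheritance outside planted events", {
  cfg <- small_sim_config(seed = 13)
  ref <- simulate_reference(cfg)
  truth <- simulate_trio(cfg, ref)
  inherited <- truth$genotypes |>
    dplyr::filter(startsWith(origin, "parental")) |>
    tidyr::pivot_wider(id_cols = c(chrom, pos, ref, alt),
                       names_from = sample, values_from = c(a1, a2))
  consistent <- mapply(function(f1, f2, m1, m2, o1, o2) {
    (o1 %in% c(f1, f2) && o2 %in% c(m1, m2)) ||
      (o2 %in% c(f1, f2) && o1 %in% c(m1, m2))
  }, inherited$a1_F, inherited$a2_F, inherited$a1_M, inherited$a2_M,
     inherited$a1_O1, inherited$a2_O1)
  expect_true(all(consistent)) # exhaustive over all simulated sites

  # true DNM positions never collide with parental variants
  par_keys <- with(dplyr::filter(truth$genotypes,
                                 startsWith(origin, "parental")),
                   paste(chrom, pos))
  expect_false(any(paste(truth$true_dnms$chrom, truth$true_dnms$pos) %in%
                     par_keys))
  expect_equal(nrow(truth$true_dnms), 2L * cfg$dnm_count)
})

test_that("planted artifacts have the advertised genotype structure", {
  cfg <- small_sim_config(seed = 23)
  ref <- simulate_reference(cfg)
  truth <- simulate_trio(cfg, ref)
  art <- truth$artifacts |> dplyr::filter(class == "parental_allele")
  g <- truth$genotypes
  for (i in sample(nrow(art), 10)) {
    a <- art[i, ]
    rows <- g[g$chrom == a$chrom & g$pos == a$pos, ]
    parental <- unlist(rows[rows$sample %in% c("F", "M"), c("a1", "a2")])
    off <- rows[rows$sample == a$offspring, ]
    # offspring homozygous; both alleles present among the parents
    expect_equal(off$a1, off$a2)
    expect_true(all(c(off$a1, off$a2) %in% parental))
    # and yet the genotype violates Mendelian inheritance
    f <- unlist(rows[rows$sample == "F", c("a1", "a2")])
    m <- unlist(rows[rows$sample == "M", c("a1", "a2")])
    expect_false((off$a1 %in% f && off$a2 %in% m) ||
                   (off$a2 %in% f && off$a1 %in% m))
  }
  shared <- truth$artifacts |> dplyr::filter(class == "shared")
  expect_equal(nrow(shared), cfg$shared_artifact_count * cfg$n_offspring)
})

test_that("simulation with no planted DNMs yields empty truth", {
  cfg <- small_sim_config(seed = 29, dnm_count = 0)
  truth <- simulate_trio(cfg, simulate_reference(cfg))
  expect_equal(nrow(truth$true_dnms), 0L)
})

test_that("caller views are identical without dropout or false calls", {
  cfg <- small_sim_config(seed = 37)
  truth <- simulate_trio(cfg, simulate_reference(cfg))
  rendered <- render_caller_views(truth, cfg)
  expect_length(rendered$views, 4L)
  for (k in 2:4) {
    expect_identical(as.data.frame(rendered$views[[k]]),
                     as.data.frame(rendered$views[[1]]))
  }
  # false-positive sites are absent from truth by construction
  cfg2 <- small_sim_config(seed = 37, caller_fp_rate = 1e-4)
  rendered2 <- render_caller_views(truth, cfg2)
  truth_keys <- with(truth$genotypes, paste(chrom, pos))
  expect_false(any(with(rendered2$fp_sites, paste(chrom, pos)) %in%
                     truth_keys))
  expect_gt(nrow(rendered2$fp_sites), 0L)
})

test_that("rendered allelic depths are binomial at the planted fraction", {
  cfg <- trio_sim_config(genome_length = 8e5, seed = 41, dnm_count = 120,
                         mosaic_fraction_options = 0.25, depth_mean = 40,
                         depth_fixed = TRUE, artifact_rate = 0,
                         shared_artifact_count = 0,
                         parental_het_rate = 2e-4)
  truth <- simulate_trio(cfg, simulate_reference(cfg))
  rendered <- render_caller_views(truth, cfg)
  v <- rendered$views[[1]]
  dnm_rows <- dplyr::semi_join(
    v, truth$true_dnms,
    by = c("chrom", "pos", "ref", "alt")) |>
    dplyr::inner_join(truth$true_dnms |>
                        dplyr::select(chrom, pos, ref, alt, offspring),
                      by = c("chrom", "pos", "ref", "alt", sample = "offspring"))
  # mean alt reads across planted mosaics ~ Binomial(40, 0.25): mean 10
  n <- nrow(dnm_rows)
  expect_gt(n, 100) # nearly all DNMs are rendered at depth 40
  se <- sqrt(40 * 0.25 * 0.75 / n)
  expect_lt(abs(mean(dnm_rows$ad_alt) - 10), 4 * se)
})

test_that("simulated masks hit the requested fraction and homopolymers", {
  cfg <- small_sim_config(seed = 43, mask_fraction = 0.06)
  ref <- simulate_reference(cfg)
  masks <- simulate_masks(cfg, ref)
  expect_identical(masks, simulate_masks(cfg, ref)) # deterministic
  rand <- masks[masks$component %in% c("mappability", "repeat"), ]
  merged <- merge_intervals(rand)
  frac <- sum(merged$end - merged$start) / cfg$genome_length
  expect_lt(abs(frac - 0.06) / 0.06, 0.10) # within 10% relative

  zero <- simulate_masks(small_sim_config(seed = 43, mask_fraction = 0), ref)
  expect_true(all(zero$component == "low-complexity"))
  # every interval labelled low-complexity is a >= 10 bp homopolymer
  lc <- masks[masks$component == "low-complexity", ]
  for (i in seq_len(nrow(lc))) {
    run <- substr(ref[[lc$chrom[i]]], lc$start[i] + 1L, lc$end[i])
    expect_gte(nchar(run), 10L)
    expect_equal(length(unique(strsplit(run, "")[[1]])), 1L)
  }
})

test_that("planted off-target sites are recovered by re-scanning", {
  cfg <- small_sim_config(seed = 47,
                          planted_offtarget_mismatches = c(0, 3, 5, 7))
  ref <- simulate_reference(cfg)
  planted <- plant_offtargets(ref, cfg$sgRNA,
                              cfg$planted_offtarget_mismatches,
                              seed = cfg$seed)
  hits <- scan_offtargets(planted$reference, cfg$sgRNA, max_mismatches = 7)
  for (i in seq_len(nrow(planted$sites))) {
    s <- planted$sites[i, ]
    match <- hits[hits$chrom == s$chrom & hits$start == s$start &
                    hits$strand == s$strand, ]
    expect_equal(nrow(match), 1L)
    expect_equal(match$mismatches, s$mismatches)
  }
  expect_true(any(planted$sites$strand == "-")) # both strands exercised
})

test_that("target-read simulation produces the exact deletion count", {
  cfg <- small_sim_config(seed = 53)
  reads <- simulate_target_reads(cfg, cut_site = 5000L,
                                 on_target_ratio = 0.435, n_reads = 1000)
  expect_equal(on_target_ratio(reads, 5000L), 0.435)
  none <- simulate_target_reads(cfg, 5000L, on_target_ratio = 0, n_reads = 50)
  expect_equal(on_target_ratio(none, 5000L), 0)
  expect_error(simulate_target_reads(cfg, 5000L, n_reads = 0), "positive")
})
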