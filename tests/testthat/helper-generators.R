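# Random fixtures built in code under fixed seeds.

random_variant_table <- function(n_sites = 12, samples = c("F", "M", "O1"),
                                 multi_frac = 0.25) {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  pos_pool <- sort(sample(100:5000, n_sites))
  for (i in seq_len(n_sites)) {
    ref <- sample(bases, 1)
    n_alts <- if (runif(1) < multi_frac) 2L else 1L
    alts <- sample(setdiff(bases, ref), n_alts)
    # occasional indel alleles
    if (runif(1) < 0.3 && n_alts == 1L) {
      if (runif(1) < 0.5) {
        ref <- paste0(ref, paste(sample(bases, 2, TRUE), collapse = ""))
      } else {
        alts <- paste0(alts, paste(sample(bases, 2, TRUE), collapse = ""))
      }
    }
    qual <- if (runif(1) < 0.2) NA_real_ else round(runif(1, 20, 90), 1)
    qd <- if (runif(1) < 0.2) NA_real_ else round(runif(1, 2, 30), 2)
    mq <- if (runif(1) < 0.2) NA_real_ else round(runif(1, 30, 60), 1)
    has_sb <- runif(1) < 0.8
    sb <- if (has_sb) sample(0:30, 4, TRUE) else rep(NA_integer_, 4)
    alleles <- c(ref, alts)
    for (s in samples) {
      has_gt <- runif(1) < 0.9
      g <- if (has_gt) sample(alleles, 2, TRUE) else c(NA, NA)
      dp <- if (runif(1) < 0.15) NA_integer_ else sample(20:60, 1)
      gq <- if (runif(1) < 0.15) NA_integer_ else sample(10:99, 1)
      has_ad <- runif(1) < 0.85 && !is.na(dp)
      ad_ref <- if (has_ad) sample(0:20, 1) else NA_integer_
      ad_alts <- if (has_ad) sample(0:20, n_alts, TRUE) else
        rep(NA_integer_, n_alts)
      for (k in seq_len(n_alts)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = "chr1", pos = pos_pool[i], ref = ref, alt = alts[k],
          qual = qual, qd = qd, mq = mq,
          sr_fwd = sb[1], sr_rev = sb[2], sa_fwd = sb[3], sa_rev = sb[4],
          sample = s, a1 = g[1], a2 = g[2], dp = dp, gq = gq,
          ad_ref = ad_ref, ad_alt = ad_alts[k])
      }
    }
  }
  dplyr::bind_rows(rows)
}

# single-sample, single-site variant table for filter unit tests
one_site <- function(qd = 12, mq = 60, ad = c(22, 18), sb = NULL,
                     gt = c("A", "G"), dp = sum(ad), gq = 99,
                     ref = "A", alt = "G", pos = 101, sample = "O1") {
  if (is.null(sb)) {
    sb <- c(floor(ad[1] / 2), ceiling(ad[1] / 2),
            floor(ad[2] / 2), ceiling(ad[2] / 2))
  }
  tibble::tibble(
    chrom = "chr1", pos = pos, ref = ref, alt = alt, qual = 50,
    qd = qd, mq = mq, sr_fwd = sb[1], sr_rev = sb[2], sa_fwd = sb[3],
    sa_rev = sb[4], sample = sample, a1 = gt[1], a2 = gt[2],
    dp = dp, gq = gq, ad_ref = ad[1], ad_alt = ad[2])
}

# trio variant table from per-sample genotypes given as two-allele vectors
trio_site <- function(f, m, o, ref = "A", alt = "G", pos = 500,
                      dp = 40, gq = 99) {
  dplyr::bind_rows(
    one_site(gt = f, ref = ref, alt = alt, pos = pos, sample = "F",
             dp = dp, gq = gq, ad = c(20, 20)),
    one_site(gt = m, ref = ref, alt = alt, pos = pos, sample = "M",
             dp = dp, gq = gq, ad = c(20, 20)),
    one_site(gt = o, ref = ref, alt = alt, pos = pos, sample = "O1",
             dp = dp, gq = gq, ad = c(20, 20)))
}

random_sv <- function(n, chroms = c("chr1", "chr2"),
                      types = c("DEL", "DUP", "INV")) {
  start <- sample(0:50000, n, TRUE)
  len <- sample(60:4000, n, TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, TRUE), start = start, end = start + len,
    svtype = sample(types, n, TRUE), length = len,
    support = sample(11:30, n, TRUE), precise = TRUE, filter = "PASS",
    sample = "O1")
}

small_sim_config <- function(...) {
  args <- list(genome_length = 2e5, n_chroms = 2, parental_het_rate = 5e-4,
               dnm_count = 8, artifact_rate = 0.1, shared_artifact_count = 3)
  do.call(trio_sim_config, utils::modifyList(args, list(...)))
}
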