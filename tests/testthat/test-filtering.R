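test_that("site filter applies strict thresholds and bias rules", {
  # boundary: QD exactly at the cutoff fails (pass requires QD > 2.0)
  v <- one_site(qd = 2.0)
  sf <- site_filter(v)
  expect_false(sf$pass_sf)
  expect_match(sf$sf_reasons, "QD")

  # clean het site passes
  sf <- site_filter(one_site(qd = 12, mq = 60, ad = c(22, 18)))
  expect_true(sf$pass_sf)

  # MQ boundary
  expect_false(site_filter(one_site(mq = 30))$pass_sf)

  # allele bias: AB = 2/40 = 0.05 <= 0.1 and exact binomial p << 0.05
  v <- one_site(ad = c(38, 2), sb = c(19, 19, 1, 1))
  expect_lt(2 * pbinom(2, 40, 0.5), 0.05) # oracle for the binomial branch
  sf <- site_filter(v)
  expect_false(sf$pass_sf)
  expect_match(sf$sf_reasons, "AB")

  # a variant at exactly the minimum calling allele frequency is not
  # struck by the allele-bias rule (boundary is exclusive by default)
  v <- one_site(ad = c(36, 4), sb = c(18, 18, 2, 2))
  expect_true(site_filter(v)$pass_sf)
  expect_false(site_filter(v, filter_thresholds(ab_inclusive = TRUE))$pass_sf)

  # low allele balance but tiny depth: binomial test not significant
  v <- one_site(ad = c(4, 0), sb = c(2, 2, 0, 0))
  expect_gt(2 * pbinom(0, 4, 0.5), 0.05)
  expect_true(site_filter(v)$pass_sf)

  # strand bias: all alt reads on one strand, Fisher p < 0.05
  sb <- c(20, 20, 12, 0)
  p_oracle <- fisher.test(matrix(sb, 2, byrow = TRUE))$p.value
  expect_lt(p_oracle, 0.05)
  sf <- site_filter(one_site(ad = c(40, 12), sb = sb))
  expect_match(sf$sf_reasons, "SB")
})

test_that("missing site annotations are unevaluable, not failed", {
  sf <- site_filter(one_site(qd = NA_real_))
  expect_true(sf$pass_sf)
  expect_match(sf$sf_unevaluable, "QD")

  # no alt carrier: allele balance cannot be evaluated
  sf <- site_filter(one_site(gt = c("A", "A")))
  expect_match(sf$sf_unevaluable, "AB")
})

test_that("genotype filter uses strict open depth interval and GQ floor", {
  gf <- function(dp, gq) genotype_filter(one_site(dp = dp, gq = gq))$pass_gf
  expect_false(gf(15, 99)) # 15 < DP is strict
  expect_true(gf(16, 31))
  expect_false(gf(100, 99)) # DP < 100 is strict
  expect_false(gf(40, 30)) # GQ > 30 is strict
  expect_true(gf(40, 31))

  v <- genotype_filter(one_site(dp = NA_integer_))
  expect_false(v$pass_gf)
  expect_match(v$gf_unevaluable, "DP")
  expect_equal(v$gf_reasons, "")
})

test_that("raising thresholds never admits more records", {
  withr::with_seed(7, v <- random_variant_table(n_sites = 40))
  pass_n <- function(qd_min, gq_min, dp_max) {
    t <- filter_thresholds(qd_min = qd_min, gq_min = gq_min, dp_max = dp_max,
                           indel_dp_max = dp_max)
    sum(site_filter(v, t)$pass_sf) + sum(genotype_filter(v, t)$pass_gf)
  }
  base <- pass_n(2, 30, 100)
  expect_lte(pass_n(10, 30, 100), base)
  expect_lte(pass_n(2, 60, 100), base)
  expect_lte(pass_n(2, 30, 50), base)
})

test_that("universal mask removes intersecting REF spans", {
  mask <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L,
                         component = "merged")
  v <- one_site(pos = 15) # 0-based 14, inside [10, 20)
  expect_equal(nrow(apply_universal_mask(v, mask)), 0L)
  expect_equal(nrow(apply_universal_mask(v, mask[0, ])), 1L)
  # deletion whose span reaches into the mask from outside
  v <- one_site(pos = 8, ref = "AAAA", alt = "A")
  expect_equal(nrow(apply_universal_mask(v, mask)), 0L)

  for (case_seed in 1:5) {
    withr::with_seed(3000 + case_seed, {
      v <- random_variant_table(n_sites = 30)
      n <- sample(3:20, 1)
      start <- sample(0:5000, n, TRUE)
      mask <- merge_intervals(tibble::tibble(
        chrom = sample(c("chr1", "chr2"), n, TRUE), start = start,
        end = start + sample(5:200, n, TRUE)))
    })
    got <- apply_universal_mask(v, mask)
    want <- v[!oracle_masked(v, mask), ]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("universal mask build is a union merge and idempotent", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                      component = "mappability")
  b <- tibble::tibble(chrom = "chr1", start = 40L, end = 110L,
                      component = "repeat")
  um <- build_universal_mask(list(a, b))
  expect_equal(um$start, 0L)
  expect_equal(um$end, 150L)
  expect_equal(build_universal_mask(um), um)
})

test_that("filter stages commute as independent predicates", {
  withr::with_seed(11, v <- random_variant_table(n_sites = 30))
  v <- v[!is.na(v$dp) & !is.na(v$gq), ]
  mask <- tibble::tibble(chrom = "chr1", start = c(200L, 1500L),
                         end = c(600L, 2500L), component = "merged")
  t <- filter_thresholds()
  sf_keep <- function(x) {
    ok <- site_filter(x, t)
    dplyr::semi_join(x, ok[ok$pass_sf, c("chrom", "pos", "ref", "alt")],
                     by = c("chrom", "pos", "ref", "alt"))
  }
  gf_keep <- function(x) {
    g <- genotype_filter(x, t)
    bad <- dplyr::distinct(g[!g$pass_gf, c("chrom", "pos", "ref", "alt")])
    dplyr::anti_join(x, bad, by = c("chrom", "pos", "ref", "alt"))
  }
  um_keep <- function(x) apply_universal_mask(x, mask)
  orders <- list(c("sf", "gf", "um"), c("um", "gf", "sf"),
                 c("gf", "um", "sf"))
  results <- lapply(orders, function(ord) {
    x <- v
    for (step in ord) x <- switch(step, sf = sf_keep(x), gf = gf_keep(x),
                                  um = um_keep(x))
    dplyr::arrange(x, chrom, pos, alt, sample)
  })
  expect_equal(as.data.frame(results[[2]]), as.data.frame(results[[1]]))
  expect_equal(as.data.frame(results[[3]]), as.data.frame(results[[1]]))
})

test_that("indel normalisation left-aligns and is idempotent", {
  # context ...CAAT...: deleting the T of AT at pos 101 equals deleting
  # one A earlier — the left-aligned minimal form starts at the C-anchor
  seqstr <- paste0(strrep("G", 98), "CAAT", strrep("G", 60))
  ref <- c(chr1 = seqstr)
  v <- one_site(pos = 101, ref = "AT", alt = "A", gt = c("AT", "A"))
  got <- normalize_variants(v, ref)
  want <- oracle_normalize(seqstr, 101, "AT", "A")
  expect_equal(got$pos, want$pos)
  expect_equal(got$ref, want$ref)
  expect_equal(got$alt, want$alt)
  expect_equal(got$a1, want$ref) # genotype alleles remapped
  expect_equal(got$a2, want$alt)

  # SNV untouched
  s <- one_site(pos = 99, ref = "C", alt = "T", gt = c("C", "T"))
  expect_equal(normalize_variants(s, ref)$pos, 99)

  # idempotence and REF consistency check
  again <- normalize_variants(got, ref)
  expect_equal(as.data.frame(again), as.data.frame(got))
  bad <- one_site(pos = 101, ref = "TT", alt = "T", gt = c("TT", "T"))
  expect_error(normalize_variants(bad, ref), "REF mismatch")
})

test_that("random indels normalise to the exhaustive leftmost-minimal form", {
  withr::with_seed(99, {
    seqstr <- paste(sample(c("A", "C", "G", "T"), 400, TRUE,
                           prob = c(.4, .1, .1, .4)), collapse = "")
  })
  ref <- c(chr1 = seqstr)
  withr::with_seed(17, {
    cases <- lapply(1:10, function(i) {
      pos <- sample(50:300, 1)
      del <- runif(1) < 0.5
      if (del) {
        len <- sample(2:4, 1)
        list(pos = pos, ref = substr(seqstr, pos, pos + len - 1L),
             alt = substr(seqstr, pos, pos))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE),
                     collapse = "")
        list(pos = pos, ref = substr(seqstr, pos, pos),
             alt = paste0(substr(seqstr, pos, pos), ins))
      }
    })
  })
  for (cs in cases) {
    v <- one_site(pos = cs$pos, ref = cs$ref, alt = cs$alt,
                  gt = c(cs$ref, cs$alt))
    got <- normalize_variants(v, ref)
    want <- oracle_normalize(seqstr, cs$pos, cs$ref, cs$alt)
    expect_equal(got$pos, want$pos)
    expect_equal(got$ref, want$ref)
    expect_equal(got$alt, want$alt)
  }
})

test_that("caller intersection keeps only variants present in every set", {
  withr::with_seed(5, base <- random_variant_table(n_sites = 20))
  keys <- dplyr::distinct(base, chrom, pos, ref, alt)
  drop_one <- function(x, i) {
    dplyr::anti_join(x, keys[i, ], by = c("chrom", "pos", "ref", "alt"))
  }
  sets <- list(base, base, base, drop_one(base, 3))
  cons <- intersect_callers(sets)
  got_keys <- dplyr::distinct(cons, chrom, pos, ref, alt)
  expect_equal(nrow(got_keys), nrow(keys) - 1L)
  expect_false(nrow(dplyr::semi_join(keys[3, ], got_keys,
                                     by = names(keys))) > 0L)
  # consensus is a subset of every input, in any order
  perm <- intersect_callers(rev(sets))
  expect_setequal(variant_key(perm$chrom, perm$pos, perm$ref, perm$alt),
                  variant_key(cons$chrom, cons$pos, cons$ref, cons$alt))
  expect_error(intersect_callers(sets[1]), "at least two")
})

test_that("equivalent indel representations match after normalisation", {
  seqstr <- paste0(strrep("T", 49), "CAAAAG", strrep("T", 45))
  ref <- c(chr1 = seqstr)
  # the same single-A deletion in the A-run, written at both run ends
  left <- one_site(pos = 50, ref = "CA", alt = "C", gt = c("CA", "C"))
  right <- one_site(pos = 53, ref = "AA", alt = "A", gt = c("AA", "A"))
  sets <- lapply(list(left, right), normalize_variants, reference = ref)
  cons <- intersect_callers(sets)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$pos, 50)
  expect_equal(cons$ref, "CA")
})
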