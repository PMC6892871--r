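GUIDE <- "ACGTTGCAGGTCAATCCGGA"

test_that("protospacer input is validated and guide+PAM parsed", {
  ps <- protospacer(paste0(GUIDE, "TGG"))
  expect_equal(ps$seq, GUIDE)
  expect_error(protospacer("ACGT"), "20-nt")
  expect_error(protospacer(gsub("A", "N", GUIDE)), "A/C/G/T")
})

test_that("exact sites are found on both strands with correct coordinates", {
  genome <- c(chr1 = paste0("TTTTT", GUIDE, "CGG", "TTTTT"))
  hits <- scan_offtargets(genome, GUIDE, max_mismatches = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 5L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)
  expect_true(hits$is_on_target)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(GUIDE, "TGG"))))
  genome <- c(chr1 = paste0("CCCCCCC", rc, "CCCCCCC"))
  hits <- scan_offtargets(genome, GUIDE, max_mismatches = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$fp_start, 7L)
  # the recovered window reverse-complements back to protospacer+PAM
  win <- substr(genome[["chr1"]], hits$fp_start + 1L, hits$fp_end)
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(win))), paste0(GUIDE, "TGG"))
})

test_that("scan matches the brute-force Hamming oracle on random genomes", {
  for (case_seed in 1:3) {
    withr::with_seed(400 + case_seed, {
      genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                               collapse = ""),
                  chr2 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                               collapse = ""))
    })
    for (k in c(3L, 5L)) {
      got <- scan_offtargets(genome, GUIDE, max_mismatches = k)
      want <- oracle_scan(genome, GUIDE, k)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(got$pam, want$pam)
    }
  }
})

test_that("ambiguous-base windows are skipped", {
  genome <- c(chr1 = paste0("TTTTT", sub("^.", "N", GUIDE), "CGG", "TTTTT"))
  expect_equal(nrow(scan_offtargets(genome, GUIDE, max_mismatches = 5)), 0L)
})

test_that("site counts are monotone in mismatches and PAM set", {
  withr::with_seed(77, {
    genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 30000, TRUE),
                             collapse = ""))
  })
  counts <- vapply(c(3, 4, 5, 6, 7), function(k)
    nrow(scan_offtargets(genome, GUIDE, max_mismatches = k)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  ngg <- nrow(scan_offtargets(genome, GUIDE, 6, pam_rules = "NGG"))
  both <- nrow(scan_offtargets(genome, GUIDE, 6,
                               pam_rules = c("NGG", "NAG")))
  expect_gte(both, ngg)
})

test_that("strand symmetry: reverse-complemented genome mirrors sites", {
  withr::with_seed(88, {
    backbone <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                      collapse = "")
    # plant mutated guide copies on both strands so sites are guaranteed
    mutate_guide <- function(k) {
      g <- strsplit(GUIDE, "")[[1]]
      at <- sample(20, k)
      for (i in at) g[i] <- sample(setdiff(c("A", "C", "G", "T"), g[i]), 1)
      paste0(paste(g, collapse = ""), sample(c("AGG", "TAG", "CGG"), 1))
    }
    rc <- function(x) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(x)))
    inserts <- c(mutate_guide(1), mutate_guide(3), rc(mutate_guide(2)),
                 rc(mutate_guide(5)))
    at <- sort(sample(seq(1000, 18000, 1000), length(inserts)))
    for (i in seq_along(inserts)) {
      substr(backbone, at[i], at[i] + 22L) <- inserts[i]
    }
    genome <- c(chr1 = backbone)
  })
  L <- nchar(genome[["chr1"]])
  rc_genome <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome[["chr1"]]))))
  a <- scan_offtargets(genome, GUIDE, 6)
  b <- scan_offtargets(rc_genome, GUIDE, 6)
  expect_equal(nrow(a), nrow(b))
  mirrored <- tibble::tibble(
    fp_start = L - b$fp_end,
    strand = ifelse(b$strand == "+", "-", "+"),
    mismatches = b$mismatches)
  mirrored <- mirrored[order(mirrored$fp_start), ]
  expect_equal(mirrored$fp_start, a$fp_start)
  expect_equal(mirrored$strand, a$strand)
  expect_equal(mirrored$mismatches, a$mismatches)
  # cut sites mirror the same way
  cuts_a <- sort(cut_site_of(a))
  cuts_b <- sort(L - cut_site_of(b))
  expect_equal(cuts_a, cuts_b)
})

test_that("cut site sits 3 bp 5' of the PAM, strand-aware", {
  site <- tibble::tibble(chrom = "chr1", start = 100L, strand = "+",
                         fp_start = 100L, fp_end = 123L)
  expect_equal(cut_site_of(site), 117L)
  # on a minus-strand site the PAM is at the genomic left of the footprint
  site$strand <- "-"
  expect_equal(cut_site_of(site), 106L)
})

test_that("DNM proximity uses footprint +/- window with half-open boundary", {
  sites <- tibble::tibble(chrom = "chr1", start = 100L, strand = "+",
                          mismatches = 0L, pam = "AGG",
                          is_on_target = FALSE, fp_start = 100L,
                          fp_end = 123L)
  # positions are 1-based in dnm tables; footprint+window = [60, 163) 0-based
  dnms <- tibble::tibble(chrom = "chr1",
                         pos = c(110L, 61L, 60L, 163L, 164L),
                         ref = "A", alt = "G")
  out <- annotate_dnm_proximity(dnms, sites, window_bp = 40)
  expect_equal(out$near_offtarget, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  none <- annotate_dnm_proximity(dnms, sites[0, ])
  expect_false(any(none$near_offtarget))
})

test_that("on-target ratio counts deletion-bearing reads over the window", {
  mk_reads <- function(dels_at) {
    tibble::tibble(
      read_id = paste0("r", seq_along(dels_at)),
      aln_start = 900L, aln_end = 1100L,
      dels = lapply(dels_at, function(d) {
        if (is.na(d)) tibble::tibble(start = integer(), end = integer())
        else tibble::tibble(start = d, end = d + 5L)
      }))
  }
  reads <- mk_reads(c(1000L, NA, NA, NA))
  expect_equal(on_target_ratio(reads, cut_site = 1000L), 0.25)
  expect_equal(on_target_ratio(mk_reads(c(NA, NA)), 1000L), 0)
  expect_equal(on_target_ratio(mk_reads(c(999L, 1001L)), 1000L), 1)
  # a deletion far from the window does not count
  expect_equal(on_target_ratio(mk_reads(c(900L, NA)), 1000L), 0)
  far <- mk_reads(NA)
  far$aln_start <- 1L; far$aln_end <- 50L
  expect_error(on_target_ratio(far, 1000L), "no reads overlap")
})
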