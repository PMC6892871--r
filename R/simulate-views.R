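#' Render per-caller multi-sample call sets from trio truth
#'
#' All callers see the same sequencing experiment: depth, allelic depths and
#' site annotations are drawn once (per-allele depths binomially at the true
#' allele fraction) and shared across caller views; callers differ only by
#' dropout (missed records) and caller-specific false calls. A planted DNM is
#' emitted as a het genotype iff its sampled alt-read count reaches
#' `ceiling(min_call_af * DP)` — the caller-view detection rule — otherwise
#' the offspring is called homozygous reference. Sites where no sample
#' carries the alt allele produce no record.
#'
#' @param truth A `trio_truth` from [simulate_trio()].
#' @param config The [trio_sim_config()] used to build it.
#' @return List with `views` (named list of [variant_table] tibbles, one per
#'   caller), `detectable` (per planted DNM, did the reads support a call),
#'   and `fp_sites` (caller-specific false calls, class `caller_specific`).
#' @export
render_caller_views <- function(truth, config) {
  stopifnot(inherits(truth, "trio_truth"))
  g <- truth$genotypes
  with_purpose_seed(config$seed, "render", {
    n <- nrow(g)
    dp <- if (config$depth_fixed) rep(as.integer(config$depth_mean), n) else
      pmax(1L, rpois(n, config$depth_mean))
    ad_alt <- rbinom(n, dp, g$fraction)
    ad_ref <- dp - ad_alt
    min_reads <- as.integer(ceiling(config$min_call_af * dp))

    g <- g |>
      mutate(dp = dp, ad_alt = ad_alt, ad_ref = ad_ref,
             called_a1 = .data$a1, called_a2 = .data$a2)
    is_dnm_call <- g$origin == "dnm" & g$fraction > 0
    missed <- is_dnm_call & g$ad_alt < min_reads
    g$called_a1[missed] <- g$ref[missed]
    g$called_a2[missed] <- g$ref[missed]

    detectable <- g |>
      filter(is_dnm_call) |>
      transmute(offspring = .data$sample, .data$chrom, .data$pos, .data$ref,
                .data$alt, detectable = !missed[is_dnm_call])

    # site-level annotations, shared across callers
    site_ann <- g |>
      group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      summarise(sum_ref = sum(.data$ad_ref), sum_alt = sum(.data$ad_alt),
                .groups = "drop") |>
      mutate(qd = runif(dplyr::n(), 10, 35), mq = 60,
             # error-free reads are strand-balanced by construction; skew is
             # injected only through the annotation-error knob below
             sr_fwd = as.integer(floor(.data$sum_ref / 2)),
             sa_fwd = as.integer(floor(.data$sum_alt / 2)),
             sr_rev = as.integer(.data$sum_ref - .data$sr_fwd),
             sa_rev = as.integer(.data$sum_alt - .data$sa_fwd),
             gq_site = config$gq_high)
    if (config$anno_error_fraction > 0) {
      bad <- runif(nrow(site_ann)) < config$anno_error_fraction
      kind <- sample(c("QD", "MQ", "GQ", "SB"), nrow(site_ann),
                     replace = TRUE)
      site_ann <- site_ann |>
        mutate(qd = ifelse(bad & kind == "QD", 1.0, .data$qd),
               mq = ifelse(bad & kind == "MQ", 20, .data$mq),
               gq_site = ifelse(bad & kind == "GQ", config$gq_low,
                                .data$gq_site),
               # all alt reads pushed to one strand
               sa_fwd = ifelse(bad & kind == "SB",
                               as.integer(.data$sum_alt), .data$sa_fwd),
               sa_rev = ifelse(bad & kind == "SB", 0L, .data$sa_rev))
    }

    base <- g |>
      left_join(site_ann, by = c("chrom", "pos", "ref", "alt")) |>
      mutate(qual = 50, gq = as.integer(.data$gq_site),
             a1 = .data$called_a1, a2 = .data$called_a2) |>
      select(dplyr::all_of(vcf_call_cols))

    # a record exists only where some sample shows the alt allele
    evidenced <- base |>
      group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      filter(any(.data$a1 == .data$alt | .data$a2 == .data$alt,
                 na.rm = TRUE)) |>
      ungroup()
    site_keys <- evidenced |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt)

    views <- list()
    fp_sites <- list()
    n_fp <- round(config$caller_fp_rate * config$genome_length)
    for (k in seq_len(config$n_callers)) {
      caller <- paste0("caller", k)
      keep <- runif(nrow(site_keys)) >= config$caller_dropout
      v <- evidenced |>
        semi_join(site_keys[keep, ], by = c("chrom", "pos", "ref", "alt"))
      if (n_fp > 0L) {
        chroms <- paste0("chr", seq_len(config$n_chroms))
        chrom_len <- floor(config$genome_length / config$n_chroms)
        truth_keys <- paste(truth$genotypes$chrom, truth$genotypes$pos)
        fp <- tibble(chrom = sample(chroms, 3L * n_fp + 20L, replace = TRUE),
                     pos = sample(seq(10L, chrom_len - 10L),
                                  3L * n_fp + 20L, replace = TRUE)) |>
          distinct() |>
          filter(!paste(.data$chrom, .data$pos) %in% truth_keys) |>
          head(n_fp)
        if (nrow(fp) < n_fp) abort("could not place caller false calls")
        fp$ref <- sample(c("A", "C", "G", "T"), n_fp, replace = TRUE)
        fp$alt <- alt_base(fp$ref)
        carrier <- sample(truth$samples, n_fp, replace = TRUE)
        fp_rows <- tidyr::expand_grid(i = seq_len(n_fp),
                                      sample = truth$samples) |>
          mutate(chrom = fp$chrom[.data$i], pos = fp$pos[.data$i],
                 ref = fp$ref[.data$i], alt = fp$alt[.data$i],
                 qual = 50, qd = 20, mq = 60,
                 dp = as.integer(config$depth_mean),
                 het = .data$sample == carrier[.data$i],
                 a1 = .data$ref,
                 a2 = ifelse(.data$het, .data$alt, .data$ref),
                 ad_alt = ifelse(.data$het, as.integer(config$depth_mean / 2),
                                 0L),
                 ad_ref = .data$dp - .data$ad_alt,
                 gq = as.integer(config$gq_high)) |>
          group_by(.data$i) |>
          mutate(sr_fwd = as.integer(floor(sum(.data$ad_ref) / 2)),
                 sr_rev = as.integer(ceiling(sum(.data$ad_ref) / 2)),
                 sa_fwd = as.integer(floor(sum(.data$ad_alt) / 2)),
                 sa_rev = as.integer(ceiling(sum(.data$ad_alt) / 2))) |>
          ungroup() |>
          select(dplyr::all_of(vcf_call_cols))
        v <- bind_rows(v, fp_rows) |> arrange(.data$chrom, .data$pos)
        fp_sites[[caller]] <- fp |>
          mutate(caller = caller, class = "caller_specific")
      }
      views[[caller]] <- v
    }
    list(views = views, detectable = detectable,
         fp_sites = bind_rows(fp_sites))
  })
}

#' Simulate reads over the Cas9 target window
#'
#' Every read spans the cut site; exactly `round(on_target_ratio * n_reads)`
#' of them carry a deletion overlapping the cut boundary, so the computed
#' on-target ratio equals the input for exact-count construction.
#'
#' @param config A [trio_sim_config()].
#' @param cut_site 0-based cut boundary.
#' @param on_target_ratio Fraction of reads carrying a cut-site deletion.
#' @param n_reads Number of reads (> 0).
#' @return Read tibble for [on_target_ratio()]: `read_id`, `aln_start`,
#'   `aln_end`, `dels` (list-column).
#' @export
simulate_target_reads <- function(config, cut_site,
                                  on_target_ratio = config$on_target_ratio,
                                  n_reads = config$n_target_reads) {
  if (!is_count(n_reads) || n_reads <= 0) abort("`n_reads` must be positive.")
  if (on_target_ratio < 0 || on_target_ratio > 1) {
    abort("`on_target_ratio` must be in [0, 1].")
  }
  with_purpose_seed(config$seed, "target_reads", {
    n_del <- round(on_target_ratio * n_reads)
    has_del <- sample(rep(c(TRUE, FALSE), c(n_del, n_reads - n_del)))
    aln_start <- cut_site - sample(80:180, n_reads, replace = TRUE)
    aln_end <- aln_start + 250L
    dels <- purrr::map(seq_len(n_reads), function(i) {
      if (!has_del[i]) return(tibble(start = integer(), end = integer()))
      len <- sample(2:15, 1L)
      d0 <- cut_site - sample(0:(len - 1L), 1L)
      tibble(start = d0, end = d0 + len)
    })
    tibble(read_id = sprintf("read%04d", seq_len(n_reads)),
           aln_start = aln_start, aln_end = aln_end, dels = dels)
  })
}

#' Simulate per-caller trio SV call sets with known truth
#'
#' Plants inherited SVs (in one parent and one offspring), sibling-shared
#' artifacts (all offspring, no parent), known-database SVs, optional de novo
#' SVs, and per-caller-specific calls. Every truth SV appears in both caller
#' views with a small coordinate jitter in the second caller; planted SVs are
#' spaced so only planted relationships reciprocally overlap.
#'
#' @param config A [trio_sim_config()].
#' @return List with `svs` (tibble: `caller`, `sample`, SV columns),
#'   `known_db` (SV tibble) and `truth` (class-labelled planted SVs).
#' @export
simulate_svs <- function(config) {
  stopifnot(inherits(config, "trio_sim_config"))
  offspring_ids <- paste0("O", seq_len(config$n_offspring))
  chrom_len <- floor(config$genome_length / config$n_chroms)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  with_purpose_seed(config$seed, "svs", {
    slot <- 0L
    next_interval <- function() {
      slot <<- slot + 1L
      chrom <- chroms[(slot %% config$n_chroms) + 1L]
      start <- 1000L + (slot %/% config$n_chroms) * 8000L
      if (start + 4000L > chrom_len) {
        abort("genome too small for the requested SV counts")
      }
      len <- sample(100:3000, 1L)
      tibble(chrom = chrom, start = start, end = start + len,
             svtype = sample(c("DEL", "DUP", "INV"), 1L), length = len)
    }
    mk <- function(class, samples_carrying, in_db = FALSE) {
      iv <- next_interval()
      iv |> mutate(class = class, carriers = list(samples_carrying),
                   in_db = in_db)
    }
    truth <- list()
    for (i in seq_len(config$sv_inherited_count)) {
      truth[[length(truth) + 1L]] <-
        mk("inherited", c(sample(c("F", "M"), 1L),
                          sample(offspring_ids, 1L)))
    }
    if (config$sv_shared_count > 0L && length(offspring_ids) >= 2L) {
      for (i in seq_len(config$sv_shared_count)) {
        truth[[length(truth) + 1L]] <- mk("shared", offspring_ids)
      }
    }
    for (off in offspring_ids) {
      if (config$sv_known_count > 0L) {
        for (i in seq_len(config$sv_known_count)) {
          truth[[length(truth) + 1L]] <- mk("known_db", off, in_db = TRUE)
        }
      }
      if (config$sv_denovo_count > 0L) {
        for (i in seq_len(config$sv_denovo_count)) {
          truth[[length(truth) + 1L]] <- mk("de_novo", off)
        }
      }
    }
    truth <- bind_rows(truth)

    support <- function(n) 11L + rpois(n, 6)
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      for (sm in tr$carriers[[1]]) {
        for (caller in c("callerA", "callerB")) {
          jit <- if (caller == "callerB") sample(-10:10, 1L) else 0L
          rows[[length(rows) + 1L]] <- tibble(
            caller = caller, sample = sm, chrom = tr$chrom,
            start = tr$start + jit, end = tr$end + jit,
            svtype = tr$svtype, length = tr$length,
            support = support(1L), precise = TRUE, filter = "PASS")
        }
      }
    }
    # caller-specific extras: present in one caller only
    for (caller in c("callerA", "callerB")) {
      if (config$sv_caller_specific_count == 0L) break
      for (i in seq_len(config$sv_caller_specific_count)) {
        iv <- next_interval()
        rows[[length(rows) + 1L]] <- iv |>
          select(-"length") |>
          mutate(caller = caller, sample = sample(offspring_ids, 1L),
                 length = iv$length, support = support(1L), precise = TRUE,
                 filter = "PASS")
      }
    }
    svs <- bind_rows(rows)
    known_db <- truth |>
      filter(.data$in_db) |>
      distinct(.data$chrom, .data$start, .data$end, .data$svtype,
               .data$length)
    list(svs = svs, known_db = known_db,
         truth = truth |> select(-"in_db"))
  })
}

#' Run the SV consensus and de novo filtering on a simulated SV set
#'
#' Per sample: short-read hard filtering of each caller's calls, then
#' two-caller consensus by reciprocal overlap. Per offspring: de novo
#' filtering against both parents' consensus sets, the known-SV database and
#' the siblings' consensus sets.
#'
#' @param sv_sim Output of [simulate_svs()].
#' @param cfg An [sv_filter_config()].
#' @return List with `consensus` (per sample) and `de_novo` (per offspring).
#' @export
run_sv_pipeline <- function(sv_sim, cfg = sv_filter_config()) {
  svs <- sv_sim$svs
  samples <- unique(svs$sample)
  consensus <- list()
  for (sm in samples) {
    a <- svs |> filter(.data$caller == "callerA", .data$sample == sm) |>
      filter_sv_shortread(cfg) |> filter(.data$pass_sv)
    b <- svs |> filter(.data$caller == "callerB", .data$sample == sm) |>
      filter_sv_shortread(cfg) |> filter(.data$pass_sv)
    consensus[[sm]] <- intersect_sv_callers(a, b, cfg$reciprocal_threshold,
                                            cfg)
  }
  offspring_ids <- grep("^O", samples, value = TRUE)
  empty_sv <- svs[0, setdiff(names(svs), "caller"), drop = FALSE]
  de_novo <- list()
  for (off in offspring_ids) {
    sibs <- setdiff(offspring_ids, off)
    de_novo[[off]] <- de_novo_sv_filter(
      consensus[[off]] %||% empty_sv,
      parent_sets = list(consensus[["F"]] %||% empty_sv,
                         consensus[["M"]] %||% empty_sv),
      known_db = sv_sim$known_db,
      sibling_sets = lapply(sibs, function(s) consensus[[s]] %||% empty_sv),
      threshold = cfg$reciprocal_threshold, cfg = cfg)
  }
  list(consensus = consensus, de_novo = de_novo)
}
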