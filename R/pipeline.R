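#' End-to-end self-test on a synthetic trio with known truth
#'
#' Simulates a reference (with on-target and off-target sites planted), a
#' family with planted DNMs and artifacts, and four caller views; runs the
#' full audit — hard filtering, caller intersection, the DNM cascade,
#' off-target scanning with proximity annotation, target-read mosaic ratio,
#' SV consensus and de novo filtering, and the detection-power model — and
#' scores every stage against the simulator's ground truth.
#'
#' @param config A [trio_sim_config()].
#' @param thresholds A [filter_thresholds()].
#' @param sv_cfg An [sv_filter_config()].
#' @param write_dir Optional directory: when given, the reference FASTA,
#'   per-caller VCFs, mask BED, known-variant VCF and truth tables are
#'   written there.
#' @return A `trio_selftest` object.
#' @export
run_selftest <- function(config = trio_sim_config(),
                         thresholds = filter_thresholds(),
                         sv_cfg = sv_filter_config(),
                         write_dir = NULL) {
  reference <- simulate_reference(config)
  planted <- plant_offtargets(reference, config$sgRNA,
                              config$planted_offtarget_mismatches,
                              seed = config$seed)
  reference <- planted$reference
  on_target <- attr(reference, "on_target")

  truth <- simulate_trio(config, reference)
  mask <- build_universal_mask(truth$masks)
  rendered <- render_caller_views(truth, config)

  filtered <- lapply(rendered$views, apply_hard_filters,
                     thresholds = thresholds, mask = mask)
  caller_funnels <- purrr::imap(filtered, function(v, nm)
    tibble(caller = nm, stage = names(attr(v, "funnel")),
           n = unname(attr(v, "funnel")))) |> bind_rows()

  dnm_res <- run_dnm_pipeline(filtered, truth$pedigree,
                              known_db = truth$known_db)
  truth$true_dnms <- truth$true_dnms |>
    left_join(rendered$detectable,
              by = c("offspring", "chrom", "pos", "ref", "alt"))
  scores <- score_against_truth(dnm_res$final, truth)

  # off-target audit: rescan the edited genome, check planted recovery,
  # annotate final DNMs for proximity
  max_k <- max(c(0L, config$planted_offtarget_mismatches))
  sites <- scan_offtargets(reference, protospacer(config$sgRNA),
                           max_mismatches = max_k)
  planted_sites <- bind_rows(on_target, planted$sites)
  recovered <- planted_sites |>
    left_join(sites |> mutate(found = TRUE) |>
                select("chrom", "start", "strand", "found"),
              by = c("chrom", "start", "strand")) |>
    mutate(found = !is.na(.data$found))
  dnm_proximity <- bind_rows(dnm_res$final) |>
    annotate_dnm_proximity(sites, window_bp = 40)

  cut <- cut_site_of(on_target)
  reads <- simulate_target_reads(config, cut)
  otr <- on_target_ratio(reads, cut)

  sv_sim <- simulate_svs(config)
  sv_res <- run_sv_pipeline(sv_sim, sv_cfg)
  sv_truth_dn <- sv_sim$truth |> filter(.data$class == "de_novo")
  sv_found <- bind_rows(sv_res$de_novo)
  sv_key <- function(x) paste(x$chrom, x$start, x$svtype)
  sv_tp <- sum(sv_key(sv_found) %in% sv_key(sv_truth_dn))
  sv_scores <- tibble(
    planted_de_novo = nrow(sv_truth_dn), called_de_novo = nrow(sv_found),
    tp = sv_tp,
    precision = ifelse(nrow(sv_found) == 0, NA_real_,
                       sv_tp / nrow(sv_found)),
    recall = ifelse(nrow(sv_truth_dn) == 0, NA_real_,
                    sv_tp / nrow(sv_truth_dn)))

  power <- power_model(depth = round(config$depth_mean),
                       min_af = config$min_call_af)

  checks <- selftest_checks(config, dnm_res, scores, recovered, sv_scores)

  out <- structure(
    list(config = config, truth = truth, funnel = dnm_res$funnel,
         caller_funnels = caller_funnels, dnm = dnm_res, scores = scores,
         offtarget_sites = sites, planted_offtargets = recovered,
         dnm_proximity = dnm_proximity, on_target_ratio = otr,
         sv = sv_res, sv_scores = sv_scores, power = power,
         checks = checks),
    class = "trio_selftest")
  if (!is.null(write_dir)) write_selftest_outputs(out, rendered, write_dir)
  out
}

selftest_checks <- function(config, dnm_res, scores, recovered, sv_scores) {
  monotone <- dnm_res$funnel |>
    group_by(.data$offspring) |>
    summarise(ok = all(diff(.data$n) <= 0), .groups = "drop")
  checks <- tibble(check = "funnel_monotone", pass = all(monotone$ok))
  checks <- bind_rows(checks, tibble(
    check = "planted_offtargets_recovered", pass = all(recovered$found)))
  error_free <- config$caller_dropout == 0 && config$caller_fp_rate == 0 &&
    config$anno_error_fraction == 0
  if (error_free) {
    leak_cols <- grep("^leaked_", names(scores), value = TRUE)
    checks <- bind_rows(
      checks,
      tibble(check = "perfect_precision",
             pass = all(scores$precision == 1, na.rm = TRUE)),
      tibble(check = "perfect_recall_detectable",
             pass = all(scores$recall_detectable == 1, na.rm = TRUE)),
      tibble(check = "zero_artifact_leakage",
             pass = all(purrr::map_lgl(leak_cols, function(cn)
               all(scores[[cn]] == 0)))),
      tibble(check = "sv_de_novo_exact",
             pass = sv_scores$called_de_novo == sv_scores$tp &&
               sv_scores$tp == sv_scores$planted_de_novo))
  }
  checks
}

write_selftest_outputs <- function(x, rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- x$config
  ref <- simulate_reference(cfg)
  ref <- plant_offtargets(ref, cfg$sgRNA, cfg$planted_offtarget_mismatches,
                          seed = cfg$seed)$reference
  write_fasta(ref, file.path(dir, "reference.fa"))
  write_bed(x$truth$masks, file.path(dir, "universal_mask.bed"))
  for (nm in names(rendered$views)) {
    write_vcf(rendered$views[[nm]], file.path(dir, paste0(nm, ".vcf")),
              samples = x$truth$samples)
  }
  readr::write_tsv(x$truth$true_dnms, file.path(dir, "truth_dnms.tsv"))
  readr::write_tsv(x$truth$artifacts, file.path(dir, "truth_artifacts.tsv"))
  readr::write_tsv(x$funnel, file.path(dir, "dnm_funnel.tsv"))
  readr::write_tsv(run_report(x), file.path(dir, "report.tsv"))
  invisible(dir)
}

#' @export
print.trio_selftest <- function(x, ...) {
  cat("Trio off-target audit self-test\n")
  cat(sprintf("  seed %d, genome %.2g bp, %d offspring\n",
              x$config$seed, x$config$genome_length, x$config$n_offspring))
  print(run_report(x))
  cat("checks:\n")
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s\n", ifelse(x$checks$pass[i], "ok", "FAIL"),
                x$checks$check[i]))
  }
  invisible(x)
}

#' @method tidy trio_selftest
#' @export
tidy.trio_selftest <- function(x, ...) {
  x$funnel
}

#' @method glance trio_selftest
#' @export
glance.trio_selftest <- function(x, ...) {
  run_report(x)
}

#' Per-offspring summary report of a self-test run
#'
#' One row per offspring: depth, on-target ratio, raw candidate DNMs and the
#' final SNV/INDEL counts, plus truth-comparison precision and recall.
#'
#' @param x A `trio_selftest`.
#' @param path Optional TSV output path.
#' @return The report tibble.
#' @export
run_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "trio_selftest"))
  counts <- summarize_dnms(x$dnm$final)
  candidates <- x$funnel |>
    filter(.data$stage == "Raw") |>
    select("offspring", candidate_dnms = "n")
  report <- counts |>
    left_join(candidates, by = "offspring") |>
    left_join(x$scores |>
                select("offspring", "precision", "recall",
                       "recall_detectable"),
              by = "offspring") |>
    mutate(depth = x$config$depth_mean,
           on_target_ratio = x$on_target_ratio) |>
    select("offspring", "depth", "on_target_ratio", "candidate_dnms",
           final_snv = "snv", final_indel = "indel", final_total = "total",
           "precision", "recall", "recall_detectable")
  if (!is.null(path)) readr::write_tsv(report, path)
  report
}

#' Funnel plot for a self-test run
#'
#' @param object A `trio_selftest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trio_selftest
#' @export
autoplot.trio_selftest <- function(object, ...) {
  autoplot(object$dnm)
}
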