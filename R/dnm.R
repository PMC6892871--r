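#' Detect Mendelian-violation DNM candidates in a trio
#'
#' A site is a candidate when the offspring genotype cannot be formed by
#' drawing one allele from each parent's genotype. This is a deliberately
#' permissive front end: the downstream cascade (caller overlap, allele,
#' known-variant and sibling cross filtering) defines the final set.
#' Sites with a missing genotype in any trio member are skipped and counted
#' in the `"skipped"` attribute.
#'
#' @param variants A [variant_table] tibble holding all three trio samples.
#' @param father,mother,offspring Sample identifiers.
#' @return Candidate tibble: variant key columns, the three genotypes
#'   (`o1`,`o2`,`f1`,`f2`,`m1`,`m2`), offspring `dp`/`ad_alt`, `offspring`
#'   sample id and `class` (`"SNV"` or `"INDEL"`).
#' @export
detect_dnm_candidates <- function(variants, father, mother, offspring) {
  stop_if_not_tbl(variants, vcf_call_cols, "variants")
  wide <- variants |>
    filter(.data$sample %in% c(father, mother, offspring)) |>
    mutate(role = dplyr::case_when(.data$sample == father ~ "f",
                                   .data$sample == mother ~ "m",
                                   TRUE ~ "o")) |>
    select("chrom", "pos", "ref", "alt", "role", "a1", "a2", "dp", "ad_alt") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("a1", "a2", "dp", "ad_alt"))
  need <- c("a1_f", "a2_f", "a1_m", "a2_m", "a1_o", "a2_o")
  for (cn in setdiff(need, names(wide))) wide[[cn]] <- NA_character_
  complete <- !is.na(wide$a1_f) & !is.na(wide$a1_m) & !is.na(wide$a1_o)
  skipped <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  consistent <- purrr::pmap_lgl(
    wide[, need],
    function(a1_f, a2_f, a1_m, a2_m, a1_o, a2_o) {
      f <- c(a1_f, a2_f); m <- c(a1_m, a2_m)
      (a1_o %in% f && a2_o %in% m) || (a2_o %in% f && a1_o %in% m)
    })
  out <- wide[!consistent, , drop = FALSE] |>
    transmute(.data$chrom, .data$pos, .data$ref, .data$alt,
              o1 = .data$a1_o, o2 = .data$a2_o,
              f1 = .data$a1_f, f2 = .data$a2_f,
              m1 = .data$a1_m, m2 = .data$a2_m,
              dp = .data$dp_o, ad_alt = .data$ad_alt_o,
              offspring = offspring,
              class = ifelse(nchar(.data$ref) == 1L & nchar(.data$alt) == 1L,
                             "SNV", "INDEL"))
  attr(out, "skipped") <- skipped
  out
}

#' Intersect DNM candidates across callers
#'
#' Keeps a candidate iff its (chrom, pos, ref, alt) key appears in every
#' caller's candidate list; rows are reported from the first (primary) caller
#' with the caller support count attached.
#'
#' @param per_caller A list (>= 1) of candidate tibbles from
#'   [detect_dnm_candidates()].
#' @return The consensus candidate tibble (`caller_support` column added).
#' @export
overlap_candidates <- function(per_caller) {
  if (!is.list(per_caller) || length(per_caller) < 1L) {
    abort("`per_caller` must be a non-empty list of candidate tables.")
  }
  keysets <- lapply(per_caller, function(x)
    unique(variant_key(x$chrom, x$pos, x$ref, x$alt)))
  shared <- Reduce(intersect, keysets)
  primary <- per_caller[[1]]
  primary[variant_key(primary$chrom, primary$pos, primary$ref,
                      primary$alt) %in% shared, , drop = FALSE] |>
    mutate(caller_support = length(per_caller))
}

#' Allele filtering of DNM candidates
#'
#' Retains a candidate iff at least one offspring allele is absent from both
#' parents' genotypes — a genuinely novel allele. This removes the dominant
#' artifact class: Mendelian violations whose alleles all exist in the
#' parents (e.g. parents AA and GG, offspring called AA or GG instead of AG).
#'
#' @param candidates Candidate tibble with `o1`,`o2`,`f1`,`f2`,`m1`,`m2`.
#' @return The retained subset.
#' @export
allele_filter <- function(candidates) {
  stop_if_not_tbl(candidates, c("o1", "o2", "f1", "f2", "m1", "m2"),
                  "candidates")
  novel <- purrr::pmap_lgl(
    candidates[, c("o1", "o2", "f1", "f2", "m1", "m2")],
    function(o1, o2, f1, f2, m1, m2) {
      parental <- c(f1, f2, m1, m2)
      !(o1 %in% parental) || !(o2 %in% parental)
    })
  candidates[novel, , drop = FALSE]
}

#' Known-variant (dbSNP-style) filtering
#'
#' Removes candidates whose key is present in a known-variant database.
#' By default the key is allele-specific (chrom, pos, alt): a different alt
#' allele at a known position is still novel. Position-only matching is
#' available via `match_alt = FALSE`.
#'
#' @param candidates Candidate tibble.
#' @param db Tibble with columns `chrom`, `pos`, `alt` (alt ignored when
#'   `match_alt = FALSE`).
#' @param match_alt Include the alt allele in the lookup key.
#' @return The retained subset.
#' @export
dbsnp_filter <- function(candidates, db, match_alt = TRUE) {
  stop_if_not_tbl(candidates, c("chrom", "pos", "alt"), "candidates")
  if (is.null(db) || nrow(db) == 0L) return(candidates)
  stop_if_not_tbl(db, if (match_alt) c("chrom", "pos", "alt")
                  else c("chrom", "pos"), "db")
  if (match_alt) {
    keys <- paste(db$chrom, db$pos, db$alt)
    hit <- paste(candidates$chrom, candidates$pos, candidates$alt) %in% keys
  } else {
    keys <- paste(db$chrom, db$pos)
    hit <- paste(candidates$chrom, candidates$pos) %in% keys
  }
  candidates[!hit, , drop = FALSE]
}

#' Cross filtering: drop candidates shared between offspring
#'
#' A candidate whose variant key appears in two or more siblings' candidate
#' sets is removed from every set: independent de novo events at the same
#' position with the same allele are vanishingly unlikely, so shared keys are
#' systematic artifacts (or miscalled inherited variants).
#'
#' @param per_offspring Named list of candidate tibbles, one per offspring
#'   sharing parent(s).
#' @return List of filtered tibbles (same names). With a single offspring the
#'   input is returned with a warning.
#' @export
cross_filter <- function(per_offspring) {
  if (!is.list(per_offspring) || length(per_offspring) == 0L) {
    abort("`per_offspring` must be a non-empty list.")
  }
  if (length(per_offspring) == 1L) {
    warn("cross filtering needs >= 2 offspring; returning input unchanged")
    return(per_offspring)
  }
  keysets <- lapply(per_offspring, function(x)
    unique(variant_key(x$chrom, x$pos, x$ref, x$alt)))
  tab <- table(unlist(keysets))
  shared <- names(tab)[tab >= 2L]
  lapply(per_offspring, function(x)
    x[!variant_key(x$chrom, x$pos, x$ref, x$alt) %in% shared, , drop = FALSE])
}

#' Run the full DNM filtration cascade for one or more offspring
#'
#' For each offspring: per-caller Mendelian-violation detection (Raw),
#' caller intersection (noStrict), allele filtering (AF), known-variant
#' filtering (dbSNPF), then sibling cross filtering across offspring (CF).
#'
#' @param caller_views Named list of filtered [variant_table] tibbles, one
#'   per caller, each holding all samples.
#' @param pedigree Tibble with columns `father`, `mother`, `offspring`, one
#'   row per offspring (siblings share parents across rows).
#' @param known_db Optional known-variant tibble (`chrom`, `pos`, `alt`).
#' @return A `dnm_result`: list with `final` (named list of candidate
#'   tibbles) and `funnel` (per-offspring stage counts).
#' @export
run_dnm_pipeline <- function(caller_views, pedigree, known_db = NULL) {
  stop_if_not_tbl(pedigree, c("father", "mother", "offspring"), "pedigree")
  if (!is.list(caller_views) || length(caller_views) < 1L) {
    abort("`caller_views` must be a non-empty list of variant tables.")
  }
  stages <- c("Raw", "noStrict", "AF", "dbSNPF", "CF")
  funnel <- list()
  pre_cf <- list()
  for (i in seq_len(nrow(pedigree))) {
    off <- pedigree$offspring[i]
    per_caller <- lapply(caller_views, detect_dnm_candidates,
                         father = pedigree$father[i],
                         mother = pedigree$mother[i], offspring = off)
    raw_n <- nrow(per_caller[[1]])
    ns <- overlap_candidates(per_caller)
    af <- allele_filter(ns)
    db <- dbsnp_filter(af, known_db)
    pre_cf[[off]] <- db
    funnel[[off]] <- tibble(offspring = off,
                            stage = factor(stages, levels = stages),
                            n = c(raw_n, nrow(ns), nrow(af), nrow(db), NA))
  }
  final <- if (length(pre_cf) >= 2L) cross_filter(pre_cf) else pre_cf
  for (off in names(final)) {
    funnel[[off]]$n[funnel[[off]]$stage == "CF"] <- nrow(final[[off]])
  }
  structure(list(final = final, funnel = bind_rows(funnel)),
            class = "dnm_result")
}

#' @export
print.dnm_result <- function(x, ...) {
  cat("DNM filtration cascade\n")
  print(glance(x))
  invisible(x)
}

#' @method tidy dnm_result
#' @export
tidy.dnm_result <- function(x, ...) {
  bind_rows(x$final)
}

#' @method glance dnm_result
#' @export
glance.dnm_result <- function(x, ...) {
  summarize_dnms(x$final)
}

#' Per-offspring DNM counts by class
#'
#' @param final_sets A named list of final candidate tibbles (or a single
#'   tibble with an `offspring` column).
#' @return Tibble with `offspring`, `snv`, `indel`, `total`.
#' @export
summarize_dnms <- function(final_sets) {
  if (is.data.frame(final_sets)) {
    final_sets <- split(final_sets, final_sets$offspring)
  }
  purrr::imap(final_sets, function(x, off) {
    is_snv <- nchar(x$ref) == 1L & nchar(x$alt) == 1L
    tibble(offspring = off, snv = sum(is_snv), indel = sum(!is_snv),
           total = nrow(x))
  }) |> bind_rows()
}

#' Funnel plot of the DNM filtration cascade
#'
#' @param object A `dnm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dnm_result
#' @export
autoplot.dnm_result <- function(object, ...) {
  ggplot2::ggplot(object$funnel,
                  ggplot2::aes(x = .data$stage, y = .data$n,
                               group = .data$offspring,
                               colour = .data$offspring)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cascade stage", y = "candidate DNMs (log scale)",
                  colour = "offspring") +
    ggplot2::theme_minimal()
}

#' Score final DNM calls against simulator truth
#'
#' Exact variant-key matching against the planted DNMs. Recall is reported
#' both against all planted DNMs and against the detectable subset (those
#' whose rendered alt-read count met the caller-view calling rule), since no
#' pipeline can recover a mutation the reads do not support.
#'
#' @param final_sets Named list of final candidate tibbles (per offspring).
#' @param truth A `trio_truth` object from [simulate_trio()], or a tibble of
#'   planted DNMs with `offspring`, `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `detectable`).
#' @return Tibble per offspring: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `recall_detectable`, plus per-class artifact leakage counts.
#' @export
score_against_truth <- function(final_sets, truth) {
  if (inherits(truth, "trio_truth")) {
    true_dnms <- truth$true_dnms
    artifacts <- truth$artifacts
  } else {
    true_dnms <- truth
    artifacts <- NULL
  }
  if (is.null(true_dnms)) abort("`truth` must carry planted DNMs.")
  purrr::imap(final_sets, function(x, off) {
    tdn <- true_dnms[true_dnms$offspring == off, , drop = FALSE]
    truth_keys <- variant_key(tdn$chrom, tdn$pos, tdn$ref, tdn$alt)
    det_keys <- if ("detectable" %in% names(tdn)) {
      truth_keys[tdn$detectable]
    } else truth_keys
    call_keys <- variant_key(x$chrom, x$pos, x$ref, x$alt)
    tp <- sum(call_keys %in% truth_keys)
    fp <- sum(!call_keys %in% truth_keys)
    leak <- if (!is.null(artifacts) && nrow(artifacts) > 0L) {
      art <- artifacts[artifacts$offspring == off, , drop = FALSE]
      akeys <- variant_key(art$chrom, art$pos, art$ref, art$alt)
      art |>
        mutate(leaked = akeys %in% call_keys) |>
        group_by(.data$class) |>
        summarise(n = sum(.data$leaked), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "class", values_from = "n",
                           names_prefix = "leaked_")
    } else tibble(.rows = 1)
    bind_cols(
      tibble(
        offspring = off, tp = tp, fp = fp,
        fn = sum(!truth_keys %in% call_keys),
        precision = ifelse(tp + fp == 0, NA_real_, tp / (tp + fp)),
        recall = ifelse(length(truth_keys) == 0, NA_real_,
                        tp / length(truth_keys)),
        recall_detectable = ifelse(length(det_keys) == 0, NA_real_,
                                   sum(det_keys %in% call_keys) /
                                     length(det_keys))),
      leak)
  }) |> bind_rows()
}
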