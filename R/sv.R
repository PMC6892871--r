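#' Structural-variant tables and filter configuration
#'
#' SVs are tibbles with columns `chrom`, `start`, `end` (0-based half-open),
#' `svtype` (DEL/INS/DUP/INV/TRA), `length` (end − start for intra-chromosomal
#' types; the stated insertion length for INS), `support` (supporting-read
#' count), `precise` (logical breakpoint precision), `filter` (caller label,
#' `"PASS"` when clean) and `sample`.
#'
#' @param min_support Short-read supporting-read floor (strict `>`).
#' @param min_len,max_len Length window in bp (inclusive). SVs above `max_len`
#'   fail with a distinct `length_gt_max_review` tag (the manual-review class).
#' @param require_pass,require_precise Require `filter == "PASS"` /
#'   `precise == TRUE`.
#' @param min_support_fraction Long-read floor: support must exceed this
#'   fraction of the whole-region read depth (strict `>`).
#' @param min_calling_reads Long-read minimum supporting reads (inclusive
#'   `>=`, "at least ten high-quality reads").
#' @param reciprocal_threshold Reciprocal-overlap fraction (strict `>`).
#' @param ins_breakpoint_bp Breakpoint-distance tolerance for matching INS
#'   records (which have no meaningful interval extent).
#' @return An `sv_filter_config` list.
#' @export
sv_filter_config <- function(min_support = 10, min_len = 50,
                             max_len = 2e6, require_pass = TRUE,
                             require_precise = TRUE,
                             min_support_fraction = 0.05,
                             min_calling_reads = 10,
                             reciprocal_threshold = 0.5,
                             ins_breakpoint_bp = 100) {
  stopifnot(reciprocal_threshold > 0, reciprocal_threshold <= 1,
            min_len <= max_len)
  structure(list(min_support = min_support, min_len = min_len,
                 max_len = max_len, require_pass = require_pass,
                 require_precise = require_precise,
                 min_support_fraction = min_support_fraction,
                 min_calling_reads = min_calling_reads,
                 reciprocal_threshold = reciprocal_threshold,
                 ins_breakpoint_bp = ins_breakpoint_bp),
            class = "sv_filter_config")
}

sv_cols <- c("chrom", "start", "end", "svtype", "length", "support",
             "precise", "filter", "sample")

#' Short-read SV hard filter
#'
#' Pass iff caller filter is PASS, breakpoints are precise, supporting reads
#' exceed the floor (strict), and length is within the window. Over-length
#' SVs are auto-failed with the `length_gt_max_review` tag rather than being
#' routed to manual inspection.
#'
#' @param svs An SV tibble.
#' @param cfg An [sv_filter_config()].
#' @return `svs` with `pass_sv` and `sv_reasons` columns added.
#' @export
filter_sv_shortread <- function(svs, cfg = sv_filter_config()) {
  stop_if_not_tbl(svs, setdiff(sv_cols, "sample"), "svs")
  reasons <- purrr::pmap_chr(
    svs[, c("filter", "precise", "support", "length")],
    function(filter, precise, support, length) {
      r <- character()
      if (cfg$require_pass && filter != "PASS") r <- c(r, "not_PASS")
      if (cfg$require_precise && !precise) r <- c(r, "imprecise")
      if (!(support > cfg$min_support)) r <- c(r, "low_support")
      if (length < cfg$min_len) r <- c(r, "too_short")
      if (length > cfg$max_len) r <- c(r, "length_gt_max_review")
      paste(r, collapse = ",")
    })
  svs |> mutate(pass_sv = reasons == "", sv_reasons = reasons)
}

#' Long-read SV hard filter
#'
#' Pass iff caller filter is PASS, breakpoints are precise, support is at
#' least the minimum calling reads, and support strictly exceeds
#' `min_support_fraction` of the whole-region read depth.
#'
#' @param svs An SV tibble.
#' @param region_depth Whole-region read depth (> 0).
#' @param cfg An [sv_filter_config()].
#' @return `svs` with `pass_sv` and `sv_reasons` columns added.
#' @export
filter_sv_longread <- function(svs, region_depth, cfg = sv_filter_config()) {
  stop_if_not_tbl(svs, setdiff(sv_cols, "sample"), "svs")
  if (!is.numeric(region_depth) || region_depth <= 0) {
    abort("`region_depth` must be positive.")
  }
  reasons <- purrr::pmap_chr(
    svs[, c("filter", "precise", "support")],
    function(filter, precise, support) {
      r <- character()
      if (cfg$require_pass && filter != "PASS") r <- c(r, "not_PASS")
      if (cfg$require_precise && !precise) r <- c(r, "imprecise")
      if (support < cfg$min_calling_reads) r <- c(r, "below_min_reads")
      if (!(support > cfg$min_support_fraction * region_depth)) {
        r <- c(r, "low_support_fraction")
      }
      paste(r, collapse = ",")
    })
  svs |> mutate(pass_sv = reasons == "", sv_reasons = reasons)
}

# Overlap fraction pair for two interval SVs: (ov/len_a, ov/len_b).
sv_overlap_fraction <- function(a_start, a_end, b_start, b_end) {
  ov <- max(0, min(a_end, b_end) - max(a_start, b_start))
  c(ov / max(1, a_end - a_start), ov / max(1, b_end - b_start))
}

#' Reciprocal overlap between two SV records
#'
#' Two intervals match when the overlap length strictly exceeds `threshold`
#' times the length of *each* interval. Records on different chromosomes or
#' of different types never match. INS records (no interval extent) match via
#' a breakpoint-distance rule: start positions within `ins_breakpoint_bp` and
#' stated-length ratio strictly above the threshold.
#'
#' @param a,b Single-row SV tibbles (or lists with the SV fields).
#' @param threshold Reciprocal fraction (strict `>`, default 0.5).
#' @param cfg An [sv_filter_config()] (for the INS rule).
#' @return Logical.
#' @export
sv_reciprocal_overlap <- function(a, b, threshold = 0.5,
                                  cfg = sv_filter_config()) {
  if (a$chrom != b$chrom || a$svtype != b$svtype) return(FALSE)
  if (a$svtype == "INS") {
    ratio <- min(a$length, b$length) / max(a$length, b$length)
    return(abs(a$start - b$start) <= cfg$ins_breakpoint_bp &&
             ratio > threshold)
  }
  fr <- sv_overlap_fraction(a$start, a$end, b$start, b$end)
  fr[1] > threshold && fr[2] > threshold
}

# All qualifying (i, j, weight) pairs between two SV tables; weight is the
# smaller of the two overlap fractions (INS: length ratio, gated on distance).
sv_overlap_pairs <- function(setA, setB, threshold, cfg) {
  pairs <- list()
  for (i in seq_len(nrow(setA))) {
    a <- setA[i, ]
    cand <- which(setB$chrom == a$chrom & setB$svtype == a$svtype)
    for (j in cand) {
      b <- setB[j, ]
      if (a$svtype == "INS") {
        if (abs(a$start - b$start) > cfg$ins_breakpoint_bp) next
        w <- min(a$length, b$length) / max(a$length, b$length)
      } else {
        fr <- sv_overlap_fraction(a$start, a$end, b$start, b$end)
        w <- min(fr)
      }
      if (w > threshold) {
        pairs[[length(pairs) + 1L]] <- tibble(i = i, j = j, w = w)
      }
    }
  }
  bind_rows(pairs)
}

#' Consensus SVs between two callers by reciprocal overlap
#'
#' An SV from `setA` is kept iff some `setB` SV of the same chromosome and
#' type reciprocally overlaps it; chained overlaps are resolved greedily by
#' best overlap fraction (each record matched at most once). Coordinates are
#' reported from `setA`.
#'
#' @param setA,setB SV tibbles.
#' @param threshold Reciprocal-overlap fraction (strict `>`).
#' @param cfg An [sv_filter_config()].
#' @return The consensus subset of `setA`.
#' @export
intersect_sv_callers <- function(setA, setB, threshold = 0.5,
                                 cfg = sv_filter_config()) {
  stop_if_not_tbl(setA, c("chrom", "start", "end", "svtype", "length"), "setA")
  stop_if_not_tbl(setB, c("chrom", "start", "end", "svtype", "length"), "setB")
  if (nrow(setA) == 0L || nrow(setB) == 0L) return(setA[0, , drop = FALSE])
  pairs <- sv_overlap_pairs(setA, setB, threshold, cfg)
  if (nrow(pairs) == 0L) return(setA[0, , drop = FALSE])
  pairs <- pairs |> arrange(dplyr::desc(.data$w))
  used_a <- logical(nrow(setA)); used_b <- logical(nrow(setB))
  keep <- integer()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    keep <- c(keep, i)
  }
  setA[sort(keep), , drop = FALSE]
}

#' De novo SV filtering against parents, known databases and siblings
#'
#' Removes any offspring SV reciprocally overlapping a parental SV
#' (inherited), a known-database SV, or a sibling SV (cross filtering);
#' the remainder is the de novo set. A `removed_by` summary is attached as an
#' attribute for the review table.
#'
#' @param offspring Offspring SV tibble.
#' @param parent_sets List of parental SV tibbles.
#' @param known_db Known-SV tibble (or NULL).
#' @param sibling_sets List of sibling SV tibbles (or empty).
#' @param threshold Reciprocal-overlap fraction.
#' @param cfg An [sv_filter_config()].
#' @return The de novo subset of `offspring`.
#' @export
de_novo_sv_filter <- function(offspring, parent_sets, known_db = NULL,
                              sibling_sets = list(), threshold = 0.5,
                              cfg = sv_filter_config()) {
  stop_if_not_tbl(offspring, c("chrom", "start", "end", "svtype", "length"),
                  "offspring")
  if (is.data.frame(parent_sets)) parent_sets <- list(parent_sets)
  if (is.data.frame(sibling_sets)) sibling_sets <- list(sibling_sets)
  removed_by <- rep(NA_character_, nrow(offspring))
  mark <- function(other, tag) {
    if (is.null(other) || nrow(other) == 0L || nrow(offspring) == 0L) return()
    pairs <- sv_overlap_pairs(offspring, other, threshold, cfg)
    if (nrow(pairs) > 0L) {
      idx <- unique(pairs$i)
      removed_by[idx][is.na(removed_by[idx])] <<- tag
    }
  }
  for (p in parent_sets) mark(p, "parent_inherit")
  mark(known_db, "known_db")
  for (s in sibling_sets) mark(s, "sibling_shared")
  out <- offspring[is.na(removed_by), , drop = FALSE]
  attr(out, "removed") <- offspring[!is.na(removed_by), , drop = FALSE] |>
    mutate(removed_by = removed_by[!is.na(removed_by)])
  out
}
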