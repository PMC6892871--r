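#' Hard-filter thresholds for site and genotype filtering
#'
#' All comparisons are strict, matching the usual `QD > 2.0`-style notation:
#' a value exactly at a threshold fails. The allele-bias rule fires only when
#' both the allele balance is at or below `ab_min` *and* the exact two-sided
#' binomial test against 0.5 is significant; the strand-bias rule uses
#' Fisher's exact test on the ref/alt by fwd/rev table. INDEL depth bounds
#' default to the SNV bounds but are separate keys.
#'
#' @param qd_min,mq_min Site-level quality-by-depth and mapping-quality floors.
#' @param ab_min,ab_pval Allele-balance floor and binomial p-value cutoff.
#' @param ab_inclusive Fire the allele-bias rule when AB equals `ab_min`
#'   (default `FALSE`: a variant sitting exactly at the minimum calling
#'   allele frequency is not struck, which keeps the filter cascade
#'   consistent with the binomial detection-power model).
#' @param strand_pval Fisher strand-bias p-value cutoff.
#' @param dp_min,dp_max,gq_min Genotype-level depth bounds and GQ floor (SNVs).
#' @param indel_dp_min,indel_dp_max Depth bounds for INDEL genotypes.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(qd_min = 2.0, mq_min = 30, ab_min = 0.10,
                              ab_pval = 0.05, ab_inclusive = FALSE,
                              strand_pval = 0.05,
                              dp_min = 15, dp_max = 100, gq_min = 30,
                              indel_dp_min = dp_min, indel_dp_max = dp_max) {
  stopifnot(ab_min >= 0, ab_min <= 0.5, dp_min < dp_max,
            indel_dp_min < indel_dp_max)
  structure(
    list(qd_min = qd_min, mq_min = mq_min, ab_min = ab_min, ab_pval = ab_pval,
         ab_inclusive = ab_inclusive, strand_pval = strand_pval,
         dp_min = dp_min, dp_max = dp_max,
         gq_min = gq_min, indel_dp_min = indel_dp_min,
         indel_dp_max = indel_dp_max),
    class = "filter_thresholds")
}

#' Site-level hard filter (SF)
#'
#' Evaluates one verdict per distinct (chrom, pos, ref, alt) site: QD, MQ,
#' allele bias and strand bias. Allele balance is computed from the summed
#' allelic depths of the samples whose genotype carries the alt allele.
#' A missing annotation yields an `unevaluable` tag, not a failure.
#'
#' @param variants A [variant_table] tibble.
#' @param thresholds A [filter_thresholds()] object.
#' @return Per-site tibble: `chrom`, `pos`, `ref`, `alt`, `pass_sf`,
#'   `sf_reasons`, `sf_unevaluable` (comma-joined tags).
#' @export
site_filter <- function(variants, thresholds = filter_thresholds()) {
  stop_if_not_tbl(variants, vcf_call_cols, "variants")
  t <- thresholds
  variants |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    group_modify(function(d, key) {
      reasons <- character()
      uneval <- character()
      qd <- d$qd[1]; mq <- d$mq[1]
      if (is.na(qd)) uneval <- c(uneval, "QD")
      else if (!(qd > t$qd_min)) reasons <- c(reasons, "QD")
      if (is.na(mq)) uneval <- c(uneval, "MQ")
      else if (!(mq > t$mq_min)) reasons <- c(reasons, "MQ")

      carriers <- d[!is.na(d$a1) & (d$a1 == key$alt | d$a2 == key$alt), ]
      if (nrow(carriers) == 0L || all(is.na(carriers$ad_alt))) {
        uneval <- c(uneval, "AB")
      } else {
        k <- sum(carriers$ad_alt, na.rm = TRUE)
        n <- k + sum(carriers$ad_ref, na.rm = TRUE)
        if (n == 0L) {
          uneval <- c(uneval, "AB")
        } else {
          ab <- k / n
          ab_low <- if (isTRUE(t$ab_inclusive)) ab <= t$ab_min else
            ab < t$ab_min
          if (ab_low && binom_p_half(k, n) < t$ab_pval) {
            reasons <- c(reasons, "AB")
          }
        }
      }

      sb <- c(d$sr_fwd[1], d$sr_rev[1], d$sa_fwd[1], d$sa_rev[1])
      if (anyNA(sb)) {
        uneval <- c(uneval, "SB")
      } else if (sum(sb) > 0L) {
        p <- fisher.test(matrix(sb, nrow = 2, byrow = TRUE))$p.value
        if (p < t$strand_pval) reasons <- c(reasons, "SB")
      }
      tibble(pass_sf = length(reasons) == 0L,
             sf_reasons = paste(reasons, collapse = ","),
             sf_unevaluable = paste(uneval, collapse = ","))
    }) |>
    ungroup()
}

#' Genotype-level hard filter (GF)
#'
#' One verdict per (site, sample) row: pass iff `dp_min < DP < dp_max` and
#' `GQ > gq_min` (all strict). Missing DP or GQ makes the call unevaluable.
#' INDEL rows use the INDEL depth bounds.
#'
#' @inheritParams site_filter
#' @return `variants` with `pass_gf`, `gf_reasons`, `gf_unevaluable` added.
#' @export
genotype_filter <- function(variants, thresholds = filter_thresholds()) {
  stop_if_not_tbl(variants, vcf_call_cols, "variants")
  t <- thresholds
  is_indel <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L
  lo <- ifelse(is_indel, t$indel_dp_min, t$dp_min)
  hi <- ifelse(is_indel, t$indel_dp_max, t$dp_max)
  dp_bad <- !is.na(variants$dp) & !(variants$dp > lo & variants$dp < hi)
  gq_bad <- !is.na(variants$gq) & !(variants$gq > t$gq_min)
  reasons <- purrr::map2_chr(dp_bad, gq_bad, function(a, b)
    paste(c(if (a) "DP", if (b) "GQ"), collapse = ","))
  uneval <- purrr::map2_chr(is.na(variants$dp), is.na(variants$gq),
                            function(a, b)
    paste(c(if (a) "DP", if (b) "GQ"), collapse = ","))
  variants |>
    mutate(pass_gf = !dp_bad & !gq_bad & !is.na(.data$dp) & !is.na(.data$gq),
           gf_reasons = reasons, gf_unevaluable = uneval)
}

#' Union-merge mask components into the universal mask (UM)
#'
#' @param components A list of mask tibbles (or a single bound tibble):
#'   mappability, low-complexity and repeat regions.
#' @return A merged mask tibble labelled `"merged"`.
#' @export
build_universal_mask <- function(components) {
  if (is.data.frame(components)) components <- list(components)
  merged <- merge_intervals(bind_rows(lapply(components, function(x)
    x[, c("chrom", "start", "end")])))
  merged |> mutate(component = "merged")
}

#' Remove variants whose REF span intersects the universal mask
#'
#' The REF span of a record is `[pos - 1, pos - 1 + nchar(ref))` in 0-based
#' half-open coordinates.
#'
#' @param variants A [variant_table] tibble.
#' @param mask A mask tibble (`chrom`, `start`, `end`).
#' @return The unmasked subset of `variants`.
#' @export
apply_universal_mask <- function(variants, mask) {
  stop_if_not_tbl(variants, c("chrom", "pos", "ref"), "variants")
  stop_if_not_tbl(mask, c("chrom", "start", "end"), "mask")
  if (nrow(variants) == 0L || nrow(mask) == 0L) return(variants)
  keep <- rep(TRUE, nrow(variants))
  for (cm in unique(variants$chrom)) {
    m <- mask[mask$chrom == cm, ]
    idx <- which(variants$chrom == cm)
    if (nrow(m) == 0L || length(idx) == 0L) next
    v_start <- variants$pos[idx] - 1L
    v_end <- v_start + nchar(variants$ref[idx])
    q <- IRanges::IRanges(start = v_start + 1L, end = v_end)
    s <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    hit <- IRanges::overlapsAny(q, s)
    keep[idx[hit]] <- FALSE
  }
  variants[keep, , drop = FALSE]
}

#' Left-align and trim indel representations against the reference
#'
#' Applies the standard variant-normalisation algorithm: shared trailing
#' bases are trimmed (extending left through the reference when an allele
#' would empty), then shared leading bases are trimmed. SNVs pass through
#' unchanged. Genotype allele strings are remapped to the normalised
#' representation. Normalisation is idempotent.
#'
#' @param variants A [variant_table] tibble.
#' @param reference Named character vector of sequences.
#' @return `variants` with normalised `pos`, `ref`, `alt` (and `a1`, `a2`).
#' @export
normalize_variants <- function(variants, reference) {
  stop_if_not_tbl(variants, c("chrom", "pos", "ref", "alt"), "variants")
  if (nrow(variants) == 0L) return(variants)
  keys <- variants |> distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  norm <- purrr::pmap(keys, function(chrom, pos, ref, alt) {
    seqstr <- reference[[chrom]]
    if (is.null(seqstr)) abort(sprintf("chromosome %s not in reference", chrom))
    obs <- substr(seqstr, pos, pos + nchar(ref) - 1L)
    if (!identical(toupper(obs), ref)) {
      abort(sprintf("REF mismatch at %s:%d: record %s, reference %s",
                    chrom, pos, ref, obs))
    }
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      return(list(pos = pos, ref = ref, alt = alt))
    }
    r <- ref; a <- alt; p <- pos
    repeat {
      if (nchar(r) > 0L && nchar(a) > 0L &&
          substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
        r <- substr(r, 1L, nchar(r) - 1L)
        a <- substr(a, 1L, nchar(a) - 1L)
        if (nchar(r) == 0L || nchar(a) == 0L) {
          if (p == 1L) abort(sprintf(
            "cannot left-extend allele at %s:%d past the sequence start",
            chrom, pos))
          p <- p - 1L
          b <- toupper(substr(seqstr, p, p))
          r <- paste0(b, r)
          a <- paste0(b, a)
        }
      } else break
    }
    while (nchar(r) >= 2L && nchar(a) >= 2L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    list(pos = p, ref = r, alt = a)
  })
  keys$new_pos <- purrr::map_int(norm, function(x) as.integer(x$pos))
  keys$new_ref <- purrr::map_chr(norm, "ref")
  keys$new_alt <- purrr::map_chr(norm, "alt")
  out <- variants |>
    left_join(keys, by = c("chrom", "pos", "ref", "alt"))
  if ("a1" %in% names(out)) {
    out <- out |>
      mutate(
        a1 = dplyr::case_when(.data$a1 == .data$ref ~ .data$new_ref,
                              .data$a1 == .data$alt ~ .data$new_alt,
                              TRUE ~ .data$a1),
        a2 = dplyr::case_when(.data$a2 == .data$ref ~ .data$new_ref,
                              .data$a2 == .data$alt ~ .data$new_alt,
                              TRUE ~ .data$a2))
  }
  out |>
    mutate(pos = .data$new_pos, ref = .data$new_ref, alt = .data$new_alt) |>
    select(-"new_pos", -"new_ref", -"new_alt")
}

#' Intersect variant sets across callers
#'
#' Keeps a variant iff a record with the same (chrom, pos, ref, alt) key is
#' present in every caller's set; annotations are reported from the first
#' (primary) caller. Inputs should be normalised first (see
#' [normalize_variants()]) so equivalent indel representations match.
#'
#' @param caller_sets A list (>= 2) of [variant_table] tibbles.
#' @return The consensus subset of the primary caller's table.
#' @export
intersect_callers <- function(caller_sets) {
  if (!is.list(caller_sets) || length(caller_sets) < 2L) {
    abort("`caller_sets` must be a list of at least two variant tables.")
  }
  key_sets <- lapply(caller_sets, function(x) {
    stop_if_not_tbl(x, c("chrom", "pos", "ref", "alt"), "caller set")
    unique(variant_key(x$chrom, x$pos, x$ref, x$alt))
  })
  shared <- Reduce(intersect, key_sets)
  primary <- caller_sets[[1]]
  primary[variant_key(primary$chrom, primary$pos, primary$ref,
                      primary$alt) %in% shared, , drop = FALSE]
}

#' Apply SF, GF and UM to one caller's trio call set
#'
#' A site survives iff it passes the site filter, every sample's genotype at
#' the site passes the genotype filter (a trio DNM call needs all three
#' genotypes), and its REF span is outside the universal mask. Sites with
#' unevaluable-only annotations are kept (missing is not failing) unless
#' `drop_unevaluable = TRUE`.
#'
#' @param variants A [variant_table] tibble (one caller, all trio samples).
#' @param thresholds A [filter_thresholds()] object.
#' @param mask Optional universal-mask tibble.
#' @param drop_unevaluable Drop sites with missing SF/GF annotations.
#' @return The filtered variant table, with an attribute `"funnel"` giving
#'   per-stage site counts.
#' @export
apply_hard_filters <- function(variants, thresholds = filter_thresholds(),
                               mask = NULL, drop_unevaluable = FALSE) {
  n_sites <- function(v) nrow(distinct(v, .data$chrom, .data$pos, .data$ref,
                                       .data$alt))
  funnel <- c(input = n_sites(variants))

  sf <- site_filter(variants, thresholds)
  keep_sf <- sf$pass_sf
  if (drop_unevaluable) keep_sf <- keep_sf & sf$sf_unevaluable == ""
  ok <- sf[keep_sf, c("chrom", "pos", "ref", "alt")]
  v <- variants |> semi_join(ok, by = c("chrom", "pos", "ref", "alt"))
  funnel <- c(funnel, SF = n_sites(v))

  gf <- genotype_filter(v, thresholds)
  bad_rows <- !gf$pass_gf
  if (!drop_unevaluable) bad_rows <- bad_rows & gf$gf_reasons != ""
  bad_sites <- gf[bad_rows, c("chrom", "pos", "ref", "alt")] |> distinct()
  v <- v |> anti_join(bad_sites, by = c("chrom", "pos", "ref", "alt"))
  funnel <- c(funnel, GF = n_sites(v))

  if (!is.null(mask)) v <- apply_universal_mask(v, mask)
  funnel <- c(funnel, UM = n_sites(v))

  attr(v, "funnel") <- funnel
  v
}
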