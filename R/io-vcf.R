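#' Tidy variant-call tables
#'
#' The package represents variant calls as a plain tibble with one row per
#' (biallelic site, sample) pair, so that the whole pipeline composes with
#' dplyr verbs. Columns:
#'
#' * `chrom`, `pos` — sequence name and 1-based position of the first REF base
#'   (the VCF convention; interval operations convert at the boundary).
#' * `ref`, `alt` — the REF allele and a single ALT allele. Multi-allelic
#'   records are split into one row per ALT on read, with AD collapsed to
#'   (ref, that alt).
#' * `qual`, `qd`, `mq` — site quality, quality-by-depth and mapping quality
#'   (`NA` when the caller did not emit them; missing is distinct from
#'   failing).
#' * `sr_fwd`, `sr_rev`, `sa_fwd`, `sa_rev` — site-level strand counts for
#'   ref/alt reads on forward/reverse strands.
#' * `sample` — sample identifier.
#' * `a1`, `a2` — the two called alleles as bases (not indices), `NA` when the
#'   genotype is missing. Storing bases keeps allele identity intact across
#'   the multi-allelic split, which the Mendelian logic relies on.
#' * `dp`, `gq`, `ad_ref`, `ad_alt` — per-genotype depth, genotype quality and
#'   per-allele read depths.
#'
#' @name variant_table
NULL

vcf_call_cols <- c(
  "chrom", "pos", "ref", "alt", "qual", "qd", "mq",
  "sr_fwd", "sr_rev", "sa_fwd", "sa_rev",
  "sample", "a1", "a2", "dp", "gq", "ad_ref", "ad_alt"
)

empty_variant_table <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), qual = double(), qd = double(), mq = double(),
    sr_fwd = integer(), sr_rev = integer(), sa_fwd = integer(),
    sa_rev = integer(), sample = character(), a1 = character(),
    a2 = character(), dp = integer(), gq = integer(),
    ad_ref = integer(), ad_alt = integer()
  )
}

parse_info_field <- function(info) {
  if (info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1L) kv[2] else TRUE
  }
  out
}

num_or_na <- function(x) {
  if (is.null(x) || identical(x, ".")) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

int_or_na <- function(x) {
  if (is.null(x) || identical(x, ".") || is.na(x)) return(NA_integer_)
  suppressWarnings(as.integer(x))
}

#' Read a minimal multi-sample VCF into a tidy variant table
#'
#' Parses the subset of VCF 4.2 the audit pipeline touches: INFO keys `QD`,
#' `MQ` and `SB` (four comma-separated ref-fwd/ref-rev/alt-fwd/alt-rev strand
#' counts) and FORMAT keys `GT`, `DP`, `GQ`, `AD`. Unknown FORMAT keys are
#' ignored with a warning; missing annotations become `NA`, never zero.
#' Multi-allelic records are split into one row per ALT allele, with genotype
#' alleles kept as bases so no allele identity is lost.
#'
#' @param path Path to a VCF file.
#' @param dialect Caller-name tag; reserved for caller-specific INFO field
#'   mappings. Currently all supported callers share the `"generic"` mapping.
#' @return A [variant_table] tibble with one row per (site, ALT, sample).
#' @export
read_vcf <- function(path, dialect = "generic") {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  lines <- readLines(path)
  hdr_idx <- grep("^#CHROM", lines)
  if (length(hdr_idx) != 1L) {
    abort(sprintf("%s: header line '#CHROM ...' missing or duplicated", path))
  }
  hdr <- strsplit(lines[hdr_idx], "\\s+")[[1]]
  samples <- if (length(hdr) > 9L) hdr[10:length(hdr)] else character()
  body_idx <- which(seq_along(lines) > hdr_idx & !startsWith(lines, "#") &
                      nzchar(trimws(lines)))
  if (length(body_idx) == 0L) return(empty_variant_table())

  warned_keys <- character()
  rows <- vector("list", length(body_idx))
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    f <- strsplit(lines[i], "\\s+")[[1]]
    if (length(f) < 8L) {
      abort(sprintf("%s: malformed VCF line %d (fewer than 8 fields)", path, i))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) {
      abort(sprintf("%s: malformed VCF line %d (bad POS '%s')", path, i, f[2]))
    }
    ref <- toupper(f[4])
    alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    qual <- num_or_na(f[6])
    info <- parse_info_field(f[8])
    sb <- if (!is.null(info$SB)) {
      suppressWarnings(as.integer(strsplit(info$SB, ",", fixed = TRUE)[[1]]))
    } else rep(NA_integer_, 4L)
    if (length(sb) != 4L) sb <- rep(NA_integer_, 4L)

    fmt_keys <- if (length(f) >= 9L) strsplit(f[9], ":", fixed = TRUE)[[1]] else character()
    known <- c("GT", "DP", "GQ", "AD")
    unknown <- setdiff(fmt_keys, known)
    if (length(unknown) > 0L) {
      new_unknown <- setdiff(unknown, warned_keys)
      if (length(new_unknown) > 0L) {
        warn(sprintf("%s: ignoring unknown FORMAT key(s): %s", path,
                     paste(new_unknown, collapse = ", ")))
        warned_keys <- c(warned_keys, new_unknown)
      }
    }
    alleles <- c(ref, alts)

    site_rows <- vector("list", length(samples))
    for (s in seq_along(samples)) {
      sf <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]]
      val <- function(key) {
        k <- match(key, fmt_keys)
        if (is.na(k) || k > length(sf)) NULL else sf[k]
      }
      gt <- val("GT")
      a <- c(NA_character_, NA_character_)
      if (!is.null(gt) && !gt %in% c(".", "./.", ".|.")) {
        idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
        if (length(idx) == 2L && !anyNA(idx)) {
          if (any(idx < 0L | idx >= length(alleles))) {
            abort(sprintf("%s: line %d sample %s: GT index out of range",
                          path, i, samples[s]))
          }
          a <- alleles[idx + 1L]
        }
      }
      ad_raw <- val("AD")
      ad <- if (is.null(ad_raw) || ad_raw == ".") NULL else
        suppressWarnings(as.integer(strsplit(ad_raw, ",", fixed = TRUE)[[1]]))
      site_rows[[s]] <- tibble(
        sample = samples[s], a1 = a[1], a2 = a[2],
        dp = int_or_na(val("DP")), gq = int_or_na(val("GQ")),
        ad = list(ad)
      )
    }
    calls <- bind_rows(site_rows)

    # split multi-allelic: one biallelic row per ALT, AD collapsed
    per_alt <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      per_alt[[k]] <- calls |>
        mutate(
          chrom = f[1], pos = pos, ref = ref, alt = alts[k],
          qual = qual, qd = num_or_na(info$QD), mq = num_or_na(info$MQ),
          sr_fwd = sb[1], sr_rev = sb[2], sa_fwd = sb[3], sa_rev = sb[4],
          ad_ref = purrr::map_int(.data$ad, function(v)
            if (is.null(v)) NA_integer_ else v[1]),
          ad_alt = purrr::map_int(.data$ad, function(v)
            if (is.null(v) || length(v) < k + 1L) NA_integer_ else v[k + 1L])
        ) |>
        select(dplyr::all_of(vcf_call_cols))
    }
    rows[[j]] <- bind_rows(per_alt)
  }
  bind_rows(rows)
}

#' Write a tidy variant table as a minimal multi-sample VCF
#'
#' Inverse of [read_vcf()] on the modeled fields: biallelic rows sharing
#' (chrom, pos, ref) are re-joined into one (possibly multi-allelic) VCF line,
#' genotype bases are re-encoded as allele indices, and missing values are
#' emitted as `"."`.
#'
#' @param calls A [variant_table] tibble.
#' @param path Output path.
#' @param samples Sample column order; defaults to order of first appearance.
#'   Rows referencing undeclared samples are an error.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, samples = NULL) {
  stop_if_not_tbl(calls, setdiff(vcf_call_cols, c("qd")), "calls")
  samples <- samples %||% unique(calls$sample)
  if (nrow(calls) > 0L && !all(calls$sample %in% samples)) {
    abort("`calls` references samples not in `samples`.")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=SB,Number=4,Type=Integer,Description=\"Strand counts: ref-fwd,ref-rev,alt-fwd,alt-rev\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (nrow(calls) == 0L) return(invisible(path))

  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  sites <- calls |>
    group_by(.data$chrom, .data$pos, .data$ref) |>
    group_split()
  # preserve input order of first appearance
  first_seen <- vapply(sites, function(s)
    min(which(calls$chrom == s$chrom[1] & calls$pos == s$pos[1] &
                calls$ref == s$ref[1])), integer(1))
  sites <- sites[order(first_seen)]

  for (site in sites) {
    alts <- unique(site$alt)
    alleles <- c(site$ref[1], alts)
    info <- character()
    if (!is.na(site$qd[1])) info <- c(info, sprintf("QD=%s", format(site$qd[1])))
    if (!is.na(site$mq[1])) info <- c(info, sprintf("MQ=%s", format(site$mq[1])))
    if (!is.na(site$sr_fwd[1])) {
      info <- c(info, sprintf("SB=%d,%d,%d,%d", site$sr_fwd[1], site$sr_rev[1],
                              site$sa_fwd[1], site$sa_rev[1]))
    }
    info_str <- if (length(info) == 0L) "." else paste(info, collapse = ";")

    cells <- vapply(samples, function(sm) {
      rows_s <- site[site$sample == sm, , drop = FALSE]
      if (nrow(rows_s) == 0L) return("./.:.:.:.")
      r1 <- rows_s[1, ]
      gt <- if (is.na(r1$a1) || is.na(r1$a2)) "./." else {
        i1 <- match(r1$a1, alleles) - 1L
        i2 <- match(r1$a2, alleles) - 1L
        if (is.na(i1) || is.na(i2)) {
          abort(sprintf("sample %s at %s:%d carries an allele not among REF/ALT",
                        sm, r1$chrom, r1$pos))
        }
        paste(i1, i2, sep = "/")
      }
      ad <- if (all(is.na(rows_s$ad_ref))) "." else {
        alt_depths <- vapply(alts, function(a) {
          v <- rows_s$ad_alt[rows_s$alt == a]
          if (length(v) == 0L || is.na(v[1])) 0L else as.integer(v[1])
        }, integer(1))
        paste(c(rows_s$ad_ref[!is.na(rows_s$ad_ref)][1], alt_depths),
              collapse = ",")
      }
      paste(gt, dot(r1$dp), dot(r1$gq), ad, sep = ":")
    }, character(1))

    writeLines(paste(c(site$chrom[1], site$pos[1], ".", site$ref[1],
                       paste(alts, collapse = ","), dot(site$qual[1]), ".",
                       info_str, "GT:DP:GQ:AD", cells), collapse = "\t"), con)
  }
  invisible(path)
}
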