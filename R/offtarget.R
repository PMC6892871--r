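#' Construct a protospacer (guide) object
#'
#' Accepts either a bare 20-nt protospacer or a 23-nt guide-plus-PAM string
#' (the trailing 3-mer is dropped; the PAM is a property of the genomic site,
#' not of the guide).
#'
#' @param seq 20- or 23-nt uppercase DNA string.
#' @param pam_rules Allowed PAM patterns 3' of the protospacer; `N` matches
#'   any base. Canonical SpCas9 accepts NGG and tolerates NAG.
#' @param name Optional guide name.
#' @return A `protospacer` object (list with `seq`, `pam_rules`, `name`).
#' @export
protospacer <- function(seq, pam_rules = c("NGG", "NAG"), name = "sgRNA") {
  seq <- toupper(seq)
  if (nchar(seq) == 23L) seq <- substr(seq, 1L, 20L)
  if (nchar(seq) != 20L) {
    abort("`seq` must be a 20-nt protospacer (or 23-nt protospacer+PAM).")
  }
  if (grepl("[^ACGT]", seq)) abort("`seq` must contain only A/C/G/T.")
  pam_rules <- toupper(pam_rules)
  if (any(nchar(pam_rules) != 3L) || any(grepl("[^ACGTN]", pam_rules))) {
    abort("PAM patterns must be 3-mers over A/C/G/T/N.")
  }
  structure(list(seq = seq, pam_rules = pam_rules, name = name),
            class = "protospacer")
}

#' @export
print.protospacer <- function(x, ...) {
  cat(sprintf("protospacer %s: %s (PAM: %s)\n", x$name, x$seq,
              paste(x$pam_rules, collapse = "/")))
  invisible(x)
}

# does `triplet` match any PAM pattern (N = wildcard)?
pam_matches <- function(triplet, patterns) {
  if (nchar(triplet) != 3L || grepl("[^ACGT]", triplet)) return(FALSE)
  for (p in patterns) {
    ok <- TRUE
    for (i in 1:3) {
      pc <- substr(p, i, i)
      if (pc != "N" && pc != substr(triplet, i, i)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Enumerate candidate off-target sites of a guide across a genome
#'
#' Reports every 20-mer, on either strand, whose immediately 3'-adjacent
#' 3-mer matches an allowed PAM and whose ungapped Hamming distance to the
#' protospacer is at most `max_mismatches`. Windows containing ambiguous
#' bases (non-ACGT) are skipped.
#'
#' Coordinates follow the convention: `start` is the 0-based genomic position
#' of the protospacer's 5' base on its own strand; `fp_start`/`fp_end` give
#' the 23-bp protospacer+PAM footprint as a genomic half-open interval.
#'
#' @param reference Named character vector of sequences (see [read_fasta()]).
#' @param ps A [protospacer()] (or a character guide, coerced).
#' @param max_mismatches Maximum Hamming distance (0-20).
#' @param pam_rules Optional override of `ps$pam_rules`.
#' @return Tibble with columns `chrom`, `start`, `strand`, `mismatches`,
#'   `pam`, `is_on_target`, `fp_start`, `fp_end`.
#' @export
scan_offtargets <- function(reference, ps, max_mismatches = 5,
                            pam_rules = NULL) {
  if (is.character(ps)) ps <- protospacer(ps)
  stopifnot(inherits(ps, "protospacer"))
  if (!is_count(max_mismatches) || max_mismatches > 20) {
    abort("`max_mismatches` must be an integer in [0, 20].")
  }
  pam_rules <- toupper(pam_rules %||% ps$pam_rules)
  if (!is.character(reference) || is.null(names(reference)) ||
      length(reference) == 0L) {
    abort("`reference` must be a named character vector of sequences.")
  }

  scan_strand <- function(seqstr, chrom, strand, L) {
    subj <- Biostrings::DNAString(seqstr)
    hits <- Biostrings::matchPattern(ps$seq, subj,
                                     max.mismatch = max_mismatches,
                                     fixed = FALSE)
    out <- list()
    for (s in Biostrings::start(hits)) { # 1-based start of 20-mer
      if (s + 22L > L) next              # no room for the PAM
      window <- substr(seqstr, s, s + 22L)
      if (grepl("[^ACGT]", window)) next # ambiguous bases: skip window
      pam <- substr(window, 21L, 23L)
      if (!pam_matches(pam, pam_rules)) next
      mm <- hamming(substr(window, 1L, 20L), ps$seq)
      if (mm > max_mismatches) next
      if (strand == "+") {
        a <- s - 1L                      # genomic 0-based footprint start
        start <- a
      } else {
        a <- L - (s - 1L) - 23L          # footprint leftmost on the genome
        start <- a + 22L                 # protospacer 5' end on minus strand
      }
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = start, strand = strand, mismatches = mm,
        pam = pam, is_on_target = mm == 0L, fp_start = a, fp_end = a + 23L)
    }
    if (length(out) == 0L) return(empty_offtarget_sites())
    bind_rows(out)
  }

  res <- purrr::imap(reference, function(seqstr, chrom) {
    seqstr <- toupper(seqstr)
    L <- nchar(seqstr)
    if (L < 23L) return(empty_offtarget_sites())
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqstr)))
    bind_rows(scan_strand(seqstr, chrom, "+", L),
              scan_strand(rc, chrom, "-", L))
  })
  bind_rows(res) |>
    distinct(.data$chrom, .data$start, .data$strand, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$fp_start, .data$strand)
}

empty_offtarget_sites <- function() {
  tibble(chrom = character(), start = integer(), strand = character(),
         mismatches = integer(), pam = character(), is_on_target = logical(),
         fp_start = integer(), fp_end = integer())
}

#' Cas9 cut-site position of an off-target site
#'
#' SpCas9 cuts bluntly between protospacer positions 17 and 18, 3 bp 5' of
#' the PAM. Returns the 0-based genomic boundary coordinate, strand-aware.
#'
#' @param sites Tibble from [scan_offtargets()] (needs `fp_start`, `strand`).
#' @return Integer vector of cut boundaries (one per site).
#' @export
cut_site_of <- function(sites) {
  stop_if_not_tbl(sites, c("fp_start", "strand"), "sites")
  ifelse(sites$strand == "+", sites$fp_start + 17L, sites$fp_start + 6L)
}

#' Flag DNMs near predicted off-target sites
#'
#' A DNM is flagged when its position falls within `window_bp` of the 23-bp
#' protospacer+PAM footprint of any predicted site, i.e. inside
#' `[fp_start - window_bp, fp_end + window_bp)`.
#'
#' @param dnms Tibble with `chrom` and 1-based `pos` columns.
#' @param sites Off-target sites from [scan_offtargets()].
#' @param window_bp Flanking distance in bp (default 40).
#' @return `dnms` with logical `near_offtarget` and integer
#'   `n_offtargets_near` columns added.
#' @export
annotate_dnm_proximity <- function(dnms, sites, window_bp = 40) {
  stop_if_not_tbl(dnms, c("chrom", "pos"), "dnms")
  stop_if_not_tbl(sites, c("chrom", "fp_start", "fp_end"), "sites")
  p0 <- dnms$pos - 1L # 0-based
  n_near <- integer(nrow(dnms))
  if (nrow(sites) > 0L) {
    for (i in seq_len(nrow(dnms))) {
      n_near[i] <- sum(sites$chrom == dnms$chrom[i] &
                         p0[i] >= sites$fp_start - window_bp &
                         p0[i] < sites$fp_end + window_bp)
    }
  }
  dnms |> mutate(n_offtargets_near = n_near, near_offtarget = n_near > 0L)
}

#' Read-level on-target (mosaic editing) ratio at a cut site
#'
#' Among reads whose alignment overlaps a small window around the cut site,
#' the fraction carrying at least one deletion that intersects the window.
#'
#' @param reads Tibble with columns `read_id`, `aln_start`, `aln_end`
#'   (0-based half-open) and a list-column `dels` of per-read deletion tables
#'   (`start`, `end`, 0-based half-open; possibly zero rows).
#' @param cut_site 0-based cut boundary (see [cut_site_of()]).
#' @param near_window_bp Half-width of the window around the cut site
#'   (default 5 bp; "near the PAM" is not a sharply defined distance).
#' @return Fraction of overlapping reads with a deletion in the window.
#' @export
on_target_ratio <- function(reads, cut_site, near_window_bp = 5) {
  stop_if_not_tbl(reads, c("read_id", "aln_start", "aln_end", "dels"), "reads")
  win_start <- cut_site - near_window_bp
  win_end <- cut_site + near_window_bp
  overlapping <- reads$aln_start < win_end & reads$aln_end > win_start
  if (!any(overlapping)) {
    abort("no reads overlap the cut-site window")
  }
  has_del <- purrr::map_lgl(reads$dels[overlapping], function(d) {
    if (is.null(d) || nrow(d) == 0L) return(FALSE)
    any(d$start < win_end & d$end > win_start)
  })
  mean(has_del)
}
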