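#' Read a three-column BED file as a merged mask table
#'
#' Masks are tibbles of half-open, 0-based `[start, end)` intervals with
#' columns `chrom`, `start`, `end` and a `component` label. Intervals are
#' merged per chromosome on read, so downstream code can assume sorted,
#' disjoint intervals.
#'
#' @param path Path to a 3-column BED file (0-based half-open).
#' @param component Label attached to the intervals (e.g. `"mappability"`,
#'   `"low-complexity"`, `"repeat"`).
#' @return A mask tibble with columns `chrom`, `start`, `end`, `component`.
#' @export
read_bed <- function(path, component = "merged") {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  component = character()))
  }
  f <- strsplit(lines, "\\s+")
  bad <- which(vapply(f, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("%s: BED line %d has fewer than 3 columns", path, bad[1]))
  }
  x <- tibble(
    chrom = vapply(f, `[`, character(1), 1L),
    start = as.integer(vapply(f, `[`, character(1), 2L)),
    end = as.integer(vapply(f, `[`, character(1), 3L))
  )
  if (any(is.na(x$start) | is.na(x$end))) {
    abort(sprintf("%s: non-integer BED coordinates", path))
  }
  if (any(x$start >= x$end)) {
    i <- which(x$start >= x$end)[1]
    abort(sprintf("%s: BED line %d has start >= end (%d >= %d)", path, i,
                  x$start[i], x$end[i]))
  }
  merge_intervals(x) |> mutate(component = component)
}

#' Write a mask table as a three-column BED file
#'
#' @param mask A mask tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mask, path) {
  stop_if_not_tbl(mask, c("chrom", "start", "end"), "mask")
  readr::write_tsv(mask[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Merge overlapping or touching intervals per chromosome
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Sorted tibble of disjoint intervals per chromosome.
#' @export
merge_intervals <- function(intervals) {
  stop_if_not_tbl(intervals, c("chrom", "start", "end"), "intervals")
  if (nrow(intervals) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  intervals |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
      tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; names are taken up to the first whitespace.
#' Duplicate names are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(sprintf("%s: duplicate sequence names: %s", path,
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  setNames(toupper(as.character(set)), nm)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
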