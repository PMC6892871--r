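# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# All-positions Hamming scan for protospacer+PAM sites. Vectorised over
# positions: O(20 * L) character comparisons per strand.
oracle_scan <- function(reference, ps_seq, max_mm, pams = c("NGG", "NAG")) {
  pam_ok <- function(tri) {
    ok <- !grepl("[^ACGT]", tri)
    hit <- rep(FALSE, length(tri))
    for (p in pams) {
      m <- rep(TRUE, length(tri))
      for (i in 1:3) {
        pc <- substr(p, i, i)
        if (pc != "N") m <- m & substr(tri, i, i) == pc
      }
      hit <- hit | m
    }
    ok & hit
  }
  ps <- strsplit(ps_seq, "")[[1]]
  revcomp <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  one_strand <- function(seqstr, chrom, strand, L) {
    n_win <- L - 22L
    if (n_win < 1L) return(NULL)
    chars <- strsplit(seqstr, "")[[1]]
    mm <- integer(n_win)
    ambig <- rep(FALSE, n_win)
    for (i in 1:20) {
      w <- chars[i:(i + n_win - 1L)]
      mm <- mm + (w != ps[i])
      ambig <- ambig | !w %in% c("A", "C", "G", "T")
    }
    tri <- substring(seqstr, 21:(20L + n_win), 23:(22L + n_win))
    ambig <- ambig | grepl("[^ACGT]", tri)
    sel <- which(!ambig & mm <= max_mm & pam_ok(tri))
    if (length(sel) == 0L) return(NULL)
    if (strand == "+") {
      data.frame(chrom = chrom, start = sel - 1L, strand = "+",
                 mismatches = mm[sel], pam = tri[sel],
                 fp_start = sel - 1L, fp_end = sel + 22L)
    } else {
      a <- L - (sel - 1L) - 23L
      data.frame(chrom = chrom, start = a + 22L, strand = "-",
                 mismatches = mm[sel], pam = tri[sel],
                 fp_start = a, fp_end = a + 23L)
    }
  }
  out <- list()
  for (chrom in names(reference)) {
    seqstr <- toupper(reference[[chrom]])
    L <- nchar(seqstr)
    out[[length(out) + 1L]] <- one_strand(seqstr, chrom, "+", L)
    out[[length(out) + 1L]] <- one_strand(revcomp(seqstr), chrom, "-", L)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      pam = character(), fp_start = integer(),
                      fp_end = integer()))
  }
  out[order(out$chrom, out$fp_start, out$strand), , drop = FALSE]
}

# O(n^2) interval merge
oracle_merge <- function(df) {
  out <- list()
  for (cm in sort(unique(df$chrom))) {
    iv <- df[df$chrom == cm, c("start", "end")]
    iv <- iv[order(iv$start), , drop = FALSE]
    merged <- list()
    for (i in seq_len(nrow(iv))) {
      s <- iv$start[i]; e <- iv$end[i]
      placed <- FALSE
      for (j in seq_along(merged)) {
        if (s <= merged[[j]][2] && e >= merged[[j]][1]) {
          merged[[j]] <- c(min(s, merged[[j]][1]), max(e, merged[[j]][2]))
          placed <- TRUE
          break
        }
      }
      if (!placed) merged[[length(merged) + 1L]] <- c(s, e)
    }
    # repeat passes until stable (merging can cascade)
    repeat {
      changed <- FALSE
      for (a in seq_along(merged)) {
        for (b in seq_along(merged)) {
          if (a >= b || is.null(merged[[a]]) || is.null(merged[[b]])) next
          if (merged[[a]][1] <= merged[[b]][2] &&
              merged[[b]][1] <= merged[[a]][2]) {
            merged[[a]] <- c(min(merged[[a]][1], merged[[b]][1]),
                             max(merged[[a]][2], merged[[b]][2]))
            merged[[b]] <- NULL
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    merged <- Filter(Negate(is.null), merged)
    for (m in merged) {
      out[[length(out) + 1L]] <- data.frame(chrom = cm, start = m[1],
                                            end = m[2])
    }
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# O(n * m) record-vs-mask intersection
oracle_masked <- function(variants, mask) {
  hit <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v_start <- variants$pos[i] - 1L
    v_end <- v_start + nchar(variants$ref[i])
    for (j in seq_len(nrow(mask))) {
      if (variants$chrom[i] == mask$chrom[j] &&
          v_start < mask$end[j] && v_end > mask$start[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# exhaustive maximum-weight matching between two SV sets, weights = min
# reciprocal-overlap fraction, pairs admissible when weight > threshold
oracle_sv_matching <- function(setA, setB, threshold) {
  wt <- matrix(0, nrow(setA), nrow(setB))
  for (i in seq_len(nrow(setA))) {
    for (j in seq_len(nrow(setB))) {
      if (setA$chrom[i] != setB$chrom[j] ||
          setA$svtype[i] != setB$svtype[j]) next
      ov <- max(0, min(setA$end[i], setB$end[j]) -
                  max(setA$start[i], setB$start[j]))
      w <- min(ov / (setA$end[i] - setA$start[i]),
               ov / (setB$end[j] - setB$start[j]))
      if (w > threshold) wt[i, j] <- w
    }
  }
  best <- list(weight = -1, rows = integer())
  recurse <- function(i, used_b, rows, weight) {
    if (i > nrow(setA)) {
      if (weight > best$weight ||
          (weight == best$weight && length(rows) > length(best$rows))) {
        best <<- list(weight = weight, rows = rows)
      }
      return()
    }
    recurse(i + 1L, used_b, rows, weight) # leave i unmatched
    for (j in seq_len(nrow(setB))) {
      if (!used_b[j] && wt[i, j] > 0) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, c(rows, i), weight + wt[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nrow(setB)), integer(), 0)
  sort(best$rows)
}

# direct-summation Pearson r and two-sided t-test p
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# left-aligned minimal representation of an indel by exhaustive search over
# equivalent edits of the haplotype
oracle_normalize <- function(seqstr, pos, ref, alt) {
  apply_var <- function(p, r, a) {
    paste0(substr(seqstr, 1, p - 1), a,
           substr(seqstr, p + nchar(r), nchar(seqstr)))
  }
  target <- apply_var(pos, ref, alt)
  best <- NULL
  for (p in seq_len(nchar(seqstr))) {
    for (rl in 1:6) {
      if (p + rl - 1L > nchar(seqstr)) next
      r <- substr(seqstr, p, p + rl - 1L)
      for (al in 1:6) {
        # candidate alts: substrings of the target at the same prefix offset
        a <- substr(target, p, p + al - 1L)
        if (nchar(a) != al) next
        if (rl > 1L && al > 1L) next      # not parsimonious unless trimmed
        if (r == a) next
        if (apply_var(p, r, a) == target) {
          cand <- list(pos = p, ref = r, alt = a)
          if (is.null(best) || p < best$pos ||
              (p == best$pos && rl + al < nchar(best$ref) + nchar(best$alt))) {
            best <- cand
          }
        }
      }
    }
  }
  best
}
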