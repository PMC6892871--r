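#' @import dplyr
#' @import tibble
#' @importFrom rlang .data abort warn %||%
#' @importFrom stats pbinom fisher.test cor.test rbinom runif rpois setNames
#' @importFrom utils head
NULL

# Canonical variant key used for caller intersection, dbSNP lookup and
# sibling cross filtering. Allele-specific by design.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Deterministic sub-seed for a named simulation purpose, so that adding one
# simulation feature does not perturb the random draws of the others.
# Polynomial string hash folded into [0, 2^31 - 2].
purpose_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- seed %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run `expr` under a purpose-local RNG stream, restoring the caller's RNG.
with_purpose_seed <- function(seed, label, expr) {
  withr::with_seed(purpose_seed(seed, label), expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

stop_if_not_tbl <- function(x, cols, what) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing columns: %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(x)
}

# Two-sided exact binomial p-value against p = 0.5 (symmetric case), vectorised.
binom_p_half <- function(k, n) {
  p <- 2 * pbinom(pmin(k, n - k), n, 0.5)
  # when n even and k == n/2 the two tails share the midpoint
  pmin(p, 1)
}
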