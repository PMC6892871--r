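#' Minimum mutant-read count implied by a calling allele-frequency floor
#'
#' A variant caller requiring a minimum allele frequency `min_af` at sequencing
#' depth `n` implicitly requires at least `ceiling(min_af * n)` mutant reads.
#'
#' @param n Sequencing depth (reads covering the site).
#' @param min_af Minimum allele frequency required to call a variant
#'   (default 0.10).
#' @return Integer minimum mutant-read count.
#' @export
#' @examples
#' min_supporting_reads(40, 0.10) # 4
min_supporting_reads <- function(n, min_af = 0.10) {
  if (!is_count(n) || n <= 0) abort("`n` must be a positive integer depth.")
  if (!is.numeric(min_af) || min_af < 0 || min_af > 1) {
    abort("`min_af` must be in [0, 1].")
  }
  as.integer(ceiling(min_af * n))
}

#' Binomial power model for detecting a mosaic de novo mutation
#'
#' A mutation arising at the single-cell stage of the zygote is expected in
#' half of the reads (allele fraction 0.5, heterozygous); a mutation at the
#' two-cell stage in a quarter (0.25). With `n` reads covering the site and a
#' caller that needs at least `m = ceiling(min_af * n)` mutant reads, the
#' mutant read count is Binomial(n, p) and the mutation is missed when fewer
#' than `m` mutant reads are drawn.
#'
#' @param depth Sequencing depth `n`.
#' @param allele_fraction Expected mutant-allele fraction `p`, or use `stage`.
#' @param stage `"single-cell"` (p = 0.5) or `"two-cell"` (p = 0.25);
#'   ignored when `allele_fraction` is given.
#' @param min_af Minimum calling allele frequency (default 0.10).
#' @return An object of class `dnm_power_model` with fields `depth`, `p`,
#'   `min_af`, `min_reads`, `miss_probability`, `power`.
#' @export
#' @examples
#' power_model(depth = 40, stage = "two-cell")
power_model <- function(depth, allele_fraction = NULL,
                        stage = c("two-cell", "single-cell"),
                        min_af = 0.10) {
  p <- allele_fraction %||% stage_fraction(match.arg(stage))
  if (!is.numeric(p) || p <= 0 || p > 0.5) {
    abort("`allele_fraction` must be in (0, 0.5].")
  }
  m <- min_supporting_reads(depth, min_af)
  miss <- miss_probability(depth, p, m)
  structure(
    list(depth = as.integer(depth), p = p, min_af = min_af, min_reads = m,
         miss_probability = miss, power = 1 - miss),
    class = "dnm_power_model"
  )
}

#' Map a zygotic stage to its expected mutant-allele fraction
#'
#' Assumes a heterozygous mutation and unbiased read sampling: a mutation
#' before the first cleavage is carried by all cells (fraction 0.5); one in a
#' single blastomere of the two-cell embryo by half of them (0.25).
#'
#' @param stage `"single-cell"` or `"two-cell"`.
#' @return Allele fraction.
#' @export
stage_fraction <- function(stage = c("two-cell", "single-cell")) {
  switch(match.arg(stage), "single-cell" = 0.5, "two-cell" = 0.25)
}

#' Probability of missing a mosaic mutation
#'
#' Exact binomial tail: `P(X <= m - 1)` for `X ~ Binomial(n, p)`.
#'
#' @param n Sequencing depth.
#' @param p Mutant-allele fraction.
#' @param m Minimum mutant reads required to call.
#' @return Miss probability in \[0, 1\].
#' @export
#' @examples
#' miss_probability(40, 0.25, 4) # ~0.005
miss_probability <- function(n, p, m) {
  if (!is_count(n) || n <= 0) abort("`n` must be a positive integer depth.")
  if (!is_count(m)) abort("`m` must be a non-negative integer.")
  if (!is.numeric(p) || p < 0 || p > 1) abort("`p` must be in [0, 1].")
  if (m == 0L) return(0)
  pbinom(m - 1, size = n, prob = p)
}

#' Power to detect a mosaic mutation
#'
#' Complement of [miss_probability()]. `detection_power(model)` accepts a
#' fitted [power_model()]; the default method takes the raw parameters.
#'
#' @param n Depth, or a `dnm_power_model`.
#' @param p Mutant-allele fraction (ignored for a model object).
#' @param m Minimum mutant reads (ignored for a model object).
#' @return Detection probability.
#' @export
detection_power <- function(n, p = NULL, m = NULL) {
  if (inherits(n, "dnm_power_model")) return(n$power)
  1 - miss_probability(n, p, m)
}

#' @export
print.dnm_power_model <- function(x, ...) {
  cat(sprintf(
    "Mosaic DNM detection power\n  depth: %d, allele fraction: %.3g, min AF: %.3g (>= %d mutant reads)\n  miss probability: %.4g\n  power: %.4f (%.1f%%)\n",
    x$depth, x$p, x$min_af, x$min_reads, x$miss_probability, x$power,
    100 * x$power))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy dnm_power_model
#' @export
tidy.dnm_power_model <- function(x, ...) {
  tibble(
    stage = c("single-cell", "two-cell"),
    allele_fraction = c(0.5, 0.25),
    depth = x$depth,
    min_reads = x$min_reads,
    miss_probability = c(miss_probability(x$depth, 0.5, x$min_reads),
                         miss_probability(x$depth, 0.25, x$min_reads)),
    power = 1 - .data$miss_probability
  )
}

#' @method glance dnm_power_model
#' @export
glance.dnm_power_model <- function(x, ...) {
  tibble(depth = x$depth, allele_fraction = x$p, min_af = x$min_af,
         min_reads = x$min_reads, miss_probability = x$miss_probability,
         power = x$power)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Power curve across sequencing depth for both zygotic stages
#'
#' @param object A `dnm_power_model`.
#' @param depths Depth grid for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dnm_power_model
#' @export
autoplot.dnm_power_model <- function(object, depths = 10:100, ...) {
  grid <- tidyr::expand_grid(depth = depths,
                             stage = c("single-cell", "two-cell")) |>
    mutate(
      p = ifelse(.data$stage == "single-cell", 0.5, 0.25),
      power = purrr::map2_dbl(.data$depth, .data$p, function(n, p)
        detection_power(n, p, min_supporting_reads(n, object$min_af)))
    )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$depth, y = .data$power,
                                     colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$depth, linetype = 2) +
    ggplot2::labs(x = "sequencing depth", y = "detection power",
                  colour = "zygotic stage") +
    ggplot2::theme_minimal()
}

#' Expected spontaneous de novo mutation count per generation
#'
#' Multiplies a per-nucleotide per-generation mutation-rate range by the
#' number of callable diploid sites.
#'
#' @param mu_low,mu_high Per-nucleotide per-generation mutation rates.
#' @param callable_sites Diploid nucleotide count over which DNMs can be
#'   called (default two haploid genomes of 2.9 Gb).
#' @return Tibble with columns `mu`, `expected_dnms` (low and high rows).
#' @export
expected_dnm_count <- function(mu_low, mu_high = mu_low,
                               callable_sites = 2 * 2.9e9) {
  if (!is.numeric(mu_low) || !is.numeric(mu_high) || mu_low <= 0 ||
      mu_high < mu_low) {
    abort("need 0 < mu_low <= mu_high")
  }
  if (!is.numeric(callable_sites) || callable_sites <= 0) {
    abort("`callable_sites` must be positive.")
  }
  tibble(bound = c("low", "high"), mu = c(mu_low, mu_high),
         callable_sites = callable_sites,
         expected_dnms = c(mu_low, mu_high) * callable_sites)
}

#' Pearson correlation between editing efficiency and DNM count
#'
#' Tests whether per-animal on-target editing ratios predict the number of
#' high-confidence DNMs (they should not, if editing does not induce DNMs).
#'
#' @param data Tibble with one row per animal.
#' @param efficiency,dnms Column names (tidy-eval) of the on-target ratio and
#'   the DNM count.
#' @return Tibble with `estimate` (Pearson r), `p.value` (two-sided t test),
#'   `n`.
#' @export
dnm_efficiency_correlation <- function(data, efficiency = "on_target_ratio",
                                       dnms = "dnm_count") {
  stop_if_not_tbl(data, c(efficiency, dnms), "data")
  x <- data[[efficiency]]
  y <- data[[dnms]]
  if (length(x) < 3L) abort("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("degenerate input: zero variance in a coordinate")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
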