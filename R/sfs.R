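#' Site-frequency-spectrum mixture moments and solver
#'
#' The generator draws alternate-allele population frequencies from a
#' two-component mixture: with probability `1 - w` a neutral spectrum with
#' density proportional to `1/q` truncated below at `q_min`, and with
#' probability `w` a "reference-minor" component with `q` uniform on
#' `ref_minor_q_range` (sites whose less common allele sits in the
#' reference, which therefore appear homozygous-alternate in essentially
#' every genome). Under Hardy-Weinberg genotypes the expected per-genome
#' homozygote/heterozygote count ratio is
#' `E[q^2] / E[2 q (1 - q)]` over the mixture; `solve_sfs_mixture()`
#' inverts this for `w` so that the emitted cohort hits a target ratio.
#'
#' @param target_hom_het_ratio desired expected hom_alt/het ratio, in (0, 2).
#' @param q_min lower truncation of the neutral spectrum.
#' @param ref_minor_q_range frequency range of the reference-minor
#'   component.
#' @return `solve_sfs_mixture()`: list with `w` (mixture weight), the
#'   `achieved` ratio and the `feasible` ratio range. Solved to
#'   `|achieved - target| < 1e-6` (well inside the 1e-4 contract); targets
#'   outside the feasible range by more than 1e-4 are an error, and targets
#'   within 1e-4 of a boundary are clamped to it.
#' @export
solve_sfs_mixture <- function(target_hom_het_ratio, q_min = 0.01,
                              ref_minor_q_range = c(0.9, 1)) {
  stopifnot(target_hom_het_ratio > 0)
  m <- sfs_mixture_moments(q_min, ref_minor_q_range)
  ratio_at <- function(w) {
    ((1 - w) * m$hom_neutral + w * m$hom_refminor) /
      ((1 - w) * m$het_neutral + w * m$het_refminor)
  }
  lo <- ratio_at(0)
  hi <- ratio_at(1)
  t <- target_hom_het_ratio
  if (t < lo - 1e-4 || t > hi + 1e-4) {
    stop(sprintf(
      "target hom/het ratio %.4f unattainable; feasible range is [%.4f, %.4f]",
      t, lo, hi
    ))
  }
  if (t <= lo) {
    w <- 0
  } else if (t >= hi) {
    w <- 1
  } else {
    w <- stats::uniroot(
      function(w) ratio_at(w) - t,
      interval = c(0, 1), tol = 1e-10
    )$root
  }
  list(w = w, achieved = ratio_at(w), feasible = c(lo, hi))
}

#' @rdname solve_sfs_mixture
#' @return `sfs_mixture_moments()`: per-component expectations of the
#'   per-genome homozygote (`E[q^2]`) and heterozygote (`E[2q(1-q)]`)
#'   probabilities.
#' @export
sfs_mixture_moments <- function(q_min = 0.01, ref_minor_q_range = c(0.9, 1)) {
  stopifnot(q_min > 0, q_min < 1)
  L <- log(1 / q_min)
  hom_neutral <- (1 - q_min^2) / (2 * L)
  het_neutral <- (2 * (1 - q_min) - (1 - q_min^2)) / L
  a <- ref_minor_q_range[1]
  b <- ref_minor_q_range[2]
  stopifnot(a < b)
  e_q <- (a + b) / 2
  e_q2 <- (b^3 - a^3) / (3 * (b - a))
  list(
    hom_neutral = hom_neutral, het_neutral = het_neutral,
    hom_refminor = e_q2, het_refminor = 2 * (e_q - e_q2)
  )
}

#' Draw site frequencies from the mixture
#'
#' Uses the current RNG state. Neutral draws use the inverse CDF of the
#' truncated `1/q` density, `q = q_min^(1-u)`.
#'
#' @param n number of sites.
#' @param w reference-minor mixture weight.
#' @inheritParams solve_sfs_mixture
#' @return list with `q` (frequencies) and `ref_minor` (logical component
#'   indicator).
#' @export
draw_site_freqs <- function(n, w, q_min = 0.01, ref_minor_q_range = c(0.9, 1)) {
  ref_minor <- stats::runif(n) < w
  q <- q_min^(1 - stats::runif(n))
  n_rm <- sum(ref_minor)
  if (n_rm) {
    q[ref_minor] <- stats::runif(n_rm, ref_minor_q_range[1], ref_minor_q_range[2])
  }
  list(q = q, ref_minor = ref_minor)
}
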