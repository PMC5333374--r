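# Validation statistics: localization error against a gold standard,
# inter-rater reliability, and the paired sign-flip permutation test.

#' Assemble rater localizations
#'
#' @param coords K x R x 3 array: K contacts localized by R raters
#'   (world mm), no missing entries.
#' @param method `"manual"` or `"semi_automatic"` tag.
#' @return An object of class `iel_raters`.
#' @export
rater_localizations <- function(coords, method = c("manual", "semi_automatic")) {
  method <- match.arg(method)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("coords must be a K x R x 3 array")
  }
  if (anyNA(coords)) abort("missing rater coordinates")
  structure(list(coords = coords, method = method), class = "iel_raters")
}

#' Gold-standard contact locations
#'
#' The per-contact componentwise mean of the rater localizations,
#' `G_k = (1/R) sum_r L_{k,r}`.
#'
#' @param rl an [rater_localizations()] object (R >= 2).
#' @return K x 3 matrix.
#' @export
gold_standard <- function(rl) {
  stopifnot(inherits(rl, "iel_raters"))
  if (dim(rl$coords)[2] < 2L) abort("need at least 2 raters for a gold standard")
  apply(rl$coords, c(1, 3), mean)
}

#' Per-contact Euclidean localization errors
#'
#' `e_k = |est_k - ref_k|` in mm.
#'
#' @param est,ref K x 3 coordinate matrices.
#' @return Numeric vector of K distances.
#' @export
localization_errors <- function(est, ref) {
  est <- to_mat3(est); ref <- to_mat3(ref)
  if (nrow(est) != nrow(ref)) abort("coordinate sets must have equal K")
  sqrt(rowSums((est - ref)^2))
}

#' @rdname localization_errors
#' @param e numeric vector of errors (mm).
#' @export
summarize_errors <- function(e) {
  tibble(mean = mean(e), sd = sd(e), median = median(e), max = max(e),
         n = length(e))
}

#' Krippendorff's alpha for interval data
#'
#' `alpha = 1 - D_o / D_e` with the squared-difference metric:
#' observed disagreement averages squared differences over all rater pairs
#' within each unit (each pair weighted by `1/(m_u - 1)`), expected
#' disagreement over all pairs of values in the pooled data. 3D coordinates
#' enter as one unit per contact *component* (x, y and z of each contact are
#' separate units), matching a scalar reliability coefficient.
#'
#' @param ratings units x raters numeric matrix (complete data, >= 2 raters,
#'   >= 2 units).
#' @return Scalar alpha; 1 when all values are identical (zero expected
#'   disagreement).
#' @export
krippendorff_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  U <- nrow(ratings); m <- ncol(ratings)
  if (m < 2L || U < 2L) abort("need >= 2 raters and >= 2 units")
  if (anyNA(ratings)) abort("complete data required")
  n <- U * m
  # observed: within-unit squared differences, ordered pairs / (m - 1)
  unit_ss <- rowSums(ratings^2)
  unit_sum <- rowSums(ratings)
  within <- 2 * (m * unit_ss - unit_sum^2)   # sum over ordered pairs
  Do <- sum(within / (m - 1)) / n
  # expected: all ordered pairs in the pooled values
  allv <- as.vector(ratings)
  De <- 2 * (n * sum(allv^2) - sum(allv)^2) / (n * (n - 1))
  if (De <= 0) return(1)
  1 - Do / De
}

#' Build an alpha ratings matrix from rater coordinates
#'
#' Each contact contributes three units (its x, y, z components); columns are
#' raters.
#'
#' @param rl an [rater_localizations()] object or K x R x 3 array.
#' @return (3K) x R matrix.
#' @export
coordinate_ratings <- function(rl) {
  coords <- if (inherits(rl, "iel_raters")) rl$coords else rl
  K <- dim(coords)[1]; R <- dim(coords)[2]
  out <- matrix(NA_real_, 3L * K, R)
  for (ax in 1:3) out[seq_len(K) + (ax - 1L) * K, ] <- coords[, , ax]
  out
}

#' Paired sign-flip permutation test
#'
#' Paired t statistic on the differences `a - b`; the null distribution is
#' built by randomly flipping the signs of the paired differences. The
#' two-sided p-value is the proportion of permuted `|t| >= |t_obs|`, with the
#' observed permutation included so that `p >= 1/(n_perm + 1)`.
#'
#' @param a,b paired numeric vectors of equal length n >= 2.
#' @param n_perm number of sign-flip permutations (default 100,000).
#' @param seed RNG seed.
#' @return A list of class `iel_permtest`: `statistic` (observed t),
#'   `p.value`, `n`, `n_perm`.
#' @export
paired_permutation_test <- function(a, b, n_perm = 1e5, seed = 1L) {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  n <- length(a)
  if (n < 2L) abort("need n >= 2 pairs")
  d <- a - b
  if (sd(d) == 0 && mean(d) == 0) {
    return(structure(list(statistic = 0, p.value = 1, n = n, n_perm = n_perm),
                     class = "iel_permtest"))
  }
  # constant nonzero differences: |t| is infinite; only all-equal sign
  # patterns tie with it under flipping
  tstat <- function(x, s) {
    # x: matrix n_rep x n of signed differences
    m <- rowMeans(x)
    v <- (rowSums(x^2) - length(s) * m^2) / (length(s) - 1)
    m / sqrt(v / length(s))
  }
  t_obs <- if (sd(d) == 0) Inf else mean(d) / (sd(d) / sqrt(n))
  n_perm <- as.integer(n_perm)
  count <- 0L
  with_seed(seed, {
    chunk <- 10000L
    done <- 0L
    while (done < n_perm) {
      nr <- min(chunk, n_perm - done)
      signs <- matrix(sample(c(-1, 1), nr * n, replace = TRUE), nr, n)
      X <- sweep(signs, 2, d, "*")
      tp <- tstat(X, d)
      tp[!is.finite(tp)] <- Inf        # zero variance under flip: maximal |t|
      count <- count + sum(abs(tp) >= abs(t_obs) - 1e-12)
      done <- done + nr
    }
  })
  p <- (count + 1) / (n_perm + 1)
  structure(list(statistic = t_obs, p.value = min(p, 1), n = n,
                 n_perm = n_perm),
            class = "iel_permtest")
}

#' @export
print.iel_permtest <- function(x, ...) {
  cat(sprintf("Paired sign-flip permutation test: t = %.3f, p = %.3g (n = %d, %d permutations)\n",
              x$statistic, x$p.value, x$n, x$n_perm))
  invisible(x)
}
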