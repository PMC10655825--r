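#' Paired t test with Cohen's d
#'
#' For per-subject differences: `t = mean / (sd / sqrt(n))`, two-sided p
#' from the t distribution with n - 1 df, and the paired effect size
#' `d = mean / sd` (sd with the n - 1 denominator), so `t = d * sqrt(n)`.
#'
#' @param differences numeric vector of per-subject differences (n >= 2).
#' @param label descriptive label.
#' @return object of class `group_test`: list with label, n, mean, sd, t,
#'   p, d.
#' @export
paired_t_d <- function(differences, label = "") {
  x <- as.numeric(differences)
  n <- length(x)
  if (n < 2) stop("need at least 2 differences")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate variance: differences are constant")
  m <- mean(x)
  tval <- m / (s / sqrt(n))
  structure(list(label = label, n = n, mean = m, sd = s, t = tval,
                 p = 2 * stats::pt(-abs(tval), df = n - 1), d = m / s),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("group_test%s: n=%d mean=%.4g t=%.4f p=%.4g d=%.4f\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n, x$mean, x$t, x$p, x$d))
  invisible(x)
}

#' Unit-wise paired t map
#'
#' Applies [paired_t_d()] at every unit of a subjects x units matrix of
#' per-subject deltas. Units with zero variance across subjects are masked
#' (NA).
#'
#' @param deltas numeric matrix, subjects x units.
#' @return list with `t`, `p` (uncorrected, two-sided), `mean` vectors and
#'   `masked` (logical, zero-variance units).
#' @export
unit_t_map <- function(deltas) {
  deltas <- as.matrix(deltas)
  n <- nrow(deltas)
  if (n < 2) stop("need at least 2 subjects")
  m <- unname(colMeans(deltas))
  s <- unname(sqrt(colSums(sweep(deltas, 2, m)^2) / (n - 1)))
  masked <- s == 0
  tval <- ifelse(masked, NA_real_, m / (s / sqrt(n)))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1),
       mean = m, n = n, masked = masked)
}

#' Sign-flipping permutation max-T family-wise correction
#'
#' Permutation null of the maximum |t| across units under random sign flips
#' of each subject's delta map (exchangeability of the paired difference
#' sign under the null). Corrected
#' `p(unit) = (1 + #\{perm max|t| >= |t_obs|\}) / (n_permutations + 1)`, so
#' the smallest attainable value is `1 / (n_permutations + 1)` and the
#' corrected p is never below the uncorrected p.
#'
#' @param deltas numeric matrix, subjects x units.
#' @param n_permutations number of random sign-flip draws (default 10000).
#' @param rng_seed integer seed making the draw deterministic.
#' @param alpha nominal family-wise level recorded in the output.
#' @return list with `p_corrected`, `t` (observed), `max_t_null`
#'   (permutation distribution), `alpha`, `significant` (logical at
#'   `alpha`).
#' @export
permutation_maxT <- function(deltas, n_permutations = 10000, rng_seed = 1,
                             alpha = 0.05) {
  deltas <- as.matrix(deltas)
  n <- nrow(deltas)
  if (n < 2) stop("need at least 2 subjects")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  obs <- unit_t_map(deltas)
  keep <- !obs$masked
  x <- deltas[, keep, drop = FALSE]
  ss <- colSums(x^2)                      # invariant under sign flips
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  M <- (signs %*% x) / n
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  Tm <- abs(M / sqrt(V / n))
  max_t <- apply(Tm, 1, max)
  p_corr <- rep(NA_real_, ncol(deltas))
  p_corr[keep] <- vapply(abs(obs$t[keep]), function(t0)
    (1 + sum(max_t >= t0 - 1e-12)) / (n_permutations + 1), numeric(1))
  list(p_corrected = p_corr, t = obs$t, max_t_null = max_t,
       alpha = alpha, significant = !is.na(p_corr) & p_corr <= alpha)
}

#' Entry-wise comparison of paired FC matrices
#'
#' Paired t test on Fisher z values at every region pair of matched pre and
#' post matrices; outputs are symmetric with a masked diagonal, plus
#' network-block summaries of the mean delta z.
#'
#' @param pre,post lists of `fc_matrix` objects, matched by subject and
#'   with identical region ordering.
#' @return list with `delta_z` (mean post - pre matrix), `t`, `p`
#'   (uncorrected) matrices, `n`, and `blocks` (data.frame of
#'   network-pair mean delta z).
#' @export
matrix_comparison <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  pt <- attr(pre[[1]], "parcels")
  for (m in c(pre, post))
    if (!identical(rownames(m), rownames(pre[[1]])))
      stop("region ordering mismatch between matrices")
  d <- lapply(seq_along(pre), function(i) unclass(post[[i]]) - unclass(pre[[i]]))
  k <- nrow(d[[1]])
  arr <- simplify2array(d)                    # k x k x subjects
  flat <- matrix(arr, k * k, length(d))
  res <- unit_t_map(t(flat))
  shape <- function(v) {
    m <- matrix(v, k, k, dimnames = dimnames(pre[[1]]))
    m <- (m + t(m)) / 2
    diag(m) <- NA_real_
    m
  }
  delta <- structure(shape(res$mean), parcels = pt)
  tmat <- shape(res$t)
  pmat <- matrix(res$p, k, k, dimnames = dimnames(pre[[1]]))
  pmat <- pmin(pmat, t(pmat), na.rm = FALSE); diag(pmat) <- NA_real_
  nets <- unique(pt$network)
  blocks <- do.call(rbind, lapply(nets, function(a)
    do.call(rbind, lapply(nets, function(b)
      data.frame(network_a = a, network_b = b,
                 mean_delta_z = fc_block_mean(delta, a, b))))))
  list(delta_z = delta, t = tmat, p = pmat, n = length(pre), blocks = blocks)
}

#' Across-subject coupling between metabolic and FC changes
#'
#' Pearson correlation between per-subject metabolic deltas and FC deltas,
#' with `R^2 = r^2` and a two-sided p from the t transform with n - 2 df.
#'
#' @param x per-subject metabolic deltas.
#' @param y per-subject FC deltas.
#' @param x_label,y_label descriptive labels.
#' @return object of class `coupling_result`: list with labels, n, r,
#'   r_squared, p.
#' @export
coupling_correlation <- function(x, y, x_label = "delta metabolism",
                                 y_label = "delta FC") {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need matched vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in coupling inputs")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(x_label = x_label, y_label = y_label, n = n, r = r,
                 r_squared = r^2, p = p),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("coupling [%s ~ %s]: n=%d r=%.3f R^2=%.3f p=%.4g\n",
              x$x_label, x$y_label, x$n, x$r, x$r_squared, x$p))
  invisible(x)
}

#' Divergent-subgroup subanalysis
#'
#' Sorts subjects by their metabolic delta (ties broken by subject id) and
#' contrasts the bottom-k against the top-k on a companion FC delta,
#' mirroring the analysis of the five individuals diverging most in each
#' direction from the group trend.
#'
#' @param delta per-subject metabolic deltas.
#' @param fc_delta companion per-subject FC deltas.
#' @param k subgroup size (default 5); requires `n >= 2k`.
#' @param ids subject identifiers (default seq_along).
#' @return list with `bottom` and `top`, each holding `ids`, `delta_mean`,
#'   `fc_mean`.
#' @export
subgroup_divergence <- function(delta, fc_delta, k = 5,
                                ids = seq_along(delta)) {
  n <- length(delta)
  stopifnot(length(fc_delta) == n, length(ids) == n)
  if (n < 2 * k) stop("need at least 2k subjects")
  ord <- order(delta, ids)
  lo <- ord[seq_len(k)]; hi <- ord[seq.int(n - k + 1L, n)]
  grp <- function(ix) list(ids = ids[ix], delta_mean = mean(delta[ix]),
                           fc_mean = mean(fc_delta[ix]))
  list(bottom = grp(lo), top = grp(hi), k = k)
}
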