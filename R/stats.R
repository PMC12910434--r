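#' Two-sample permutation test on the difference of means
#'
#' The inferential test used for monolayer roughness: the statistic is the
#' difference of group means of per-image roughness SDs; the null is built
#' by label shuffling; the two-sided p-value uses the add-one rule
#' `p = (1 + #{|T*| >= |T|}) / (n_perm + 1)`, so it is never exactly 0.
#' Deterministic given `seed` (the global RNG state is restored).
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param n_perm number of label permutations (>= 999; default 10000).
#' @param seed integer seed for the permutation stream.
#' @return a `permutation_result`: list with `observed_diff`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 10000L, seed = 1L) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (n_perm < 999L) stop("n_perm must be at least 999")
  obs <- mean(group_a) - mean(group_b)
  pool <- c(group_a, group_b)
  na <- length(group_a)
  n <- length(pool)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  tstar <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1))
  p <- (1 + sum(abs(tstar) >= abs(obs))) / (n_perm + 1)
  structure(list(observed_diff = obs, p_value = p,
                 n_permutations = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: diff of means = %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$observed_diff, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Mann-Whitney U test pass-through
#'
#' Thin wrapper around the standard two-sided rank-sum test, recorded in
#' outputs alongside permutation results.
#'
#' @param a,b nonempty numeric vectors.
#' @return two-sided p-value.
#' @export
rank_test_passthrough <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input sample")
  suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
}
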