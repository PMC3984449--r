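# Voxel-based lesion-symptom mapping: a per-voxel linear model of the
# behavioral score on the binary lesion indicator (equivalent to a
# pooled-variance two-sample t between lesioned and spared groups), a 10/10
# coverage rule, and a family-wise threshold from the permutation null of the
# maximum statistic.

#' Coverage filter: voxels testable under the min-group rule
#'
#' A voxel is tested iff at least `min_group` subjects have a lesion there
#' AND at least `min_group` do not.
#' @param lesions subjects x voxels binary matrix (0/1)
#' @param min_group minimum group size (default 10)
#' @return logical vector over voxels
#' @export
vlsm_coverage_filter <- function(lesions, min_group = 10L) {
  lesions <- as.matrix(lesions)
  n1 <- colSums(lesions)
  n1 >= min_group & (nrow(lesions) - n1) >= min_group
}

# slope t of score ~ lesion at each voxel of `cols`; identical to the
# pooled-variance two-sample t (lesioned vs spared), df = n - 2.
# scores may be a matrix (one row per permutation) -> returns a matrix.
vlsm_t_stat <- function(scores, lesions, cols = seq_len(ncol(lesions))) {
  L <- lesions[, cols, drop = FALSE]
  S <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
  n <- ncol(S)
  stopifnot(nrow(L) == n)
  n1 <- colSums(L); n0 <- n - n1
  s1 <- S %*% L                       # perms x voxels: sum of lesioned scores
  stot <- rowSums(S)
  m1 <- sweep(s1, 2L, n1, "/")
  m0 <- sweep(-s1 + stot, 2L, n0, "/")
  ss1 <- (S^2) %*% L
  sstot <- rowSums(S^2)
  ssw <- (ss1 - sweep(m1^2, 2L, n1, "*")) +
         ((-ss1 + sstot) - sweep(m0^2, 2L, n0, "*"))
  sp2 <- ssw / (n - 2)
  se <- sqrt(sweep(sp2, 2L, 1 / n1 + 1 / n0, "*"))
  diffm <- m1 - m0
  t <- diffm / se
  t[diffm == 0] <- 0               # identical group means -> t = 0, even if sp = 0
  t[diffm != 0 & se == 0] <- NA    # zero within-group variance but real difference
  if (is.matrix(scores)) t else t[1L, ]
}

#' Per-voxel lesion-symptom t map
#'
#' Slope t statistic of the score on the binary lesion indicator at each
#' tested voxel; algebraically the pooled-variance two-sample t between
#' lesioned and spared subjects, df = n_subjects - 2. Voxels with zero
#' within-group variance but unequal means are flagged NA.
#' @param scores numeric vector, one behavioral score per subject
#' @param lesions subjects x voxels binary matrix
#' @param tested_mask logical vector from [vlsm_coverage_filter()]
#' @return numeric vector of t values over ALL voxels (untested = NA)
#' @export
vlsm_t_map <- function(scores, lesions, tested_mask) {
  stopifnot(length(scores) == nrow(lesions))
  if (!any(tested_mask)) stop("no voxels pass the coverage filter", call. = FALSE)
  t <- rep(NA_real_, ncol(lesions))
  t[tested_mask] <- vlsm_t_stat(scores, lesions, which(tested_mask))
  t
}

#' Voxel-based lesion-symptom mapping with max-statistic permutation test
#'
#' Fits the per-voxel linear model, then reassigns the behavioral scores
#' across subjects `n_perm` times (lesions fixed), recording the maximum
#' statistic over tested voxels for each permutation. The critical threshold
#' is the empirical (1 - alpha) quantile of that null; voxels with observed
#' t above it are significant. One-tailed (largest t) by default; the
#' two-tailed variant uses max |t|.
#'
#' @param scores numeric vector of behavioral scores (higher = more severe),
#'   one per subject; NAs are dropped with their subjects
#' @param lesions subjects x voxels binary lesion-indicator matrix
#' @param min_group coverage rule (default 10 lesioned and 10 spared)
#' @param n_perm number of permutations (default 1000; >= 100 required)
#' @param alpha family-wise significance level (default 0.01)
#' @param seed integer seed for the permutation engine
#' @param tails `"one"` (default) or `"two"`
#' @return object of class `vlsm`: `t_map`, `tested_mask`, `null_max_t`,
#'   `t_critical`, `significant_mask`, `n_permutations`, `alpha`, `seed`,
#'   `n_subjects`, `n_dropped`
#' @export
vlsm <- function(scores, lesions, min_group = 10L, n_perm = 1000L,
                 alpha = 0.01, seed = 11L, tails = c("one", "two")) {
  tails <- match.arg(tails)
  lesions <- as.matrix(lesions)
  if (length(scores) != nrow(lesions))
    stop("scores and lesion stack are not aligned by subject", call. = FALSE)
  keep <- !is.na(scores)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) without scores dropped")
    scores <- scores[keep]
    lesions <- lesions[keep, , drop = FALSE]
  }
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  tested <- vlsm_coverage_filter(lesions, min_group)
  tmap <- vlsm_t_map(scores, lesions, tested)
  cols <- which(tested)
  stat <- function(tt) if (tails == "one") tt else abs(tt)

  set.seed(seed)
  null_max <- numeric(n_perm)
  block <- max(1L, min(n_perm, floor(2e7 / max(length(cols), 1L))))
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    P <- t(vapply(seq_len(b), function(i) sample(scores), numeric(length(scores))))
    tb <- vlsm_t_stat(P, lesions, cols)
    null_max[done + seq_len(b)] <- apply(stat(tb), 1L, max, na.rm = TRUE)
    done <- done + b
  }
  k <- max(1L, ceiling((1 - alpha) * n_perm))
  t_crit <- sort(null_max)[k]
  sig <- !is.na(tmap) & stat(tmap) > t_crit & tested
  structure(list(t_map = tmap, tested_mask = tested, null_max_t = null_max,
                 t_critical = t_crit, significant_mask = sig,
                 n_permutations = n_perm, alpha = alpha, seed = seed,
                 tails = tails, n_subjects = length(scores),
                 n_dropped = n_dropped),
            class = "vlsm")
}

#' @export
print.vlsm <- function(x, ...) {
  cat(sprintf(
    "<vlsm> %d subjects, %d tested voxels, %d permutations (%s-tailed)\n",
    x$n_subjects, sum(x$tested_mask), x$n_permutations, x$tails))
  cat(sprintf("  t_critical = %.3f (alpha = %g), significant voxels: %d\n",
              x$t_critical, x$alpha, sum(x$significant_mask)))
  invisible(x)
}

#' @export
summary.vlsm <- function(object, ...) {
  out <- list(n_subjects = object$n_subjects,
              n_dropped = object$n_dropped,
              n_tested = sum(object$tested_mask),
              n_significant = sum(object$significant_mask),
              t_critical = object$t_critical,
              max_t = suppressWarnings(max(object$t_map, na.rm = TRUE)),
              alpha = object$alpha,
              n_permutations = object$n_permutations)
  class(out) <- "summary.vlsm"
  out
}

#' @export
print.summary.vlsm <- function(x, ...) {
  cat(sprintf(paste0(
    "VLSM: %d subjects (%d dropped for missing scores)\n",
    "  tested voxels (coverage rule): %d\n",
    "  max observed t: %.3f; permutation t_critical (alpha %g, %d perms): %.3f\n",
    "  significant voxels: %d\n"),
    x$n_subjects, x$n_dropped, x$n_tested, x$max_t, x$alpha,
    x$n_permutations, x$t_critical, x$n_significant))
  invisible(x)
}

#' @export
plot.vlsm <- function(x, ...) {
  graphics::hist(x$null_max_t, breaks = 30, col = "grey80",
                 main = "Permutation null of the maximum t",
                 xlab = "max t per permutation", ...)
  graphics::abline(v = x$t_critical, col = "red", lwd = 2)
  mx <- suppressWarnings(max(x$t_map, na.rm = TRUE))
  graphics::abline(v = mx, col = "blue", lwd = 2, lty = 2)
  graphics::legend("topright", legend = c("t_critical", "observed max t"),
                   col = c("red", "blue"), lty = c(1, 2), lwd = 2)
  invisible(x)
}

#' Read a two-column behavioral score table
#'
#' Plain-text delimited file: subject id, score. Returns a named numeric
#' vector.
#' @param path file path
#' @param ... passed to [utils::read.table()]
#' @export
read_scores <- function(path, ...) {
  tb <- utils::read.table(path, header = FALSE, col.names = c("id", "score"),
                          stringsAsFactors = FALSE, ...)
  stats::setNames(as.numeric(tb$score), as.character(tb$id))
}

#' Stack ternary lesion maps into a subjects x voxels binary matrix
#' @param maps list of [lesion_map()]s on one grid
#' @return binary matrix, one row per map
#' @export
lesion_stack <- function(maps) {
  stopifnot(length(maps) >= 1L)
  t(vapply(maps, function(m) as.numeric(m$labels != 0L),
           numeric(length(maps[[1]]$labels))))
}

#' Lesion overlap map across subjects
#' @param maps list of [lesion_map()]s on one grid
#' @return `ct_volume` of per-voxel lesion counts
#' @export
lesion_overlap <- function(maps) {
  counts <- Reduce(`+`, lapply(maps, function(m) (m$labels != 0L) + 0))
  v <- ct_volume(counts, maps[[1]]$affine, space = maps[[1]]$space,
                 units = "scaled")
  v$units <- "scaled"
  v
}
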