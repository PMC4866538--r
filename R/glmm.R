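# Per-variant binomial mixed-model divergence test, exhaustive balanced
# label permutations, and the empirical permutation-ratio FDR that calls
# significantly diverged variants (SDV).

# Gauss-Hermite nodes/weights for weight exp(-x^2) (Golub-Welsch).
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1L, ord]^2)
}

#' Fit the per-variant binomial random-intercept GLMM
#'
#' Fits \eqn{logit(p_i) = \beta_0 + \beta_1 treat_i + u_i}, with
#' \eqn{alt_i \sim Binom(depth_i, p_i)} and \eqn{u_i \sim N(0, \sigma^2)}
#' one random intercept per replicate population, by maximum likelihood with
#' per-observation adaptive Gauss-Hermite quadrature. The default p-value is
#' the two-sided Wald test on the treatment coefficient; under
#' quasi-complete separation (a treatment group fixed at 0 or 1 in the
#' pooled counts) the reported p falls back to a likelihood-ratio test
#' against the no-treatment model and the fit is flagged.
#'
#' @param alt Alternate-allele read counts, one per sample.
#' @param depth Total depths (> 0), same length.
#' @param treat 0/1 treatment indicators, at least 2 samples per group.
#' @param nodes Quadrature nodes (default 15).
#' @return List with beta0, beta1, sigma_u, se1, z, p, p_lrt, loglik,
#'   loglik_null, converged and separated.
#' @export
fit_site_glmm <- function(alt, depth, treat, nodes = 15L) {
  stopifnot(length(alt) == length(depth), length(alt) == length(treat))
  if (any(depth <= 0)) stop("all samples must have depth > 0", call. = FALSE)
  if (min(table(factor(treat, levels = c(0, 1)))) < 2L)
    stop("need at least 2 samples per treatment group", call. = FALSE)
  gh <- gauss_hermite(nodes)
  fit <- .fit_glmm_batch(matrix(as.numeric(alt), 1L),
                         matrix(as.numeric(depth), 1L),
                         matrix(as.numeric(treat), 1L), gh$x, gh$w)
  z <- fit$beta1[1] / fit$se1[1]
  p_wald <- 2 * pnorm(-abs(z))
  lrt <- 2 * (fit$loglik[1] - fit$loglik_null[1])
  p_lrt <- pchisq(max(lrt, 0), df = 1L, lower.tail = FALSE)
  separated <- fit$separated[1] == 1L
  list(beta0 = fit$beta0[1], beta1 = fit$beta1[1], sigma_u = fit$sigma[1],
       se1 = fit$se1[1], z = z,
       p = if (separated || !is.finite(p_wald)) p_lrt else p_wald,
       p_wald = p_wald, p_lrt = p_lrt,
       loglik = fit$loglik[1], loglik_null = fit$loglik_null[1],
       converged = fit$converged[1] == 1L, separated = separated)
}

#' Enumerate balanced label permutations
#'
#' All distinct partitions of the 2k late-generation samples into two
#' unlabeled groups of k, excluding the observed assignment:
#' \eqn{C(2k, k)/2 - 1} relabelings (9 for the 3-vs-3 design).
#'
#' @param treat Observed 0/1 treatment assignment of the samples.
#' @return Matrix (relabelings x samples) of 0/1 assignments.
#' @export
enumerate_permutations <- function(treat) {
  treat <- as.integer(treat)
  n <- length(treat)
  k <- sum(treat == 1L)
  if (k * 2L != n)
    stop("permutation testing requires a balanced design (equal replicates ",
         "per treatment); subsample to balance before testing", call. = FALSE)
  sets <- combn(n, k)
  # canonical representative of each unlabeled partition: the half that
  # contains sample 1
  sets <- sets[, sets[1L, ] == 1L, drop = FALSE]
  obs <- which(treat == if (treat[1L] == 1L) 1L else 0L)
  keep <- apply(sets, 2L, function(s) !identical(sort(s), sort(obs)))
  sets <- sets[, keep, drop = FALSE]
  out <- matrix(0L, ncol(sets), n)
  for (j in seq_len(ncol(sets))) out[j, sets[, j]] <- 1L
  out
}

#' Empirical permutation FDR and SDV calling
#'
#' On the grid of distinct observed p-values \eqn{P}, computes
#' \eqn{FDR(P) = \frac{1}{N}\sum_n \#\{p_n < P\} / \#\{p_{obs} < P\}}
#' (strict inequalities), selects the largest grid threshold with
#' \eqn{FDR < \alpha}, and calls the variants below it significantly
#' diverged.
#'
#' @param p_obs Observed per-variant p-values.
#' @param p_perm Matrix (variants x relabelings) of permutation p-values;
#'   all permutation runs must use the identical variant set.
#' @param alpha FDR level (default 0.05).
#' @param monotone If TRUE, regularize the curve by a cumulative minimum
#'   from the smallest threshold upward (q-value style); off by default.
#' @return List with \code{curve} (data frame: threshold, s_obs, mean_perm,
#'   fdr), \code{threshold} (NA when no grid point passes), and \code{sdv}
#'   (logical vector).
#' @export
permutation_fdr <- function(p_obs, p_perm, alpha = 0.05, monotone = FALSE) {
  if (!length(p_obs)) stop("empty observed p-value set", call. = FALSE)
  p_perm <- as.matrix(p_perm)
  if (nrow(p_perm) != length(p_obs))
    stop("permutation p-values must cover the same variants", call. = FALSE)
  grid <- sort(unique(p_obs))
  so <- sort(p_obs)
  s_obs <- findInterval(grid, so, left.open = TRUE)
  nperm <- ncol(p_perm)
  mean_perm <- rowMeans(vapply(seq_len(nperm), function(j) {
    findInterval(grid, sort(p_perm[, j]), left.open = TRUE)
  }, numeric(length(grid))))
  fdr <- ifelse(s_obs > 0, mean_perm / s_obs, NA_real_)
  if (monotone) {
    ok <- !is.na(fdr)
    fdr[ok] <- rev(cummin(rev(fdr[ok])))
  }
  pass <- which(!is.na(fdr) & fdr < alpha)
  threshold <- if (length(pass)) grid[max(pass)] else NA_real_
  sdv <- if (is.na(threshold)) rep(FALSE, length(p_obs)) else p_obs < threshold
  list(curve = data.frame(threshold = grid, s_obs = s_obs,
                          mean_perm = mean_perm, fdr = fdr),
       threshold = threshold, sdv = sdv)
}

#' Genome-wide divergence scan with permutation FDR
#'
#' Fits the binomial GLMM at every variant for the observed late-generation
#' treatment labels and for all balanced relabelings, computes the
#' empirical permutation FDR, and calls SDV at the \code{alpha} threshold.
#' Sites inside \code{mask} regions (e.g. a heterochromatin analogue) are
#' excluded from SDV reporting but retained in the results.
#'
#' @param bt A \code{biallelic_table} from \code{\link{filter_variants}}.
#' @param design Sample design data frame.
#' @param alpha FDR level for SDV calling (default 0.05).
#' @param nodes Quadrature nodes (default 15).
#' @param generation Generation to test (default: the latest in the
#'   design).
#' @param mask Optional data frame (arm, start, end; 1-based closed) of
#'   regions whose variants are never reported as SDV.
#' @param permute If FALSE, fit only the observed labeling and skip the
#'   permutation FDR (no SDV calls); useful for calibration checks.
#' @return List with \code{results} (per-variant data frame: site, GLMM
#'   fit, permutation p-values p1..pN, sdv and masked flags), \code{fdr}
#'   (the \code{\link{permutation_fdr}} output), \code{threshold} and
#'   \code{perms} (the relabeling matrix).
#' @export
run_divergence_scan <- function(bt, design, alpha = 0.05, nodes = 15L,
                                generation = NULL, mask = NULL,
                                permute = TRUE) {
  design <- design[match(bt$samples, design$id), , drop = FALSE]
  if (anyNA(design$id)) stop("design does not cover all samples", call. = FALSE)
  if (is.null(generation)) generation <- max(design$generation)
  late <- which(design$generation == generation)
  if (!length(late)) stop("no samples at the requested generation", call. = FALSE)
  treat <- as.integer(design$treatment[late] == "selected")
  perms <- if (permute) enumerate_permutations(treat) else
    matrix(integer(0), 0L, length(treat))
  labelings <- rbind(treat, perms)

  alt <- bt$alt[, late, drop = FALSE]
  depth <- bt$depth[, late, drop = FALSE]
  testable <- rowSums(depth > 0L) == length(late)
  if (!any(testable)) stop("no testable variants (zero depths)", call. = FALSE)

  gh <- gauss_hermite(nodes)
  fit <- .fit_glmm_batch(matrix(as.numeric(alt[testable, ]), sum(testable)),
                         matrix(as.numeric(depth[testable, ]), sum(testable)),
                         matrix(as.numeric(labelings), nrow(labelings)),
                         gh$x, gh$w)

  nl <- nrow(labelings)
  z <- fit$beta1 / fit$se1
  p_wald <- 2 * pnorm(-abs(z))
  lrt <- pmax(2 * (fit$loglik - fit$loglik_null), 0)
  p_lrt <- pchisq(lrt, df = 1L, lower.tail = FALSE)
  use_lrt <- fit$separated == 1L | !is.finite(p_wald)
  p_all <- ifelse(use_lrt, p_lrt, p_wald)
  p_all <- matrix(p_all, ncol = nl)

  p_obs <- p_all[, 1L]
  p_perm <- p_all[, -1L, drop = FALSE]
  fdr <- if (permute) permutation_fdr(p_obs, p_perm, alpha = alpha) else
    list(curve = NULL, threshold = NA_real_, sdv = rep(FALSE, length(p_obs)))

  res <- bt$sites[testable, , drop = FALSE]
  res$beta1 <- fit$beta1[, 1L]
  res$se1 <- fit$se1[, 1L]
  res$sigma_u <- fit$sigma[, 1L]
  res$z <- z[, 1L]
  res$p <- p_obs
  res$converged <- fit$converged[, 1L] == 1L
  res$separated <- fit$separated[, 1L] == 1L
  if (ncol(p_perm)) {
    perm_cols <- as.data.frame(p_perm)
    names(perm_cols) <- paste0("p", seq_len(ncol(p_perm)))
    res <- cbind(res, perm_cols)
  }
  res$masked <- is_masked(res, mask)
  res$sdv <- fdr$sdv & !res$masked
  rownames(res) <- NULL

  list(results = res, fdr = fdr, threshold = fdr$threshold, perms = perms,
       generation = generation, nodes = nodes, alpha = alpha)
}

is_masked <- function(sites, mask) {
  if (is.null(mask) || !nrow(mask)) return(rep(FALSE, nrow(sites)))
  out <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(mask))) {
    out <- out | (sites$arm == mask$arm[i] & sites$pos >= mask$start[i] &
                    sites$pos <= mask$end[i])
  }
  out
}
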