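#' Filter and log2-transform an LFQ protein-intensity matrix
#'
#' Standard proteinGroups cleanup before a two-group comparison: decoy
#' (reversed), contaminant and identified-only-by-modification-site entries
#' are removed regardless of coverage; proteins quantified in fewer than
#' `min_valid` samples are removed; remaining intensities are log2
#' transformed (missing entries stay NA).
#'
#' @param matrix tibble with `protein_id`, optional logical flag columns
#'   `reverse`, `contaminant`, `only_by_site`, and one intensity column per
#'   sample.
#' @param samples character vector naming the sample columns; defaults to all
#'   non-id, non-flag columns.
#' @param min_valid minimum number of samples with a quantified value.
#' @return tibble `protein_id` + log2-intensity sample columns.
#' @export
filter_and_transform <- function(matrix, samples = NULL, min_valid = 3) {
  flags <- intersect(c("reverse", "contaminant", "only_by_site"), names(matrix))
  if (is.null(samples)) {
    samples <- setdiff(names(matrix), c("protein_id", flags))
  }
  check_that(length(samples) >= 2, "samples", "need at least two sample columns")
  keep <- rep(TRUE, nrow(matrix))
  for (f in flags) keep <- keep & !matrix[[f]]
  out <- matrix[keep, c("protein_id", samples)]
  n_valid <- rowSums(!is.na(as.matrix(out[samples])))
  out <- out[n_valid >= min_valid, ]
  for (s in samples) out[[s]] <- log2(out[[s]])
  out
}

#' Left-shifted normal imputation of missing log2 intensities
#'
#' Replaces each missing value with a draw from a normal distribution shifted
#' below the sample's observed intensity distribution, the conventional
#' treatment for left-censored (limit-of-detection) missingness in LFQ data:
#' missing cells in sample s are drawn from
#' Normal(mean_s - downshift * sd_s, (width * sd_s)^2), where mean_s and sd_s
#' are that sample's observed log2 mean and sd.
#'
#' @param matrix log2 matrix from [filter_and_transform()].
#' @param width imputation width as a fraction of the per-sample sd.
#' @param downshift centre shift in per-sample sd units.
#' @param seed integer seed; fixed seed gives identical imputations.
#' @return the completed tibble (no NAs).
#' @export
impute_lfq <- function(matrix, width = 0.3, downshift = 1.8, seed = 1L) {
  check_that(is.numeric(width) && width > 0, "width", "must be > 0")
  check_that(is.numeric(downshift) && downshift >= 0, "downshift", "must be >= 0")
  set.seed(as.integer(seed))
  samples <- setdiff(names(matrix), "protein_id")
  out <- matrix
  for (s in samples) {
    x <- out[[s]]
    obs <- x[!is.na(x)]
    if (sum(!is.na(x)) < length(x)) {
      if (length(obs) < 2) {
        abort(sprintf("sample '%s' has fewer than 2 observed values; cannot impute", s))
      }
      n_miss <- sum(is.na(x))
      x[is.na(x)] <- rnorm(n_miss,
                           mean = mean(obs) - downshift * sd(obs),
                           sd = width * sd(obs))
      out[[s]] <- x
    }
  }
  out
}

## Per-protein two-sample statistics for one label assignment.
## Returns diff (mean g1 - mean g2), pooled-variance se, and d = diff/(se+s0).
two_group_stats <- function(X, idx1, idx2, s0, var_equal = TRUE) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(X[, idx1, drop = FALSE])
  m2 <- rowMeans(X[, idx2, drop = FALSE])
  v1 <- rowSums((X[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(diff = m1 - m2, se = se, df = df, d = (m1 - m2) / (se + s0))
}

#' Modified two-sample t-test with an s0 fudge factor
#'
#' Per protein, the difference of group means on the log2 scale is tested
#' with a two-sample t statistic (pooled variance by default), and a
#' moderated statistic d = diff / (se + s0) is computed alongside it. The
#' constant s0 damps artefactually small standard errors, so that proteins
#' need both a large fold change and a stable estimate to score highly; with
#' s0 = 0, d equals the ordinary t statistic. Proteins with zero variance in
#' both groups get d defined by s0 alone and a flagged (NA) p value.
#'
#' @param matrix complete log2 tibble (see [impute_lfq()]).
#' @param groups tibble `sample, group` with exactly two group levels; the
#'   first level (by factor order `treated` before `untreated` if both named
#'   so, else first occurrence) is the minuend of the difference.
#' @param s0 fudge factor on the standard-error scale (log2 units).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return tibble `protein_id, difference, se, t, df, p, d`.
#' @export
modified_t_test <- function(matrix, groups, s0 = 1, var_equal = TRUE) {
  check_that(is.numeric(s0) && s0 >= 0, "s0", "must be >= 0")
  samples <- setdiff(names(matrix), "protein_id")
  check_that(all(samples %in% groups$sample), "groups",
             "must assign a group to every sample column")
  g <- setNames(groups$group, groups$sample)[samples]
  lev <- if (all(c("treated", "untreated") %in% g)) {
    c("treated", "untreated")
  } else {
    unique(g)
  }
  check_that(length(unique(g)) == 2, "groups", "need exactly two groups")
  idx1 <- which(g == lev[1]); idx2 <- which(g == lev[2])
  check_that(length(idx1) >= 2 && length(idx2) >= 2, "groups",
             "need >= 2 samples per group")

  X <- as.matrix(matrix[samples])
  st <- two_group_stats(X, idx1, idx2, s0, var_equal)
  t_stat <- st$diff / st$se
  p <- 2 * pt(-abs(t_stat), df = st$df)
  p[st$se == 0] <- NA_real_  # zero variance in both groups: p undefined

  tibble::tibble(protein_id = matrix$protein_id, difference = st$diff,
                 se = st$se, t = t_stat, df = st$df, p = p, d = st$d)
}

## All distinct non-trivial balanced label splits of n1 + n2 samples. Each
## split is a set of columns relabelled "group 1"; the identity assignment
## (and, for balanced designs, its mirror) is excluded because it reproduces
## the observed statistics rather than a null draw.
nontrivial_splits <- function(idx1, idx2) {
  n <- length(idx1) + length(idx2)
  combos <- utils::combn(n, length(idx1), simplify = FALSE)
  balanced <- length(idx1) == length(idx2)
  keep <- Filter(function(cmb) {
    if (setequal(cmb, idx1)) return(FALSE)
    if (balanced && setequal(cmb, idx2)) return(FALSE)
    TRUE
  }, combos)
  if (balanced) {
    seen <- character(0)
    out <- list()
    for (cmb in keep) {
      key_a <- paste(sort(cmb), collapse = ",")
      key_b <- paste(sort(setdiff(seq_len(n), cmb)), collapse = ",")
      if (key_a %in% seen || key_b %in% seen) next
      seen <- c(seen, key_a)
      out <- c(out, list(cmb))
    }
    keep <- out
  }
  keep
}

#' Permutation-based FDR thresholding of the moderated statistic
#'
#' Sweeps |d| thresholds over the observed statistics and estimates, at each
#' threshold, FDR = (mean permuted count of |d| >= threshold) / (observed
#' count of |d| >= threshold), where the permutations relabel the samples.
#' For small balanced designs (e.g. 3 vs 3) all distinct non-trivial label
#' splits are enumerated exactly (9 splits for 3 vs 3); for larger designs
#' `n_perm` random relabellings are drawn. The estimate is made monotone
#' (non-increasing in the threshold) by taking the running minimum from the
#' top, and the smallest threshold with estimated FDR <= `fdr_target` defines
#' the significance cut.
#'
#' @param matrix complete log2 tibble (see [impute_lfq()]).
#' @param groups tibble `sample, group` as in [modified_t_test()].
#' @param fdr_target target false-discovery rate (default 0.05).
#' @param s0 fudge factor, as in [modified_t_test()].
#' @param n_perm number of random permutations when exact enumeration is not
#'   feasible (> 12 samples); ignored for exact enumeration.
#' @param seed integer seed for sampled permutations.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return the [modified_t_test()] tibble plus `significant` (logical) and
#'   `est_fdr` (the monotone FDR estimate at that protein's |d|), with
#'   attributes `d_cut` (threshold defining significance; Inf when nothing
#'   passes) and `n_perm` (permutations used).
#' @export
permutation_fdr <- function(matrix, groups, fdr_target = 0.05, s0 = 1,
                            n_perm = 250, seed = 1L, var_equal = TRUE) {
  check_that(is.numeric(fdr_target) && fdr_target > 0 && fdr_target < 1,
             "fdr_target", "must be in (0, 1)")
  check_that(is.numeric(n_perm) && n_perm >= 1, "n_perm", "must be >= 1")
  res <- modified_t_test(matrix, groups, s0 = s0, var_equal = var_equal)

  samples <- setdiff(names(matrix), "protein_id")
  g <- setNames(groups$group, groups$sample)[samples]
  lev <- if (all(c("treated", "untreated") %in% g)) c("treated", "untreated") else unique(g)
  idx1 <- which(g == lev[1]); idx2 <- which(g == lev[2])
  X <- as.matrix(matrix[samples])
  n <- length(samples)

  if (n <= 12) {
    splits <- nontrivial_splits(idx1, idx2)
  } else {
    set.seed(as.integer(seed))
    splits <- replicate(n_perm, sort(sample(n, length(idx1))), simplify = FALSE)
  }
  if (length(splits) == 0) abort("no non-trivial label permutation available")

  perm_d <- vapply(splits, function(cmb) {
    abs(two_group_stats(X, cmb, setdiff(seq_len(n), cmb), s0, var_equal)$d)
  }, numeric(nrow(X)))

  obs <- abs(res$d)
  thresholds <- sort(unique(obs))
  obs_count <- vapply(thresholds, function(th) sum(obs >= th), numeric(1))
  perm_count <- vapply(thresholds, function(th) mean(colSums(perm_d >= th)), numeric(1))
  raw_fdr <- pmin(perm_count / obs_count, 1)
  ## q-value-style monotone estimate: each threshold reports the best FDR
  ## achievable by any looser (smaller) threshold whose rejection set
  ## contains its own, so the estimate is non-increasing in the threshold
  mono_fdr <- cummin(raw_fdr)

  d_cut <- if (any(mono_fdr <= fdr_target)) min(thresholds[mono_fdr <= fdr_target]) else Inf
  est <- mono_fdr[match(obs, thresholds)]

  out <- dplyr::mutate(res, est_fdr = est, significant = obs >= d_cut)
  attr(out, "d_cut") <- d_cut
  attr(out, "n_perm") <- length(splits)
  out
}

#' Full null-proteome comparison
#'
#' Convenience wrapper running the whole chain: flag/coverage filtering and
#' log2 transform, left-shifted normal imputation, the s0-moderated t-test
#' and permutation FDR thresholding.
#'
#' @param matrix raw intensity tibble (see [filter_and_transform()]).
#' @param groups tibble `sample, group`.
#' @param fdr_target,s0 significance parameters.
#' @param width,downshift imputation parameters (see [impute_lfq()]).
#' @param min_valid coverage filter (see [filter_and_transform()]).
#' @param seed seed for imputation (and sampled permutations).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return as [permutation_fdr()].
#' @export
proteome_compare <- function(matrix, groups, fdr_target = 0.05, s0 = 1,
                             width = 0.3, downshift = 1.8, min_valid = 3,
                             seed = 1L, var_equal = TRUE) {
  filtered <- filter_and_transform(matrix, samples = groups$sample,
                                   min_valid = min_valid)
  complete <- impute_lfq(filtered, width = width, downshift = downshift, seed = seed)
  permutation_fdr(complete, groups, fdr_target = fdr_target, s0 = s0,
                  seed = seed, var_equal = var_equal)
}
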