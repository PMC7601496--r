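# Genealogy-aware uncertainty quantification.  Snapshots at a level that
# descend from a common ancestor n levels back form an nth-order descendant
# group; a Fisher-type intraclass correlation over the per-snapshot
# advancement probabilities picks the smallest effectively uncorrelated
# grouping, whose group means then feed the standard error of the mean.

# ancestor of snapshot `j` at `order` levels above `level` (0-based levels)
ancestor_ids <- function(genealogy, level, order) {
  ids <- seq_along(genealogy[[level + 1]]$parent)
  for (k in seq_len(order)) {
    ids <- genealogy[[level + 2 - k]]$parent[ids]
  }
  ids
}

#' Group level snapshots by common ancestry
#'
#' Partitions the snapshots of level `level` (0-based, level 0 being the
#' crossing snapshots at \eqn{\lambda_0}) by their ancestor `order` levels
#' earlier. Order 0 puts every snapshot in its own group; order 1 groups
#' siblings; higher orders add cousins of increasing remove. Snapshots
#' without a defined advancement probability (no allocated trials) are
#' excluded from the grouping.
#'
#' @param genealogy the `genealogy` component of an `ffs_result`
#' @param level 0-based level index
#' @param order ancestry depth `n`, `0 <= n <= level`
#' @return an object of class `descendant_grouping`: a list of integer
#'   vectors (snapshot indices) with attributes `level`, `order` and
#'   `n_pairs` (the number of intragroup pairs)
#' @export
descendant_groups <- function(genealogy, level, order) {
  if (order > level) stop("descendant_groups: order exceeds level")
  stopifnot(level >= 0, order >= 0, level + 1 <= length(genealogy))
  lev <- genealogy[[level + 1]]
  keep <- if (is.null(lev$trials)) seq_along(lev$parent) else
    which(lev$trials > 0)
  anc <- ancestor_ids(genealogy, level, order)[keep]
  groups <- split(keep, anc)
  names(groups) <- NULL
  sizes <- lengths(groups)
  structure(groups, class = "descendant_grouping", level = level,
            order = order, n_pairs = sum(sizes * (sizes - 1) / 2))
}

#' Ancestry-corrected mean advancement probability
#'
#' Mean of group means: each descendant group contributes once, removing
#' the over-averaging of snapshots correlated through common ancestry.
#' With all-singleton groups this reduces to the flat mean.
#'
#' @param grouping a [descendant_groups()] partition
#' @param p per-snapshot advancement probabilities (indexed as in the
#'   genealogy level)
#' @return the corrected mean
#' @export
corrected_mean <- function(grouping, p) {
  stopifnot(inherits(grouping, "descendant_grouping"), length(grouping) >= 1)
  mean(vapply(grouping, function(g) mean(p[g]), numeric(1)))
}

#' Intraclass correlation of advancement probabilities
#'
#' Fisher-type intraclass correlation over the intragroup pairs of a
#' descendant grouping,
#' \deqn{r = \frac{|M|}{|P|}\,
#'   \frac{\sum_{(j,k)\in P}(p_j - \bar p)(p_k - \bar p)}
#'        {\sum_{j\in M}(p_j-\bar p)^2},}
#' with \eqn{\bar p} the ancestry-corrected mean. Values may fall outside
#' \eqn{[-1,1]} for small samples; they are reported unclipped. When all
#' probabilities are equal the correlation is defined as 0 and flagged
#' `degenerate`.
#'
#' @inheritParams corrected_mean
#' @return the correlation, with attribute `degenerate = TRUE` when the
#'   variance vanished
#' @export
intraclass_correlation <- function(grouping, p) {
  stopifnot(inherits(grouping, "descendant_grouping"))
  n_pairs <- attr(grouping, "n_pairs")
  if (n_pairs < 1) {
    stop("intraclass_correlation: grouping has no intragroup pairs")
  }
  pbar <- corrected_mean(grouping, p)
  members <- unlist(grouping, use.names = FALSE)
  denom <- sum((p[members] - pbar)^2)
  if (denom <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  # sum over intragroup pairs via the square-of-sums identity
  pairsum <- sum(vapply(grouping, function(g) {
    d <- p[g] - pbar
    (sum(d)^2 - sum(d^2)) / 2
  }, numeric(1)))
  (length(members) / n_pairs) * pairsum / denom
}

#' Select the smallest effectively uncorrelated grouping order
#'
#' The smallest ancestry order `L` whose intraclass correlation drops to
#' `threshold` (1/e) or below; capped at `level` (grouping by the level-0
#' founders) with attribute `capped = TRUE` if the correlation never
#' relaxes.
#'
#' @param genealogy the `genealogy` component of an `ffs_result`
#' @param level 0-based level index (needs at least 2 snapshots with
#'   trials)
#' @param p per-snapshot advancement probabilities
#' @param threshold correlation threshold
#' @return the order `L` (integer), possibly with attribute `capped`
#' @export
select_order <- function(genealogy, level, p, threshold = exp(-1)) {
  if (level == 0) return(0L)
  for (n in seq_len(level)) {
    g <- descendant_groups(genealogy, level, n)
    # no intragroup pairs: all ancestors distinct, uncorrelated by structure
    if (attr(g, "n_pairs") < 1) return(as.integer(n))
    r <- intraclass_correlation(g, p)
    if (r <= threshold) return(as.integer(n))
  }
  structure(as.integer(level), capped = TRUE)
}

#' Standard error of a level's advancement probability
#'
#' SEM over the group means of the selected grouping,
#' \deqn{\sigma_{p_i} = \sqrt{\frac{1}{|G|(|G|-1)}
#'   \sum_{g\in G}\Big(\bar p - \tfrac1{|g|}\sum_{j\in g}p_j\Big)^2}.}
#' At order 0 this is the classic SEM of the per-snapshot probabilities.
#'
#' @inheritParams corrected_mean
#' @return the standard error; `NA` with attribute `single_group = TRUE`
#'   when only one group exists (no error estimate possible)
#' @export
level_sem <- function(grouping, p) {
  stopifnot(inherits(grouping, "descendant_grouping"))
  G <- length(grouping)
  if (G < 2) {
    return(structure(NA_real_, single_group = TRUE))
  }
  gm <- vapply(grouping, function(g) mean(p[g]), numeric(1))
  pbar <- mean(gm)
  sqrt(sum((pbar - gm)^2) / (G * (G - 1)))
}

#' Conservative standard error (founder grouping)
#'
#' Assumes any common ancestor induces perfect correlation: snapshots are
#' grouped by their level-0 founder and the SEM is taken over those group
#' means. On genealogies where correlation actually decays with ancestral
#' distance this upper-bounds the corrected estimate.
#'
#' @inheritParams select_order
#' @return the standard error (NA-flagged when a single founder remains)
#' @export
conservative_sem <- function(genealogy, level, p) {
  g <- descendant_groups(genealogy, level, level)
  level_sem(g, p)
}

#' Per-level uncertainty table for an FFS run
#'
#' For each level: the raw advancement probability, the selected
#' correlation order `L`, the ancestry-corrected mean, and both the
#' corrected (order-`L`) and conservative (founder-grouped) standard
#' errors.
#'
#' @param result an `ffs_result`
#' @return data frame with one row per level
#' @export
ffs_level_stats <- function(result) {
  stopifnot(inherits(result, "ffs_result"))
  n_lev <- length(result$p_hats)
  rows <- lapply(seq_len(n_lev) - 1L, function(i) {
    p <- result$p_values[[i + 1]]
    L <- select_order(result$genealogy, i, p)
    g <- descendant_groups(result$genealogy, i, L)
    g0 <- descendant_groups(result$genealogy, i, 0L)
    data.frame(
      level = i, lambda = if (i == 0) result$lambda_0 else
        result$levels[i],
      p_hat = result$p_hats[i + 1],
      n_snapshots = length(unlist(g0)),
      L = as.integer(L),
      p_corrected = corrected_mean(g, p),
      sem = as.numeric(level_sem(g, p)),
      sem_conservative = as.numeric(
        conservative_sem(result$genealogy, i, p)),
      capped = isTRUE(attr(L, "capped"))
    )
  })
  do.call(rbind, rows)
}

#' 95% confidence interval for the assembled rate
#'
#' Log-space propagation: the base rate contributes a Poisson relative
#' variance `1/k` on `k` counted crossings, each level a relative variance
#' \eqn{(\sigma_i/\hat p_i)^2}; the interval is
#' \eqn{r\,\exp(\pm 1.96\sqrt{\mathrm{var}\,\ln r})}. Both the corrected
#' and the conservative per-level errors are propagated. Levels whose SEM
#' is undefined (single group) contribute their conservative counterpart,
#' or are dropped with a warning if both are undefined.
#'
#' @param result an `ffs_result`
#' @param stats optional precomputed [ffs_level_stats()] table
#' @return list with `ci` (corrected), `ci_conservative`, `log_sd`,
#'   `log_sd_conservative`
#' @export
rate_confidence_interval <- function(result, stats = NULL) {
  if (is.null(stats)) stats <- ffs_level_stats(result)
  v_base <- 1 / result$n_crossings
  rel2 <- function(sem) (sem / stats$p_hat)^2
  vc <- rel2(stats$sem)
  vk <- rel2(stats$sem_conservative)
  vc[is.na(vc)] <- vk[is.na(vc)]
  if (any(is.na(vc))) {
    warning("levels with no error estimate were dropped from the CI")
    vc[is.na(vc)] <- 0
  }
  vk[is.na(vk)] <- vc[is.na(vk)]
  sd_c <- sqrt(v_base + sum(vc))
  sd_k <- sqrt(v_base + sum(vk))
  list(ci = result$rate * exp(c(-1, 1) * 1.96 * sd_c),
       ci_conservative = result$rate * exp(c(-1, 1) * 1.96 * sd_k),
       log_sd = sd_c, log_sd_conservative = sd_k)
}
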