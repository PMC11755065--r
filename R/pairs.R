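# Pair-level inference: the exhaustive female x male cross-pair table,
# collinearity screening, the matching-permutation null, and the paired /
# unpaired t-test comparisons.

#' Build the real-vs-randomized pair table
#'
#' Within each year every female is crossed with every male, giving
#' `n_F x n_M` rows; each row carries the absolute female-male difference in
#' every trait, an `is_real` flag (1 for the observed breeding pairs), and a
#' case weight. By default real pairs are weighted `n_randomized / n_real`
#' within their year and randomized pairs 1, balancing total class weight;
#' override with `weight_real`. Traits named in `standardize` are z-scored
#' across all rows after differencing. An optional per-pair overlap matrix
#' adds a `log1p_BA` column (log(1 + x)-transformed).
#'
#' @param metrics Data frame with columns `bird_id, sex, year, pair_id` and
#'   one column per trait.
#' @param traits Character vector of trait columns to difference.
#' @param standardize Traits whose absolute differences are z-scored
#'   (default none).
#' @param ba Optional named overlap lookup: a data frame with columns
#'   `female_id, male_id, ba`.
#' @param weight_real `"balanced"` (default) or a positive number used as
#'   the weight of real pairs.
#' @return Object of class `pair_table` (a data frame): `female_id, male_id,
#'   year, is_real, weight`, one `d_<trait>` column per trait, and `log1p_BA`
#'   when `ba` is given.
#' @export
build_pair_table <- function(metrics, traits,
                             standardize = character(0),
                             ba = NULL, weight_real = "balanced") {
  stopifnot(all(c("bird_id", "sex", "year", "pair_id") %in% names(metrics)))
  missing_traits <- setdiff(traits, names(metrics))
  if (length(missing_traits))
    stop("metrics lack trait column(s): ",
         paste(missing_traits, collapse = ", "))
  keep <- stats::complete.cases(metrics[, traits, drop = FALSE])
  if (any(!keep))
    message("dropping ", sum(!keep), " bird(s) with missing trait values: ",
            paste(metrics$bird_id[!keep], collapse = ", "))
  metrics <- metrics[keep, , drop = FALSE]
  rows <- list()
  for (yr in unique(metrics$year)) {
    fem <- metrics[metrics$year == yr & metrics$sex == "F", , drop = FALSE]
    mal <- metrics[metrics$year == yr & metrics$sex == "M", , drop = FALSE]
    if (!nrow(fem) || !nrow(mal)) next
    g <- expand.grid(fi = seq_len(nrow(fem)), mi = seq_len(nrow(mal)))
    tab <- data.frame(female_id = fem$bird_id[g$fi],
                      male_id = mal$bird_id[g$mi],
                      year = yr,
                      is_real = as.integer(fem$pair_id[g$fi] ==
                                             mal$pair_id[g$mi]),
                      stringsAsFactors = FALSE)
    for (tr in traits)
      tab[[paste0("d_", tr)]] <- abs(fem[[tr]][g$fi] - mal[[tr]][g$mi])
    n_real <- sum(tab$is_real)
    n_rand <- nrow(tab) - n_real
    w_real <- if (identical(weight_real, "balanced")) {
      if (n_real > 0) n_rand / n_real else 1
    } else as.numeric(weight_real)
    tab$weight <- ifelse(tab$is_real == 1, w_real, 1)
    rows[[yr]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (tr in standardize) {
    cn <- paste0("d_", tr)
    if (!cn %in% names(out)) next
    out[[cn]] <- as.numeric(scale(out[[cn]]))
  }
  if (!is.null(ba)) {
    key <- paste(out$female_id, out$male_id)
    bkey <- paste(ba$female_id, ba$male_id)
    out$log1p_BA <- log1p(ba$ba[match(key, bkey)])
  }
  class(out) <- c("pair_table", "data.frame")
  out
}

#' @export
print.pair_table <- function(x, n = 6, ...) {
  cat("Pair table:", nrow(x), "potential pairs (", sum(x$is_real), "real /",
      sum(x$is_real == 0), "randomized ) across year(s)",
      paste(unique(x$year), collapse = ", "), "\n")
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Screen traits for collinearity
#'
#' Computes the Pearson correlation matrix of the given columns and, for any
#' pair correlated beyond `threshold`, drops one of the two: the "mean"
#' variant of a metric is preferred over its "max"/"min"/"total"/"sd"
#' variants, otherwise the later column goes. Constant columns have no
#' defined correlation and are excluded with a warning.
#'
#' @param x Data frame or matrix of trait columns.
#' @param threshold Absolute correlation above which two traits cannot
#'   coexist (default 0.8).
#' @return List: `retained` (character), `dropped` (data frame with the
#'   offending pairs and correlations).
#' @export
collinearity_filter <- function(x, threshold = 0.8) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2)
  const <- vapply(x, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)),
                  TRUE)
  if (any(const)) {
    warning("constant column(s) excluded: ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  cm <- stats::cor(x)
  nm <- colnames(cm)
  retained <- nm
  dropped <- list()
  prefer <- function(a, b) {
    # returns the name to KEEP
    a_mean <- grepl("mean", a, ignore.case = TRUE)
    b_mean <- grepl("mean", b, ignore.case = TRUE)
    if (a_mean && !b_mean) a else if (b_mean && !a_mean) b else a
  }
  pairs <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(cm[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      a <- nm[pairs[r, 1]]; b <- nm[pairs[r, 2]]
      if (!(a %in% retained) || !(b %in% retained)) next
      keep <- prefer(a, b)
      drop <- setdiff(c(a, b), keep)
      retained <- setdiff(retained, drop)
      dropped[[length(dropped) + 1]] <-
        data.frame(kept = keep, dropped = drop, r = cm[pairs[r, 1],
                                                       pairs[r, 2]])
    }
  }
  list(retained = retained,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(kept = character(0), dropped = character(0),
                    r = numeric(0)))
}

# All perfect matchings (permutations) of n items, as a matrix of rows.
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Matching-permutation test of within-pair trait (dis)similarity
#'
#' The statistic is the mean absolute trait difference over real pairs minus
#' the mean over all potential pairs. The null redraws, within each year, a
#' uniform random perfect matching between females and males (each bird in
#' exactly one pseudo-real pair), which respects exactly the dependence
#' created by each bird appearing in many rows of the cross-pair table.
#' Two-sided p-value `(1 + #(|T_perm| >= |T_obs|)) / (1 + n_perm)`. When the
#' total number of matchings is small (at most `exhaustive_limit`) the full
#' enumeration is used instead and the p-value is exact.
#'
#' @param pair_table A [build_pair_table()] output.
#' @param trait Trait name (with or without the `d_` prefix).
#' @param n_perm Number of permutations (default 999; a warning below 99).
#' @param seed Integer seed.
#' @param exhaustive_limit Enumerate all matchings when their count is at
#'   most this (default 1000).
#' @return List: `statistic`, `p_value`, `null` (numeric vector of permuted
#'   statistics), `exhaustive`, `n_perm`.
#' @export
matching_permutation_test <- function(pair_table, trait, n_perm = 999,
                                      seed = 1L, exhaustive_limit = 1000) {
  cn <- if (startsWith(trait, "d_") || trait == "log1p_BA") trait
  else paste0("d_", trait)
  if (!cn %in% names(pair_table)) stop("no such trait column: ", cn)
  if (n_perm < 99) warning("n_perm < 99 gives a very coarse p-value")
  years <- unique(pair_table$year)
  # per-year difference matrix [female, male] and the observed matching
  mats <- list(); obs_match <- list()
  for (yr in years) {
    sub <- pair_table[pair_table$year == yr, ]
    f <- sort(unique(sub$female_id)); m <- sort(unique(sub$male_id))
    if (length(f) != length(m))
      stop("matching null needs equal numbers of females and males in year ",
           yr)
    M <- matrix(NA_real_, length(f), length(m), dimnames = list(f, m))
    M[cbind(match(sub$female_id, f), match(sub$male_id, m))] <- sub[[cn]]
    real <- sub[sub$is_real == 1, ]
    if (nrow(real) < 2) stop("need >= 2 real pairs per year")
    om <- match(real$male_id[match(f, real$female_id)], m)
    mats[[yr]] <- M
    obs_match[[yr]] <- om
  }
  grand_mean <- mean(unlist(lapply(mats, as.vector)), na.rm = TRUE)
  stat_for <- function(matching) {
    vals <- unlist(lapply(years, function(yr)
      mats[[yr]][cbind(seq_len(nrow(mats[[yr]])), matching[[yr]])]))
    mean(vals) - grand_mean
  }
  t_obs <- stat_for(obs_match)
  sizes <- vapply(mats, nrow, 0L)
  n_total <- prod(factorial(sizes))
  if (is.finite(n_total) && n_total <= exhaustive_limit) {
    perm_sets <- lapply(sizes, function(n) .all_perms(n))
    idx_grid <- expand.grid(lapply(perm_sets, function(p) seq_len(nrow(p))))
    null <- apply(idx_grid, 1, function(ix) {
      matching <- lapply(seq_along(years), function(j)
        perm_sets[[j]][ix[j], ])
      names(matching) <- years
      stat_for(matching)
    })
    p <- mean(abs(null) >= abs(t_obs) - 1e-12)
    return(list(statistic = t_obs, p_value = p, null = null,
                exhaustive = TRUE, n_perm = length(null)))
  }
  set.seed(as.integer(seed))
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    matching <- lapply(sizes, function(n) sample.int(n))
    names(matching) <- years
    null[b] <- stat_for(matching)
  }
  p <- (1 + sum(abs(null) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  list(statistic = t_obs, p_value = p, null = null, exhaustive = FALSE,
       n_perm = n_perm)
}

#' Unpaired two-sample Student's t-test (pooled variance)
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @return List `t`, `df`, `p` (two-sided).
#' @export
ttest_unpaired <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per sample")
  if (stats::sd(c(x, y)) == 0) stop("zero variance: t undefined")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Paired Student's t-test
#'
#' @param before,after Numeric samples of equal length.
#' @return List `t`, `df`, `p` (two-sided).
#' @export
ttest_paired <- function(before, after) {
  if (length(before) != length(after)) stop("paired samples differ in length")
  if (length(before) < 2) stop("need n >= 2 pairs")
  if (stats::sd(before - after) == 0)
    stop("zero variance of differences: t undefined")
  ht <- stats::t.test(before, after, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
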