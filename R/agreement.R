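# Agreement and robustness statistics: pairwise Dice overlap, near-zero
# variance filtering, ICC(2,1) from two-way ANOVA mean squares, robustness
# classification against a strict cutoff, and the easy-vs-challenging
# stratified comparison.

#' Dice similarity coefficient of two masks
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)` over voxel sets; 1 means perfect
#' overlap, 0 disjoint segmentations.
#'
#' @param a,b aligned `seg_mask` objects, not both empty.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!check_aligned(a, b))
    stop("masks are not geometrically aligned", call. = FALSE)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L)
    stop("DSC undefined: both masks are empty", call. = FALSE)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Pairwise DSC table for a cohort
#'
#' One row per unordered observer pair per tumor, plus per-pair and overall
#' means in the attributes.
#'
#' @param cohort list of observer sets ([make_cohort()]).
#' @return A data.frame (tumor_id, observer_a, observer_b, dsc, difficulty)
#'   with attributes `pair_means` (mean DSC per observer pair) and
#'   `overall_mean`.
#' @export
pairwise_dsc <- function(cohort) {
  rows <- list()
  for (os in cohort) {
    obs <- os$observer_masks
    k <- length(obs)
    if (k < 2) stop("tumor ", os$tumor_id, " has fewer than 2 observers",
                    call. = FALSE)
    nm <- names(obs)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = os$tumor_id, observer_a = nm[i], observer_b = nm[j],
        dsc = dsc(obs[[i]], obs[[j]]), difficulty = os$difficulty)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pair_key <- paste(out$observer_a, out$observer_b, sep = "-")
  attr(out, "pair_means") <- tapply(out$dsc, pair_key, mean)
  attr(out, "overall_mean") <- mean(out$dsc)
  out
}

#' Near-zero-variance feature filter
#'
#' Removes features whose modal value accounts for at least `threshold` of
#' all (tumor, observer) observations, and features whose values are
#' predominantly undefined (NA in more than half the records) — neither
#' carries discriminative value.
#'
#' @param ft long-format feature table ([cohort_feature_table()]).
#' @param threshold modal-share threshold (default 0.95).
#' @return list with `table` (retained rows) and `removed` (data.frame of
#'   feature_name + reason).
#' @export
nzv_filter <- function(ft, threshold = 0.95) {
  stopifnot(nrow(ft) > 0)
  split_vals <- split(ft$value, ft$feature_name)
  status <- vapply(split_vals, function(v) {
    if (mean(is.na(v)) > 0.5) return("undefined_dominant")
    v <- v[!is.na(v)]
    modal <- max(tabulate(match(v, unique(v))))
    if (modal / length(v) >= threshold) "near_zero_variance" else "ok"
  }, character(1))
  removed <- data.frame(feature_name = names(status)[status != "ok"],
                        reason = unname(status[status != "ok"]))
  kept <- ft[ft$feature_name %in% names(status)[status == "ok"], ,
             drop = FALSE]
  attributes(kept)$difficulty <- attr(ft, "difficulty")
  list(table = kept, removed = removed)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the two-way ANOVA mean squares (subjects MSR, raters MSC, residual MSE):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#'
#' @param values numeric n x k matrix: n subjects (tumors) by k raters
#'   (observers), complete.
#' @return ICC value, or `NA` when the denominator vanishes (all cells
#'   equal).
#' @export
icc21 <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2)
    stop("ICC(2,1) needs at least 2 subjects and 2 raters", call. = FALSE)
  if (anyNA(values)) stop("ICC input must be complete", call. = FALSE)
  grand <- mean(values)
  rm_ <- rowMeans(values)
  cm <- colMeans(values)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((values - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-30) return(NA_real_)
  (msr - mse) / denom
}

#' Per-feature ICC table with robustness classification
#'
#' Builds the tumors x observers matrix for every feature, applies
#' subject-wise deletion of tumors with undefined cells, computes ICC(2,1),
#' and flags features with ICC strictly above `cutoff` as robust.
#'
#' @param ft long-format feature table (after [nzv_filter()]).
#' @param cutoff robustness cutoff (strict inequality; default 0.9).
#' @param manifest optional [feature_manifest()] to attach group/filter.
#' @return data.frame (feature_name, icc, n_subjects, n_raters, robust,
#'   group, filter).
#' @export
icc_table <- function(ft, cutoff = 0.9, manifest = NULL) {
  idx_by_feat <- split(seq_len(nrow(ft)), ft$feature_name)
  feats <- unique(ft$feature_name)
  res <- lapply(feats, function(f) {
    sub <- ft[idx_by_feat[[f]], ]
    tumors <- sort(unique(sub$tumor_id))
    raters <- sort(unique(sub$observer_id))
    wide <- matrix(NA_real_, length(tumors), length(raters))
    wide[cbind(match(sub$tumor_id, tumors),
               match(sub$observer_id, raters))] <- sub$value
    complete <- stats::complete.cases(wide)
    wide <- wide[complete, , drop = FALSE]
    icc <- if (nrow(wide) >= 2 && ncol(wide) >= 2) icc21(wide) else NA_real_
    data.frame(feature_name = f, icc = icc, n_subjects = nrow(wide),
               n_raters = ncol(wide),
               robust = !is.na(icc) && icc > cutoff)
  })
  out <- do.call(rbind, res)
  if (!is.null(manifest)) {
    idx <- match(out$feature_name, manifest$name)
    out$group <- manifest$group[idx]
    out$filter <- manifest$filter[idx]
  }
  rownames(out) <- NULL
  out
}

#' Robustness report: group summaries and overall mean ICC
#'
#' Per (group, filter): mean/min/max ICC, robust count, total count and
#' robust percentage; plus the overall across-feature mean ICC with a
#' t-based 95 percent confidence interval.
#'
#' @param iccs data.frame from [icc_table()] (with group/filter columns).
#' @param manifest optional manifest for total counts (defaults to rows of
#'   `iccs`).
#' @return list with `by_group` (data.frame), `overall` (list: mean_icc,
#'   ci_low, ci_high, robust_count, total_count, robust_percentage).
#' @export
summarize_robustness <- function(iccs, manifest = NULL) {
  stopifnot(nrow(iccs) > 0)
  if (is.null(iccs$group)) iccs$group <- "all"
  if (is.null(iccs$filter)) iccs$filter <- "original"
  key <- interaction(iccs$group, iccs$filter, drop = TRUE)
  by_group <- do.call(rbind, lapply(split(iccs, key), function(g) {
    v <- g$icc[!is.na(g$icc)]
    data.frame(group = g$group[1], filter = g$filter[1],
               mean_icc = if (length(v)) mean(v) else NA_real_,
               min_icc = if (length(v)) min(v) else NA_real_,
               max_icc = if (length(v)) max(v) else NA_real_,
               robust_count = sum(g$robust), total_count = nrow(g),
               robust_percentage = 100 * sum(g$robust) / nrow(g))
  }))
  rownames(by_group) <- NULL
  v <- iccs$icc[!is.na(iccs$icc)]
  ci <- if (length(v) > 1) {
    se <- stats::sd(v) / sqrt(length(v))
    mean(v) + c(-1, 1) * stats::qt(0.975, length(v) - 1) * se
  } else c(NA_real_, NA_real_)
  total <- if (!is.null(manifest)) nrow(manifest) else nrow(iccs)
  overall <- list(mean_icc = if (length(v)) mean(v) else NA_real_,
                  ci_low = ci[1], ci_high = ci[2],
                  robust_count = sum(iccs$robust), total_count = total,
                  robust_percentage = 100 * sum(iccs$robust) / total)
  list(by_group = by_group, overall = overall)
}

#' Compare easy and challenging strata
#'
#' Per-tumor mean DSC is compared between strata with a two-sided Welch
#' independent-samples t-test; stratified robustness summaries are attached
#' when stratified ICC tables are supplied.
#'
#' @param pd pairwise DSC table from [pairwise_dsc()].
#' @param icc_by_stratum optional named list of [icc_table()] results, one
#'   per difficulty stratum.
#' @return list: per-stratum mean DSC and n, Welch `t`, `df`, `p_value`,
#'   `mean_difference`, and optional `robustness` summaries per stratum.
#' @export
stratified_compare <- function(pd, icc_by_stratum = NULL) {
  per_tumor <- stats::aggregate(dsc ~ tumor_id + difficulty, data = pd,
                                FUN = mean)
  strata <- split(per_tumor$dsc, per_tumor$difficulty)
  if (length(strata) < 2)
    stop("both difficulty strata must be present", call. = FALSE)
  if (any(vapply(strata, length, integer(1)) < 2))
    stop("each stratum needs at least 2 tumors", call. = FALSE)
  tt <- tryCatch(
    stats::t.test(strata$easy, strata$challenging, var.equal = FALSE),
    error = function(e) {
      # degenerate limit: both strata (essentially) constant
      delta <- mean(strata$easy) - mean(strata$challenging)
      if (abs(delta) < 1e-12)
        list(statistic = 0, parameter = NA_real_, p.value = 1)
      else
        list(statistic = sign(delta) * Inf, parameter = NA_real_,
             p.value = 0)
    })
  out <- list(
    mean_dsc_easy = mean(strata$easy),
    mean_dsc_challenging = mean(strata$challenging),
    n_easy = length(strata$easy),
    n_challenging = length(strata$challenging),
    mean_difference = mean(strata$easy) - mean(strata$challenging),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value)
  if (!is.null(icc_by_stratum))
    out$robustness <- lapply(icc_by_stratum, summarize_robustness)
  out
}
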