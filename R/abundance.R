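#' Construct a detection-limit-censored Log10 CFU series
#'
#' Replicated Log10 CFU observations over ordered time points with a limit
#' of detection (LOD). Values below the LOD are flagged censored and carry
#' the LOD as their numeric stand-in; the flags are preserved through every
#' transform, never dropped silently.
#'
#' @param time_point time-point label per observation.
#' @param log10_cfu observed Log10 CFU values.
#' @param replicate replicate index per observation (defaults to running
#'   index within time point).
#' @param compartment single label, e.g. "bryozoan" or "seawater".
#' @param censored logical flags; by default derived as `log10_cfu < lod`.
#' @param lod limit of detection on the Log10 scale.
#' @return data.frame of class `censored_series` with columns
#'   `compartment`, `time_point` (factor ordered by first appearance),
#'   `replicate`, `log10_cfu`, `censored`, and attribute `lod`.
#' @export
censored_series <- function(time_point, log10_cfu, replicate = NULL,
                            compartment = "sample", censored = NULL,
                            lod = 1.0) {
  stopifnot(length(time_point) == length(log10_cfu), length(log10_cfu) >= 1L)
  if (is.null(censored)) censored <- log10_cfu < lod
  stopifnot(length(censored) == length(log10_cfu))
  vals <- ifelse(censored, lod, log10_cfu)
  tp <- factor(time_point, levels = unique(time_point))
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(vals), tp, FUN = seq_along)
  out <- data.frame(compartment = compartment, time_point = tp,
                    replicate = replicate, log10_cfu = vals,
                    censored = censored, stringsAsFactors = FALSE)
  attr(out, "lod") <- lod
  class(out) <- c("censored_series", class(out))
  out
}

series_lod <- function(series) attr(series, "lod") %||% 1.0

#' Per-time-point summary of a censored series
#'
#' Mean and s.d. are computed over detected values (the reporting
#' convention "x Log10 CFU +/- y (s.d.)"), with LOD-substituted variants
#' alongside; time points with all replicates censored are labeled "<LOD".
#'
#' @param series a [censored_series()].
#' @return data.frame with one row per time point: `n`, `n_detected`,
#'   `mean_detected`, `sd_detected`, `mean_lod_sub`, `sd_lod_sub`, `label`.
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "censored_series"))
  lod <- series_lod(series)
  out <- do.call(rbind, lapply(levels(series$time_point), function(tp) {
    sub <- series[series$time_point == tp, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    det <- sub$log10_cfu[!sub$censored]
    all_vals <- ifelse(sub$censored, lod, sub$log10_cfu)
    data.frame(
      time_point = tp, n = nrow(sub), n_detected = length(det),
      mean_detected = if (length(det)) mean(det) else NA_real_,
      sd_detected = if (length(det) > 1L) stats::sd(det) else NA_real_,
      mean_lod_sub = mean(all_vals),
      sd_lod_sub = if (length(all_vals) > 1L) stats::sd(all_vals) else NA_real_,
      label = if (length(det)) sprintf("%.2f", mean(det)) else "<LOD",
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# midranks of pooled values, plus the tie-correction sum T = sum(t^3 - t)
rank_with_ties <- function(values) {
  r <- rank(values, ties.method = "average")
  t_sizes <- table(values)
  list(ranks = r, tie_sum = sum(t_sizes^3 - t_sizes))
}

#' Kruskal-Wallis test with Dunn's post hoc and Bonferroni adjustment
#'
#' Censored observations enter as ties at the LOD (any sub-LOD value is
#' exchangeable for a rank test). The Kruskal-Wallis H uses the standard
#' tie correction; Dunn's z is computed for every group pair and p-values
#' are Bonferroni-adjusted over all pairs.
#'
#' @param groups named list: group label -> numeric Log10 values (censored
#'   values already carried at the LOD), or a list of
#'   [censored_series()] objects keyed by compartment.
#' @return object of class `group_test_result`: `kw_H`, `kw_df`, `kw_p`,
#'   `dunn` (data.frame: group1, group2, z, p_raw, p_adjusted),
#'   `adjustment`, `n_comparisons`.
#' @export
kruskal_dunn <- function(groups) {
  if (all(vapply(groups, inherits, NA, "censored_series")))
    groups <- lapply(groups, `[[`, "log10_cfu")
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    stop("group(s) with zero values: ",
         paste(names(groups)[sizes == 0L], collapse = ", "))
  if (any(sizes < 2L))
    stop("each group needs >= 2 values; too small: ",
         paste(names(groups)[sizes < 2L], collapse = ", "))
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), sizes)
  N <- length(pooled)
  rk <- rank_with_ties(pooled)
  rbar <- tapply(rk$ranks, factor(g, levels = names(groups)), mean)
  n_i <- sizes[names(groups)]
  H <- (12 / (N * (N + 1))) * sum(n_i * rbar^2) - 3 * (N + 1)
  tie_corr <- 1 - rk$tie_sum / (N^3 - N)
  if (tie_corr > 0) H <- H / tie_corr
  H <- max(H, 0)
  df <- length(groups) - 1L
  kw_p <- stats::pchisq(H, df, lower.tail = FALSE)

  pairs <- utils::combn(names(groups), 2L)
  sigma2_base <- N * (N + 1) / 12 - rk$tie_sum / (12 * (N - 1))
  n_comp <- ncol(pairs)
  dunn <- do.call(rbind, lapply(seq_len(n_comp), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    se <- sqrt(sigma2_base * (1 / n_i[[g1]] + 1 / n_i[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = g1, group2 = g2, z = z, p_raw = p_raw,
               p_adjusted = min(1, p_raw * n_comp),
               stringsAsFactors = FALSE)
  }))
  rownames(dunn) <- NULL
  structure(list(groups = names(groups), n = as.integer(n_i),
                 kw_H = H, kw_df = df, kw_p = kw_p, dunn = dunn,
                 adjustment = "bonferroni", n_comparisons = n_comp),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g (df = %d), p = %.4g\n",
              x$kw_H, x$kw_df, x$kw_p))
  cat("Dunn post hoc (Bonferroni over", x$n_comparisons, "pairs):\n")
  print(x$dunn, digits = 4)
  invisible(x)
}

#' Occupancy / bimodality summary of a censored series
#'
#' Classifies time-point means (over detected values) into three occupancy
#' states: below the LOD (all replicates censored), "high" (within
#' `high_margin` Log10 units of the series maximum), or intermediate. The
#' series is flagged bimodal when both extreme states are occupied and the
#' intermediate fraction does not exceed `intermediate_threshold`.
#'
#' @param series a [censored_series()] with >= 2 time points.
#' @param high_margin Log10 window below the maximum counted as "high".
#' @param intermediate_threshold maximal intermediate fraction compatible
#'   with the bimodal flag.
#' @return list with the three fractions, per-time-point states, and
#'   `bimodal`.
#' @export
occupancy_bimodality <- function(series, high_margin = 1.0,
                                 intermediate_threshold = 0.2) {
  stopifnot(inherits(series, "censored_series"))
  s <- summarize_series(series)
  if (nrow(s) < 2L) stop("need >= 2 time points")
  detected_means <- s$mean_detected[s$n_detected > 0L]
  peak <- if (length(detected_means)) max(detected_means) else NA_real_
  state <- ifelse(s$n_detected == 0L, "below_lod",
                  ifelse(s$mean_detected >= peak - high_margin,
                         "high", "intermediate"))
  frac <- function(x) mean(state == x)
  out <- list(fraction_below_lod = frac("below_lod"),
              fraction_high = frac("high"),
              fraction_intermediate = frac("intermediate"),
              states = stats::setNames(state, s$time_point),
              high_margin = high_margin,
              intermediate_threshold = intermediate_threshold)
  out$bimodal <- out$fraction_below_lod > 0 && out$fraction_high > 0 &&
    out$fraction_intermediate <= intermediate_threshold
  out
}

#' Signed peak lag between two compartments
#'
#' Positions of the abundance peaks (argmax of time-point means over
#' detected values) are compared on the shared sampling points. Positive
#' lag means the host compartment leads (peaks earlier than) the water
#' compartment; ties are broken toward the earliest peak.
#'
#' @param host,water [censored_series()] objects sharing >= 3 time points.
#' @return list with `lag` (integer, in shared sampling points),
#'   `host_peak`, `water_peak`, `shared_time_points`.
#' @export
peak_lag <- function(host, water) {
  stopifnot(inherits(host, "censored_series"),
            inherits(water, "censored_series"))
  shared <- intersect(levels(host$time_point), levels(water$time_point))
  if (length(shared) < 3L)
    stop("series share fewer than 3 time points (",
         length(shared), ")")
  means_on <- function(series) {
    s <- summarize_series(series)
    s <- s[match(shared, s$time_point), , drop = FALSE]
    ifelse(s$n_detected > 0L, s$mean_detected, -Inf)
  }
  mh <- means_on(host); mw <- means_on(water)
  if (all(!is.finite(mh))) stop("host series all-censored on shared points")
  if (all(!is.finite(mw))) stop("water series all-censored on shared points")
  ih <- which.max(mh)  # earliest index on ties
  iw <- which.max(mw)
  list(lag = as.integer(iw - ih),
       host_peak = shared[ih], water_peak = shared[iw],
       shared_time_points = shared)
}
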