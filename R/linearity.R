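#' Select spike-species genes quantified well enough to fit
#'
#' A gene's dose-response can only be assessed where it is reliably
#' detected, so genes are filtered on their count in the reference
#' library — the one with the highest spike fraction, where every spike
#' gene is at its most abundant.  The threshold is inclusive ("at least"
#' `min_count` fragments).
#'
#' @param x a [count_table] with `spike_fraction` metadata.
#' @param min_count minimum count in the highest-fraction library
#'   (default 20).
#' @return Character vector of retained gene identifiers.
#' @export
filter_spike_genes <- function(x, min_count = 20) {
  stopifnot(inherits(x, "count_table"))
  q <- x$libraries$spike_fraction
  if (is.null(q) || all(q == 0))
    stop("no library with a positive spike fraction")
  ref <- which.max(q)
  spike <- x$species == "spike"
  if (!any(spike)) {
    warning("no spike-species genes in table")
    return(character(0))
  }
  keep <- spike & x$counts[, ref] >= min_count
  rownames(x$counts)[keep]
}

#' Fit one gene's linear dose response
#'
#' Ordinary least squares of normalized abundance against the known spike
#' fraction, plus the Pearson correlation of the two.  For an ideal
#' protocol the expected slope is 1 and intercept 0 (see
#' [normalize_abundance()]); the correlation measures how tightly the
#' response follows any line.
#'
#' @param q spike fractions (at least 3 distinct values required for a
#'   correlation with residual degrees of freedom).
#' @param a_hat normalized abundances, same length as `q`.
#' @param gene optional gene identifier carried into the result.
#' @param ref_count optional raw count in the highest-fraction library.
#' @return One-row data frame: `gene`, `slope`, `intercept`, `r`,
#'   `n_points`, `ref_count`.  `r` is `NA` when `a_hat` has zero
#'   variance (flat response).
#' @examples
#' fit_gene(c(0, .05, .1, .2), c(0, .05, .1, .2))  # slope 1, intercept 0
#' @export
fit_gene <- function(q, a_hat, gene = NA_character_, ref_count = NA_real_) {
  q <- as.numeric(q); a_hat <- as.numeric(a_hat)
  if (length(q) != length(a_hat)) stop("q and a_hat differ in length")
  if (length(q) < 3) stop("at least 3 points are required")
  if (any(is.na(q)) || any(is.na(a_hat))) stop("missing values in input")
  if (stats::var(q) == 0) stop("q is constant: slope undefined")
  f <- fit_genes_matrix(q, matrix(a_hat, nrow = 1))
  data.frame(gene = gene, slope = f$slope, intercept = f$intercept,
             r = f$r, n_points = length(q), ref_count = ref_count,
             stringsAsFactors = FALSE)
}

# Closed-form OLS + Pearson r for every row of a_hat against q at once.
fit_genes_matrix <- function(q, a_hat) {
  qc <- q - mean(q)
  sxx <- sum(qc^2)
  sxy <- as.vector(a_hat %*% qc)
  slope <- sxy / sxx
  intercept <- rowMeans(a_hat) - slope * mean(q)
  syy <- rowSums((a_hat - rowMeans(a_hat))^2)
  r <- ifelse(syy > 0, sxy / sqrt(sxx * syy), NA_real_)
  list(slope = slope, intercept = intercept, r = r)
}

#' Fit per-gene spike-in linearity for each protocol
#'
#' The package's central estimator.  For each protocol in the design it
#' (i) rescales every gene onto the spike-fraction axis with
#' [normalize_abundance()], (ii) keeps spike-species genes with at least
#' `min_count` fragments in the highest-fraction library, and (iii) fits
#' an independent least-squares line and Pearson correlation per gene
#' ([fit_gene()]).  Libraries should be at equal depth first (see
#' [subsample_counts()]) so that counts are comparable across mixture
#' levels.
#'
#' @param x a [count_table] whose library metadata carries `protocol` and
#'   `spike_fraction`.
#' @param min_count reference-library count filter (default 20).
#' @param protocols protocols to fit (default: all in the design).
#' @return An object of class `spikelin`: list with `fits` (data frame of
#'   per-gene `protocol`, `gene`, `slope`, `intercept`, `r`, `n_points`,
#'   `ref_count`), `normalized` (one `normalized_table` per protocol),
#'   `data`, `min_count` and `call`.  Use [summary.spikelin()] for
#'   per-protocol slope/intercept/correlation summaries.
#' @seealso [summarize_protocol()], [compare_protocols()],
#'   [decompose_noise()], [simulate.spikelin()]
#' @export
spikelin <- function(x, min_count = 20, protocols = NULL) {
  stopifnot(inherits(x, "count_table"))
  meta <- x$libraries
  if (is.null(meta$protocol)) meta$protocol <- "all"
  if (is.null(meta$spike_fraction))
    stop("library metadata lacks spike_fraction")
  protocols <- protocols %||% unique(meta$protocol)
  fits <- list(); normalized <- list()
  for (p in protocols) {
    j <- which(meta$protocol == p)
    if (length(j) < 3) stop("protocol ", p, " has fewer than 3 libraries")
    q <- meta$spike_fraction[j]
    if (stats::var(q) == 0) stop("protocol ", p, " has constant spike fraction")
    sub <- count_table(x$counts[, j, drop = FALSE], species = x$species,
                       libraries = meta[j, , drop = FALSE],
                       specials = x$specials[, j, drop = FALSE])
    keep <- filter_spike_genes(sub, min_count = min_count)
    norm <- normalize_abundance(sub, q = q)
    normalized[[p]] <- norm
    keep <- setdiff(keep, rownames(norm$abundance)[norm$excluded])
    if (length(keep) == 0) {
      warning("protocol ", p, ": no genes pass the filter")
      next
    }
    a <- norm$abundance[keep, , drop = FALSE]
    f <- fit_genes_matrix(q, a)
    ref <- which.max(q)
    fits[[p]] <- data.frame(
      protocol = p, gene = keep, slope = f$slope, intercept = f$intercept,
      r = f$r, n_points = length(q),
      ref_count = sub$counts[keep, ref],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  fits_df <- if (length(fits)) do.call(rbind, fits) else NULL
  rownames(fits_df) <- NULL
  structure(
    list(fits = fits_df, normalized = normalized, data = x,
         min_count = min_count, call = match.call()),
    class = "spikelin"
  )
}

#' @export
print.spikelin <- function(x, ...) {
  cat("Spike-in linearity fits\n")
  if (is.null(x$fits) || nrow(x$fits) == 0) {
    cat("  (no genes passed the filter)\n")
    return(invisible(x))
  }
  tab <- table(x$fits$protocol)
  for (p in names(tab)) {
    s <- x$fits[x$fits$protocol == p, ]
    cat(sprintf("  %-12s %5d genes  mean slope %.3f  mean r %.3f\n",
                p, nrow(s), mean(s$slope), mean(s$r, na.rm = TRUE)))
  }
  cat("  filter: >=", x$min_count, "fragments in the highest-fraction library\n")
  invisible(x)
}

#' Summarize one protocol's per-gene fits
#'
#' Means and sample (n-1) standard deviations of slope, intercept and
#' Pearson r; one-sample t tests of the slopes against 1 and the
#' intercepts against 0 (the values an ideal linear protocol attains);
#' and the interquartile range of the slopes (quartiles by linear
#' interpolation), a robust width measure used to compare protocols with
#' the counting-noise null.
#'
#' @param fits data frame of per-gene fits (as in `spikelin()$fits`),
#'   needing at least 2 rows.
#' @param protocol label carried into the result (default: taken from
#'   `fits`).
#' @return One-row data frame with `protocol`, `n_genes`, `mean_slope`,
#'   `sd_slope`, `mean_intercept`, `sd_intercept`, `mean_r`, `sd_r`,
#'   `n_r_undefined`, `t_slope_vs_1`, `p_slope`, `t_intercept_vs_0`,
#'   `p_intercept`, `iqr_slope`.  t statistics are `NA` when the spread
#'   is zero (test degenerate).
#' @export
summarize_protocol <- function(fits, protocol = NULL) {
  fits <- as.data.frame(fits)
  if (nrow(fits) < 2) stop("at least 2 per-gene fits are required")
  protocol <- protocol %||% fits$protocol[1] %||% NA_character_
  r_ok <- fits$r[!is.na(fits$r)]
  one_sample_t <- function(v, mu) {
    if (sdev(v) == 0 || is.na(sdev(v)))
      return(c(NA_real_, NA_real_))
    tt <- stats::t.test(v, mu = mu)
    c(unname(tt$statistic), tt$p.value)
  }
  ts <- one_sample_t(fits$slope, 1)
  ti <- one_sample_t(fits$intercept, 0)
  data.frame(
    protocol = protocol, n_genes = nrow(fits),
    mean_slope = mean(fits$slope), sd_slope = sdev(fits$slope),
    mean_intercept = mean(fits$intercept), sd_intercept = sdev(fits$intercept),
    mean_r = if (length(r_ok)) mean(r_ok) else NA_real_,
    sd_r = if (length(r_ok) > 1) stats::sd(r_ok) else NA_real_,
    n_r_undefined = sum(is.na(fits$r)),
    t_slope_vs_1 = ts[1], p_slope = ts[2],
    t_intercept_vs_0 = ti[1], p_intercept = ti[2],
    iqr_slope = unname(diff(stats::quantile(fits$slope, c(.25, .75),
                                            type = 7))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
summary.spikelin <- function(object, ...) {
  if (is.null(object$fits) || nrow(object$fits) == 0)
    stop("no fits to summarize")
  out <- do.call(rbind, lapply(split(object$fits, object$fits$protocol),
                               summarize_protocol))
  rownames(out) <- NULL
  class(out) <- c("summary.spikelin", "data.frame")
  out
}

#' @export
print.summary.spikelin <- function(x, digits = 3, ...) {
  cat("Per-protocol distribution of per-gene fit parameters\n")
  cat("(ideal linear response: slope 1, intercept 0, r 1)\n\n")
  df <- as.data.frame(x)
  show <- data.frame(
    protocol = df$protocol, n = df$n_genes,
    slope = sprintf("%.3g ± %.3g", df$mean_slope, df$sd_slope),
    intercept = sprintf("%.3g ± %.3g", df$mean_intercept,
                        df$sd_intercept),
    r = sprintf("%.3g ± %.3g", df$mean_r, df$sd_r),
    iqr_slope = signif(df$iqr_slope, digits)
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
coef.spikelin <- function(object, ...) {
  f <- object$fits
  if (is.null(f)) return(NULL)
  m <- cbind(slope = f$slope, intercept = f$intercept)
  rownames(m) <- if (length(unique(f$protocol)) > 1)
    paste(f$protocol, f$gene, sep = ":") else f$gene
  m
}

#' @export
predict.spikelin <- function(object, q = NULL, protocol = NULL, ...) {
  f <- object$fits
  if (!is.null(protocol)) f <- f[f$protocol %in% protocol, ]
  if (is.null(q)) q <- sort(unique(object$data$libraries$spike_fraction))
  out <- outer(f$slope, q) + f$intercept
  dimnames(out) <- list(f$gene, paste0("q=", q))
  out
}

#' @export
residuals.spikelin <- function(object, protocol = NULL, ...) {
  prots <- protocol %||% names(object$normalized)
  res <- lapply(prots, function(p) {
    f <- object$fits[object$fits$protocol == p, ]
    norm <- object$normalized[[p]]
    a <- norm$abundance[f$gene, , drop = FALSE]
    a - (outer(f$slope, norm$q) + f$intercept)
  })
  names(res) <- prots
  if (length(res) == 1L) res[[1]] else res
}

#' Histograms of per-gene fit parameters
#'
#' One row of panels per protocol: slopes (reference line at 1),
#' intercepts (reference at 0) and Pearson correlations.
#'
#' @param x a `spikelin` object.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.spikelin <- function(x, ...) {
  prots <- unique(x$fits$protocol)
  op <- graphics::par(mfrow = c(length(prots), 3),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in prots) {
    f <- x$fits[x$fits$protocol == p, ]
    graphics::hist(f$slope, main = paste(p, "slopes"), xlab = "slope", ...)
    graphics::abline(v = 1, col = 2, lty = 2)
    graphics::hist(f$intercept, main = paste(p, "intercepts"),
                   xlab = "intercept", ...)
    graphics::abline(v = 0, col = 2, lty = 2)
    graphics::hist(f$r, main = paste(p, "correlations"), xlab = "Pearson r",
                   ...)
  }
  invisible(x)
}

#' Compare per-gene correlation between two protocols
#'
#' Welch two-sample t test on the per-gene Pearson correlation
#' coefficients of two sets of fits, asking whether one protocol tracks
#' the dose linearly more faithfully than the other.
#'
#' @param s1,s2 data frames of per-gene fits with an `r` column (rows with
#'   undefined r are dropped).
#' @return List with `t`, `p`, `df`, `n1`, `n2`, `mean_r1`, `mean_r2` and
#'   `degenerate` (TRUE when both groups have zero variance, where the t
#'   statistic is undefined unless the means agree exactly).
#' @export
compare_protocols <- function(s1, s2) {
  r1 <- as.data.frame(s1)$r; r2 <- as.data.frame(s2)$r
  r1 <- r1[!is.na(r1)]; r2 <- r2[!is.na(r2)]
  if (length(r1) == 0 || length(r2) == 0)
    stop("both protocols need at least one fit with defined r")
  v1 <- stats::var(r1); v2 <- stats::var(r2)
  if (isTRUE(v1 == 0) && isTRUE(v2 == 0)) {
    equal <- isTRUE(all.equal(mean(r1), mean(r2)))
    return(list(t = if (equal) 0 else NA_real_,
                p = if (equal) 1 else NA_real_,
                df = NA_real_, n1 = length(r1), n2 = length(r2),
                mean_r1 = mean(r1), mean_r2 = mean(r2), degenerate = TRUE))
  }
  tt <- stats::t.test(r1, r2)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n1 = length(r1), n2 = length(r2),
       mean_r1 = mean(r1), mean_r2 = mean(r2), degenerate = FALSE)
}
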