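#' Configure the counting-noise null simulation
#'
#' The null model of an ideal protocol: every library is a single
#' multinomial draw over genes, so the only source of variation is the
#' finite number of reads ("counting noise").  Base probabilities
#' describe the library with the highest spike fraction; lower mixture
#' levels are derived from them with [build_level_probs()].
#'
#' @param base_probs per-gene probability vector for the reference
#'   (highest-fraction) library; must be non-negative and sum to 1.
#' @param species per-gene `"spike"`/`"background"` labels.
#' @param levels spike fractions to simulate; the maximum is the level
#'   the base probabilities represent.
#' @param depth reads drawn per library.
#' @param n_reps replicate experiments for [run_ensemble()].
#' @param seed integer seed.
#' @param min_count reference-library filter used in the ensemble
#'   pipeline (default 20).
#' @return A `sim_config` list.
#' @export
sim_config <- function(base_probs, species,
                       levels = c(0, 0.05, 0.10, 0.20),
                       depth = 2.5e6, n_reps = 1000, seed = 1,
                       min_count = 20) {
  nm <- names(base_probs)
  base_probs <- as.numeric(base_probs)
  names(base_probs) <- nm
  if (any(base_probs < 0)) stop("base_probs must be non-negative")
  if (abs(sum(base_probs) - 1) > 1e-12)
    stop("base_probs must sum to 1")
  if (length(species) != length(base_probs))
    stop("species must match base_probs in length")
  if (max(levels) <= 0) stop("maximum level must be positive")
  if (any(levels < 0) || any(levels > max(levels) + 1e-15))
    stop("levels must lie in [0, max level]")
  if (depth < 0 || depth != round(depth)) stop("depth must be a non-negative integer")
  if (n_reps < 1) stop("n_reps must be >= 1")
  structure(list(base_probs = base_probs, species = as.character(species),
                 levels = as.numeric(levels), depth = depth,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 min_count = min_count),
            class = "sim_config")
}

#' Base probabilities from a reference library
#'
#' Reconstructs the null model's gene probabilities from observed data:
#' the count vector of the highest-spike-fraction library, normalized to
#' sum to 1.  Accepts any HTSeq-dialect count table, so a real reference
#' library can seed the simulation when data are available.
#'
#' @param x a [count_table].
#' @param protocol restrict to one protocol's libraries (optional).
#' @return List with `probs` and `species`, ready for [sim_config()].
#' @export
base_probs_from_reference <- function(x, protocol = NULL) {
  stopifnot(inherits(x, "count_table"))
  meta <- x$libraries
  j <- seq_len(nrow(meta))
  if (!is.null(protocol)) j <- which(meta$protocol == protocol)
  if (length(j) == 0) stop("no libraries for protocol ", protocol)
  q <- meta$spike_fraction[j]
  if (is.null(q) || all(q == 0)) stop("no library with positive spike fraction")
  ref <- j[which.max(q)]
  counts <- x$counts[, ref]
  if (sum(counts) == 0) stop("reference library has zero depth")
  list(probs = counts / sum(counts), species = x$species)
}

#' Derive a mixture level's gene probabilities
#'
#' Emulates diluting the spike species: spike-gene probabilities are
#' scaled by `level / max_level`, and the probability mass freed by the
#' dilution is assigned evenly — the same absolute increment to every
#' background gene — so the vector still sums to 1.
#'
#' @param base_probs reference-library probabilities (at `max_level`).
#' @param species per-gene `"spike"`/`"background"` labels.
#' @param level spike fraction to emulate, in `[0, max_level]`.
#' @param max_level spike fraction the base probabilities represent.
#' @return Probability vector of the same length.
#' @examples
#' p <- c(0.1, 0.1, 0.4, 0.4)
#' s <- c("spike", "spike", "background", "background")
#' build_level_probs(p, s, level = 0.1, max_level = 0.2)
#' # spike halved to 0.05 each, background up to 0.45 each
#' @export
build_level_probs <- function(base_probs, species, level, max_level) {
  if (level < 0 || level > max_level)
    stop("level must lie in [0, max_level]")
  spike <- species == "spike"
  p <- as.numeric(base_probs)
  scaled <- p
  scaled[spike] <- p[spike] * (level / max_level)
  freed <- sum(p[spike]) - sum(scaled[spike])
  n_bg <- sum(!spike)
  if (freed > 0 && n_bg == 0)
    stop("cannot redistribute freed mass: no background genes")
  if (n_bg > 0) scaled[!spike] <- scaled[!spike] + freed / n_bg
  scaled
}

#' Simulate one experiment under pure counting noise
#'
#' One multinomial draw per mixture level at the configured depth: the
#' best any protocol could possibly do, with no amplification or
#' preparation bias of any kind.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` (optional).
#' @return A [count_table] with one library per level, protocol label
#'   `"ideal"`.
#' @export
simulate_counts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth == 0) warning("zero depth: all counts are zero")
  n <- length(config$base_probs)
  genes <- names(config$base_probs) %||%
    paste0(ifelse(config$species == "spike", "spike_g", "bg_g"), seq_len(n))
  max_level <- max(config$levels)
  probs <- vapply(config$levels, function(l)
    build_level_probs(config$base_probs, config$species, l, max_level),
    numeric(n))
  counts <- matrix(0L, n, length(config$levels))
  with_seed(seed %||% config$seed, {
    for (j in seq_along(config$levels)) {
      counts[, j] <- if (config$depth > 0)
        as.integer(stats::rmultinom(1, config$depth, probs[, j]))
      else 0L
    }
  })
  dimnames(counts) <- list(genes,
                           sprintf("sim_q%03.0f", 1000 * config$levels))
  count_table(counts, species = config$species,
              libraries = data.frame(
                library_id = colnames(counts), protocol = "ideal",
                spike_fraction = config$levels,
                preamp_id = "none", stringsAsFactors = FALSE))
}

#' Replicate the counting-noise null and score each replicate
#'
#' Runs the full analysis pipeline — normalization onto the fraction
#' axis, the reference-library count filter, per-gene least-squares fits
#' and the protocol summary — on `n_reps` independently simulated
#' experiments, giving null distributions of the quality metrics (mean
#' slope, mean intercept, mean Pearson r, slope IQR).  Observed metrics,
#' if supplied, are placed on those distributions as the percentage of
#' replicates strictly exceeding the observed value.
#'
#' @param config a [sim_config()].
#' @param observed optional named list/vector of observed metrics among
#'   `mean_r`, `iqr_slope`, `mean_slope`, `mean_intercept`.
#' @return Object of class `sim_ensemble`: `metrics` (data frame, one row
#'   per successful replicate), `ranks` (percent of replicates strictly
#'   greater than each observed metric), `n_failed`, `config`.
#' @export
run_ensemble <- function(config, observed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rows <- vector("list", config$n_reps)
  n_failed <- 0L
  for (k in seq_len(config$n_reps)) {
    rep_seed <- derive_seed(config$seed, paste0("rep", k))
    res <- tryCatch({
      tab <- simulate_counts(config, seed = rep_seed)
      fit <- spikelin(tab, min_count = config$min_count)
      s <- summarize_protocol(fit$fits)
      data.frame(rep = k, n_genes = s$n_genes, mean_slope = s$mean_slope,
                 mean_intercept = s$mean_intercept, mean_r = s$mean_r,
                 iqr_slope = s$iqr_slope, stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[k]] <- res
  }
  metrics <- do.call(rbind, rows)
  ranks <- NULL
  if (!is.null(observed) && !is.null(metrics)) {
    obs <- unlist(observed)
    ranks <- vapply(names(obs), function(m) {
      if (!m %in% names(metrics)) return(NA_real_)
      100 * sum(metrics[[m]] > obs[[m]]) / nrow(metrics)
    }, numeric(1))
  }
  structure(list(metrics = metrics, ranks = ranks, n_failed = n_failed,
                 config = config),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat("Counting-noise null ensemble:",
      if (is.null(x$metrics)) 0 else nrow(x$metrics),
      "replicates (", x$n_failed, "failed )\n")
  if (!is.null(x$metrics)) {
    for (m in c("mean_slope", "mean_intercept", "mean_r", "iqr_slope")) {
      cat(sprintf("  %-14s %.4f ± %.4f\n", m, mean(x$metrics[[m]]),
                  stats::sd(x$metrics[[m]])))
    }
  }
  if (!is.null(x$ranks)) {
    cat("  percent of replicates above observed:\n")
    for (m in names(x$ranks))
      cat(sprintf("    %-14s %.1f%%\n", m, x$ranks[[m]]))
  }
  invisible(x)
}

#' Write per-replicate ensemble metrics as TSV
#'
#' @param x a `sim_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(x, path) {
  stopifnot(inherits(x, "sim_ensemble"))
  utils::write.table(x$metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate counting-noise replicates of a fitted experiment
#'
#' `simulate()` on a [spikelin] fit draws ideal-protocol replicates of
#' the observed experiment: base probabilities are rebuilt from the
#' fitted data's highest-fraction library
#' ([base_probs_from_reference()]) and each replicate is a fresh
#' multinomial draw per mixture level at the observed (or given) depth.
#'
#' @param object a `spikelin` fit.
#' @param nsim number of replicate count tables.
#' @param seed integer seed.
#' @param protocol which protocol's libraries to emulate (default: the
#'   first fitted).
#' @param depth reads per simulated library (default: the protocol's
#'   median library depth).
#' @return List of `nsim` [count_table] objects.
#' @export
simulate.spikelin <- function(object, nsim = 1, seed = NULL,
                              protocol = NULL, depth = NULL, ...) {
  protocol <- protocol %||% unique(object$fits$protocol)[1]
  base <- base_probs_from_reference(object$data, protocol = protocol)
  j <- object$data$libraries$protocol == protocol
  levels <- object$data$libraries$spike_fraction[j]
  depth <- depth %||% round(stats::median(library_depth(object$data)[j]))
  seed <- seed %||% 1L
  cfg <- sim_config(base$probs, base$species, levels = levels,
                    depth = depth, n_reps = nsim, seed = seed,
                    min_count = object$min_count)
  lapply(seq_len(nsim), function(k)
    simulate_counts(cfg, seed = derive_seed(seed, paste0("rep", k))))
}
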