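#' Configure the synthetic two-species experiment generator
#'
#' Describes a virtual mixture experiment: a background-species
#' transcriptome with a spike species mixed in at known fractions, read
#' out by multinomial sequencing.  Gene expression is log-uniform over
#' `dynamic_range` so the spike genes densely cover the ~1e5-fold span
#' typical of RNA abundances.  An optional per-batch lognormal bias
#' emulates pre-amplification: libraries generated under the same
#' `preamp_id` share one gene-by-level bias matrix, libraries from
#' different batches get independent ones.
#'
#' @param n_background_genes,n_spike_genes gene counts for the two
#'   species (defaults 6000 and 2000).
#' @param dynamic_range fold-range of expression (default 1e5).
#' @param levels spike fractions of the mixture series (default
#'   0, 1, 5, 10, 20 percent).
#' @param depth reads per library (default 2.5e6, the scale reached
#'   after subsampling all libraries to a common depth).
#' @param bias_sd standard deviation of the log gene-specific
#'   pre-amplification bias; 0 (default) is an ideal protocol.
#' @param overdispersion optional Dirichlet-multinomial concentration
#'   parameter; smaller values give more extra-multinomial noise.
#'   `NULL` (default) draws plain multinomials.
#' @param seed integer seed.  Sub-seeds for the expression profile, each
#'   pre-amplification batch, and the read draws are derived from it
#'   deterministically, so the components can be varied independently.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_background_genes = 6000,
                             n_spike_genes = 2000,
                             dynamic_range = 1e5,
                             levels = c(0, 0.01, 0.05, 0.10, 0.20),
                             depth = 2.5e6, bias_sd = 0,
                             overdispersion = NULL, seed = 1) {
  if (n_background_genes < 1 || n_spike_genes < 1)
    stop("both species need at least one gene")
  if (dynamic_range <= 1) stop("dynamic_range must exceed 1")
  if (max(levels) <= 0 || any(levels < 0) || max(levels) > 1)
    stop("levels must lie in [0, 1] with a positive maximum")
  if (depth < 0) stop("depth must be non-negative")
  if (bias_sd < 0) stop("bias_sd must be non-negative")
  if (!is.null(overdispersion) && overdispersion <= 0)
    stop("overdispersion concentration must be positive")
  structure(list(n_background_genes = as.integer(n_background_genes),
                 n_spike_genes = as.integer(n_spike_genes),
                 dynamic_range = dynamic_range,
                 levels = as.numeric(levels), depth = depth,
                 bias_sd = bias_sd, overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw a synthetic base expression profile
#'
#' Per-gene expression values are `dynamic_range^U(0,1)` (log-uniform,
#' heavy-tailed), then normalized so that spike-species genes carry
#' total probability mass equal to the highest mixture level and
#' background genes the rest — i.e. the profile describes the
#' highest-fraction reference library.
#'
#' @param config a [generator_config()].
#' @return List with `probs` (named, sums to 1) and `species`, directly
#'   usable with [sim_config()].
#' @export
make_expression_profile <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_bg <- config$n_background_genes
  n_sp <- config$n_spike_genes
  max_level <- max(config$levels)
  profile_seed <- derive_seed(config$seed, "profile")
  expr <- with_seed(profile_seed,
                    config$dynamic_range ^ stats::runif(n_bg + n_sp))
  species <- c(rep("background", n_bg), rep("spike", n_sp))
  probs <- numeric(n_bg + n_sp)
  probs[species == "background"] <-
    expr[species == "background"] / sum(expr[species == "background"]) *
    (1 - max_level)
  probs[species == "spike"] <-
    expr[species == "spike"] / sum(expr[species == "spike"]) * max_level
  names(probs) <- c(sprintf("bg_g%05d", seq_len(n_bg)),
                    sprintf("Dvir\\g%05d", seq_len(n_sp)))
  list(probs = probs, species = stats::setNames(species, names(probs)))
}

#' Generate one synthetic mixture experiment
#'
#' Builds level-specific probability vectors from the base profile (via
#' [build_level_probs()]), optionally applies a pre-amplification bias —
#' one lognormal(0, `bias_sd`) factor per gene and mixture level, drawn
#' once per `preamp_id` and shared by every run generated under that
#' batch label, then renormalized — and draws one multinomial (or
#' Dirichlet-multinomial when `overdispersion` is set) library per
#' level.  Two runs with the same `preamp_id` but different `run_seed`
#' model re-preparing libraries from the same pre-amplified cDNA pools;
#' different `preamp_id`s model independent pre-amplifications.
#'
#' With `bias_sd = 0` and no overdispersion the generator draws from
#' exactly the same model as [simulate_counts()].
#'
#' @param config a [generator_config()].
#' @param preamp_id label of the pre-amplification batch (default
#'   `"batchA"`).
#' @param run_seed seed for the read draws of this run (default:
#'   `config$seed`); the bias matrix depends only on `config$seed` and
#'   `preamp_id`.
#' @param protocol protocol label recorded in the metadata.
#' @return A [count_table] with one library per level.
#' @export
generate_experiment <- function(config, preamp_id = "batchA",
                                run_seed = NULL, protocol = "synthetic") {
  stopifnot(inherits(config, "generator_config"))
  base <- make_expression_profile(config)
  n <- length(base$probs)
  max_level <- max(config$levels)
  probs <- vapply(config$levels, function(l)
    build_level_probs(base$probs, base$species, l, max_level),
    numeric(n))
  if (config$bias_sd > 0) {
    bias_seed <- derive_seed(config$seed, paste0("preamp:", preamp_id))
    bias <- with_seed(bias_seed,
                      matrix(stats::rlnorm(n * length(config$levels),
                                           0, config$bias_sd),
                             n, length(config$levels)))
    probs <- probs * bias
    probs <- sweep(probs, 2, colSums(probs), "/")
  }
  counts <- matrix(0L, n, length(config$levels))
  with_seed(run_seed %||% config$seed, {
    for (j in seq_along(config$levels)) {
      p <- probs[, j]
      if (!is.null(config$overdispersion)) {
        g <- stats::rgamma(n, shape = config$overdispersion * p)
        p <- if (sum(g) > 0) g / sum(g) else p
      }
      counts[, j] <- if (config$depth > 0)
        as.integer(stats::rmultinom(1, config$depth, p)) else 0L
    }
  })
  lib_ids <- sprintf("%s_q%03.0f", preamp_id, 1000 * config$levels)
  dimnames(counts) <- list(names(base$probs), lib_ids)
  count_table(counts, species = base$species,
              libraries = data.frame(
                library_id = lib_ids, protocol = protocol,
                spike_fraction = config$levels, preamp_id = preamp_id,
                stringsAsFactors = FALSE))
}

#' Export an experiment as HTSeq-dialect files plus a design CSV
#'
#' Writes one two-column count file per library (with a zeroed
#' `__no_feature` counter when none is present) and a `design.csv`
#' linking `library_id`, `path`, `protocol`, `spike_fraction` and
#' `preamp_id`, ready for [read_experiment()].
#'
#' @param x a [count_table].
#' @param dir output directory (created if needed).
#' @return Path of the design CSV, invisibly.
#' @export
export_experiment <- function(x, dir) {
  stopifnot(inherits(x, "count_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- x
  if (nrow(out$specials) == 0) {
    out$specials <- matrix(0L, 1, ncol(out$counts),
                           dimnames = list("__no_feature",
                                           colnames(out$counts)))
  }
  paths <- character(ncol(out$counts))
  for (j in seq_len(ncol(out$counts))) {
    paths[j] <- paste0(colnames(out$counts)[j], ".counts.tsv")
    write_htseq_counts(out, file.path(dir, paths[j]), library = j)
  }
  design <- cbind(out$libraries[c("library_id")], path = paths,
                  out$libraries[setdiff(names(out$libraries), "library_id")])
  design_path <- file.path(dir, "design.csv")
  utils::write.csv(design, design_path, row.names = FALSE, quote = FALSE)
  invisible(design_path)
}
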