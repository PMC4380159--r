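#' Rescale per-gene abundance onto the spike-fraction axis
#'
#' For gene \eqn{i} with abundance \eqn{A_{ij}} in library \eqn{j} and
#' known spike fractions \eqn{Q_j}, the normalized abundance is
#' \deqn{\hat A_{ij} = A_{ij} \div \frac{\sum_j Q_j A_{ij}}{\sum_j Q_j^2}.}
#' The divisor is the least-squares no-intercept slope of \eqn{A} on
#' \eqn{Q}, so after normalization a perfectly responding gene satisfies
#' \eqn{\hat A_{ij} = Q_j} exactly: every gene is put on a common scale on
#' which linearity means slope 1 and intercept 0, regardless of its
#' absolute expression.  Genes whose weighted sum is zero (no reads in any
#' positive-fraction library) have no defined scale; they are flagged
#' `excluded` rather than silently dropped.
#'
#' @param x a [count_table] with `spike_fraction` in its library metadata,
#'   or a plain numeric matrix.
#' @param q spike fractions per library; taken from `x$libraries` when
#'   omitted.  At least one must be positive.
#' @return An object of class `normalized_table`: list with `abundance`
#'   (the \eqn{\hat A} matrix), `scale` (per-gene divisor \eqn{s_i}),
#'   `excluded` (logical per gene), `q`, `species`.
#' @examples
#' a <- matrix(5 * c(0, .05, .1, .2), 1, dimnames = list("g", NULL))
#' normalize_abundance(a, q = c(0, .05, .1, .2))$abundance  # equals q
#' @export
normalize_abundance <- function(x, q = NULL) {
  if (inherits(x, "count_table")) {
    a <- x$counts
    species <- x$species
    q <- q %||% x$libraries$spike_fraction
  } else {
    a <- as.matrix(x)
    species <- rep(NA_character_, nrow(a))
  }
  if (is.null(q)) stop("spike fractions q are required")
  q <- as.numeric(q)
  if (length(q) != ncol(a))
    stop("q must have one fraction per library")
  if (any(is.na(q)) || any(q < 0)) stop("q must be non-negative")
  if (all(q == 0))
    stop("all spike fractions are zero: normalization undefined")
  storage.mode(a) <- "double"
  scale <- as.vector(a %*% q) / sum(q^2)
  names(scale) <- rownames(a)
  excluded <- scale == 0
  ahat <- a / scale            # rows with scale 0 become NaN
  ahat[excluded, ] <- NA_real_
  structure(
    list(abundance = ahat, scale = scale, excluded = excluded, q = q,
         species = species),
    class = "normalized_table"
  )
}

#' @export
print.normalized_table <- function(x, ...) {
  cat("normalized_table:", nrow(x$abundance), "genes x",
      length(x$q), "libraries\n")
  cat("  spike fractions:", paste(x$q, collapse = ", "), "\n")
  cat("  excluded (zero scale):", sum(x$excluded), "genes\n")
  invisible(x)
}

#' Write normalized abundances as TSV
#'
#' One row per gene: identifier, per-gene scale, exclusion flag, then the
#' normalized abundance in each library.
#'
#' @param x a `normalized_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(x, path) {
  stopifnot(inherits(x, "normalized_table"))
  df <- data.frame(gene = rownames(x$abundance), scale = x$scale,
                   excluded = x$excluded, x$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
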