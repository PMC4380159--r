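#' Build a two-species count table
#'
#' The central data container of the package: an integer gene-by-library
#' count matrix together with a per-gene species label (`"spike"` for the
#' mixed-in species, `"background"` for the carrier species), per-library
#' metadata, and any HTSeq special counters (`__no_feature` and friends)
#' held aside from the genes proper.
#'
#' @param counts integer matrix, genes in rows, libraries in columns.
#'   Row names are gene identifiers, column names library identifiers.
#' @param species character vector, one of `"spike"`/`"background"` per
#'   gene, or `NULL` to derive labels from `spike_prefix`.
#' @param libraries data frame of library metadata with at least a
#'   `library_id` column, and optionally `protocol`, `spike_fraction`
#'   (known mixing fraction in `[0, 1]`) and `preamp_id` columns.
#' @param specials integer matrix of special counters (rows named
#'   `__no_feature` etc.), excluded from depth and all analyses.
#' @param spike_prefix gene-name prefix identifying spike-species genes
#'   when `species` is not given (default `"Dvir\\"`, the FlyBase
#'   two-genome convention for *D. virilis* genes).
#'
#' @return An object of class `count_table`.
#' @seealso [read_htseq_counts()], [subsample_counts()], [normalize_abundance()]
#' @export
count_table <- function(counts, species = NULL, libraries = NULL,
                        specials = NULL, spike_prefix = "Dvir\\") {
  counts <- as.matrix(counts)
  if (length(counts) > 0 && !is.numeric(counts))
    stop("counts must be numeric")
  storage <- counts
  if (length(storage) > 0) {
    if (any(is.na(storage))) stop("counts contain NA")
    if (any(storage < 0)) stop("counts must be non-negative")
    if (any(storage != round(storage))) stop("counts must be integers")
  }
  mode(storage) <- "integer"
  genes <- rownames(storage)
  if (nrow(storage) > 0 && is.null(genes))
    stop("counts must have gene identifiers as row names")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (is.null(species)) {
    species <- ifelse(startsWith(genes %||% character(), spike_prefix),
                      "spike", "background")
  }
  species <- as.character(species)
  if (length(species) != nrow(storage))
    stop("species must have one label per gene")
  if (nrow(storage) > 0 && !all(species %in% c("spike", "background")))
    stop("species labels must be 'spike' or 'background'")
  names(species) <- genes

  lib_ids <- colnames(storage)
  if (is.null(libraries)) {
    libraries <- data.frame(
      library_id = lib_ids %||% sprintf("lib%d", seq_len(ncol(storage))),
      stringsAsFactors = FALSE
    )
  }
  libraries <- as.data.frame(libraries, stringsAsFactors = FALSE)
  if (is.null(libraries$library_id)) stop("libraries must have library_id")
  if (nrow(libraries) != ncol(storage))
    stop("libraries metadata rows must match count columns")
  if (!is.null(lib_ids) && !identical(as.character(libraries$library_id),
                                      lib_ids))
    stop("library_id does not match count column names")
  colnames(storage) <- libraries$library_id
  if (!is.null(libraries$spike_fraction)) {
    q <- libraries$spike_fraction
    if (any(is.na(q)) || any(q < 0) || any(q > 1))
      stop("spike_fraction must lie in [0, 1]")
  }
  if (is.null(specials)) {
    specials <- matrix(integer(), nrow = 0, ncol = ncol(storage),
                       dimnames = list(NULL, colnames(storage)))
  }
  structure(
    list(counts = storage, species = species, libraries = libraries,
         specials = specials),
    class = "count_table"
  )
}

#' Per-library sequencing depth
#'
#' Column sums of the gene counts; special counters are excluded.
#'
#' @param x a [count_table].
#' @return Named numeric vector of depths, one per library.
#' @export
library_depth <- function(x) {
  stopifnot(inherits(x, "count_table"))
  colSums(x$counts)
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries\n")
  cat("  spike genes:", sum(x$species == "spike"),
      " background genes:", sum(x$species == "background"), "\n")
  if (ncol(x$counts) > 0) {
    d <- library_depth(x)
    cat("  depth range:", format(min(d), big.mark = ","), "-",
        format(max(d), big.mark = ","), "\n")
  }
  if (!is.null(x$libraries$protocol))
    cat("  protocols:", paste(unique(x$libraries$protocol), collapse = ", "),
        "\n")
  invisible(x)
}

#' Read one HTSeq-count output file
#'
#' Parses the two-column tab-separated dialect written by `htseq-count`:
#' `gene_id TAB count`, with trailing summary counters whose names start
#' with `__` (e.g. `__no_feature`).  Special counters are kept aside and
#' never contribute to library depth.
#'
#' @param path path to the count file.
#' @param spike_prefix gene-name prefix marking spike-species genes.
#' @param library_id identifier for the library; defaults to the file
#'   name without extension.
#' @return A single-library [count_table].
#' @examples
#' f <- tempfile()
#' writeLines(c("geneA\t5", "Dvir\\g1\t2", "__no_feature\t7"), f)
#' tab <- read_htseq_counts(f)
#' library_depth(tab)   # 7: the __no_feature counter is excluded
#' @export
read_htseq_counts <- function(path, spike_prefix = "Dvir\\",
                              library_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  library_id <- library_id %||%
    sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  genes <- character(n); vals <- numeric(n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed line ", i, " in ", path, ": expected 'gene<TAB>count'")
    v <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(v) || v != round(v) || v < 0)
      stop("invalid count on line ", i, " in ", path, ": '", parts[2],
           "' (must be a non-negative integer)")
    genes[i] <- parts[1]
    vals[i] <- v
  }
  special <- startsWith(genes, "__")
  if (anyDuplicated(genes[!special]))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(genes[!special][duplicated(genes[!special])]),
               collapse = ", "))
  cm <- matrix(as.integer(vals[!special]), ncol = 1,
               dimnames = list(genes[!special], library_id))
  sm <- matrix(as.integer(vals[special]), ncol = 1,
               dimnames = list(genes[special], library_id))
  count_table(cm, specials = sm, spike_prefix = spike_prefix)
}

#' Write a library to HTSeq-count format
#'
#' Inverse of [read_htseq_counts()]: genes first, then the special `__`
#' counters, one `gene TAB count` line each.
#'
#' @param x a [count_table].
#' @param path output path.
#' @param library library identifier or column index to write
#'   (default: first column).
#' @return `path`, invisibly.
#' @export
write_htseq_counts <- function(x, path, library = 1L) {
  stopifnot(inherits(x, "count_table"))
  j <- if (is.character(library)) match(library, colnames(x$counts)) else library
  if (is.na(j) || j < 1 || (ncol(x$counts) > 0 && j > ncol(x$counts)))
    stop("unknown library: ", library)
  lines <- character(0)
  if (nrow(x$counts) > 0)
    lines <- paste(rownames(x$counts), x$counts[, j], sep = "\t")
  if (nrow(x$specials) > 0)
    lines <- c(lines, paste(rownames(x$specials), x$specials[, j], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a full mixture experiment from a design table
#'
#' The design CSV has columns `library_id`, `path`, `protocol`,
#' `spike_fraction` and optionally `preamp_id`; each `path` points to one
#' HTSeq-count file.  All files must share the same gene universe.
#'
#' @param design_path path to the design CSV.
#' @param spike_prefix gene-name prefix marking spike-species genes.
#' @param base_dir directory against which relative `path` entries are
#'   resolved (default: the design file's directory).
#' @return A merged multi-library [count_table].
#' @export
read_experiment <- function(design_path, spike_prefix = "Dvir\\",
                            base_dir = dirname(design_path)) {
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  needed <- c("library_id", "path", "protocol", "spike_fraction")
  missing <- setdiff(needed, names(design))
  if (length(missing))
    stop("design table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(design) == 0) stop("design table is empty")
  tabs <- lapply(seq_len(nrow(design)), function(i) {
    p <- design$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, design$path[i])
    read_htseq_counts(p, spike_prefix = spike_prefix,
                      library_id = design$library_id[i])
  })
  genes <- rownames(tabs[[1]]$counts)
  for (t in tabs[-1]) {
    if (!identical(rownames(t$counts), genes))
      stop("count files do not share an identical gene universe")
  }
  cm <- do.call(cbind, lapply(tabs, function(t) t$counts))
  sp_names <- unique(unlist(lapply(tabs, function(t) rownames(t$specials))))
  sm <- matrix(0L, nrow = length(sp_names), ncol = length(tabs),
               dimnames = list(sp_names, design$library_id))
  for (j in seq_along(tabs)) {
    s <- tabs[[j]]$specials
    if (nrow(s) > 0) sm[rownames(s), j] <- s[, 1]
  }
  meta <- design[setdiff(names(design), "path")]
  if (is.null(meta$preamp_id)) meta$preamp_id <- meta$protocol
  count_table(cm, species = tabs[[1]]$species, libraries = meta,
              specials = sm)
}

#' Write the merged count matrix as TSV
#'
#' Genes in rows, libraries in columns, with a `gene` and a `species`
#' leading column.
#'
#' @param x a [count_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(gene = rownames(x$counts), species = x$species,
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subsample libraries to equal depth
#'
#' Draws each library's counts without replacement down to `target_depth`
#' reads (a multivariate hypergeometric draw on the count vector), the
#' in-silico equivalent of uniformly subsampling mapped reads before
#' counting.  Used to put libraries sequenced to different depths on an
#' equal footing before any cross-library comparison.
#'
#' @param x a [count_table].
#' @param target_depth reads to keep per library.  Default: the minimum
#'   depth across libraries.
#' @param seed integer seed for reproducibility.
#' @return A [count_table] whose columns all sum exactly to `target_depth`.
#' @examples
#' tab <- count_table(matrix(c(6L, 4L, 10L, 10L), 2,
#'                    dimnames = list(c("g1", "Dvir\\g2"), c("a", "b"))))
#' library_depth(subsample_counts(tab, 5, seed = 1))  # both 5
#' @export
subsample_counts <- function(x, target_depth = NULL, seed = NULL) {
  stopifnot(inherits(x, "count_table"))
  depths <- library_depth(x)
  target_depth <- target_depth %||% min(depths)
  if (target_depth < 0 || target_depth != round(target_depth))
    stop("target_depth must be a non-negative integer")
  short <- depths < target_depth
  if (any(short))
    stop("target_depth ", target_depth, " exceeds depth of: ",
         paste(names(depths)[short], collapse = ", "))
  out <- x
  with_seed(seed, {
    for (j in seq_len(ncol(x$counts))) {
      out$counts[, j] <- rmvhyper(x$counts[, j], as.integer(target_depth))
    }
  })
  out
}
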