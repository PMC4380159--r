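#' Molar yield of a sequencing library
#'
#' Converts a fluorometric mass concentration and a mean fragment size
#' into total library molarity:
#' \deqn{Y[\mathrm{fmol}] = C[\mathrm{ng/\mu L}] \cdot 10^{-9}
#'   \cdot V[\mathrm{\mu L}] \cdot 10^{15} \div 608.9[\mathrm{g/mol\,bp}]
#'   \div S[\mathrm{bp}],}
#' using 608.9 g/mol per base pair of double-stranded DNA.
#'
#' @param concentration mass concentration in ng/µL (e.g. a Qubit
#'   reading).
#' @param volume total volume in µL.
#' @param mean_size mean fragment size in bp (e.g. from a Bioanalyzer
#'   trace).
#' @return Yield in femtomoles.  Vectorized over all arguments.
#' @examples
#' molar_yield(1, 25, 400)
#' @export
molar_yield <- function(concentration, volume, mean_size) {
  if (any(mean_size <= 0)) stop("mean_size must be positive")
  if (any(concentration < 0) || any(volume < 0))
    stop("concentration and volume must be non-negative")
  concentration * 1e-9 * volume * 1e15 / 608.9 / mean_size
}

#' Equimolar pooling volumes
#'
#' Computes per-library volumes such that each library contributes the
#' same number of femtomoles to a pool of a given total volume: volumes
#' are proportional to the inverse of molar concentration
#' (yield / volume).
#'
#' @param libraries data frame with columns `library_id`,
#'   `concentration` (ng/µL), `volume` (µL) and `mean_size` (bp).
#' @param target_total_volume desired pool volume in µL.
#' @return The input data frame with added `yield_fmol`,
#'   `molar_conc_fmol_ul` and `pool_volume` columns; pool volumes sum to
#'   `target_total_volume` and contributed fmol are equal.
#' @export
equimolar_pool <- function(libraries, target_total_volume) {
  libraries <- as.data.frame(libraries)
  needed <- c("library_id", "concentration", "volume", "mean_size")
  missing <- setdiff(needed, names(libraries))
  if (length(missing))
    stop("libraries table lacks columns: ", paste(missing, collapse = ", "))
  if (target_total_volume <= 0) stop("target_total_volume must be positive")
  y <- molar_yield(libraries$concentration, libraries$volume,
                   libraries$mean_size)
  conc <- y / libraries$volume
  zero <- conc <= 0
  if (any(zero))
    stop("zero molar concentration for: ",
         paste(libraries$library_id[zero], collapse = ", "))
  v <- (1 / conc) / sum(1 / conc) * target_total_volume
  libraries$yield_fmol <- y
  libraries$molar_conc_fmol_ul <- conc
  libraries$pool_volume <- v
  libraries
}
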