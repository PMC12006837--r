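#' 35S incorporation rate of a labeled sample
#'
#' Mean of the triplicate scintillation counts divided by the protein
#' amount.
#'
#' @param cpm numeric vector of the triplicate CPM values, or a matrix with
#'   one row per sample and one column per replicate.
#' @param protein_mg protein amount(s) in mg (> 0).
#' @return CPM per mg protein (vector if \code{cpm} is a matrix).
#' @examples
#' incorporationRate(c(900, 1000, 1100), 0.5) # 2000
#' @export
incorporationRate <- function(cpm, protein_mg) {
  if (any(protein_mg <= 0)) stop("protein amount must be > 0")
  if (any(cpm < 0)) stop("CPM must be non-negative")
  m <- if (is.matrix(cpm)) rowMeans(cpm) else mean(cpm)
  unname(m / protein_mg)
}

#' Normalize incorporation rates within experimental batches
#'
#' Implements the inter-experiment correction chain: each sample's
#' incorporation rate (CPM per mg protein) is divided by the activity of its
#' labeling-mix aliquot (dose) and then expressed as percent of the mean
#' dose-corrected rate over all slices of the same batch, so each batch mean
#' is exactly 100. The two divisions commute, so their order is immaterial.
#'
#' @param samples data.frame with columns \code{cpm1..cpm3} (or a
#'   \code{rate} column), \code{protein_mg}, \code{dose_cpm} and
#'   \code{batch}; a \code{group} column is carried through if present.
#' @param anchor_group optional group name; if given, values are rescaled so
#'   that this group's mean (rather than the all-slice mean) is 100 within
#'   each batch.
#' @return The input data.frame with columns \code{rate} (CPM/mg) and
#'   \code{normalized_pct} appended.
#' @export
normalizeBatch <- function(samples, anchor_group = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("dose_cpm", "batch") %in% names(samples)))
  if (!"rate" %in% names(samples)) {
    cols <- grep("^cpm[0-9]+$", names(samples), value = TRUE)
    if (!length(cols) || !"protein_mg" %in% names(samples))
      stop("need either a 'rate' column or cpm1..3 + protein_mg")
    samples$rate <- incorporationRate(as.matrix(samples[cols]),
                                      samples$protein_mg)
  }
  val <- samples$rate / samples$dose_cpm
  out <- rep(NA_real_, nrow(samples))
  for (b in unique(samples$batch)) {
    ib <- samples$batch == b
    if (sum(ib) < 2L)
      warning("batch ", b, " has a single sample; normalization is degenerate")
    denom <- if (is.null(anchor_group)) mean(val[ib]) else {
      ig <- ib & samples$group == anchor_group
      if (!any(ig)) stop("anchor group absent from batch ", b)
      mean(val[ig])
    }
    out[ib] <- val[ib] / denom * 100
  }
  samples$normalized_pct <- out
  samples
}
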