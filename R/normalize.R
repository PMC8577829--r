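# Per-cell fluorescence normalization: fixed-tissue mode (reference-nucleus
# anchored percentages) and live-imaging mode (per-lineage max scaling).

#' Subtract per-cell background
#'
#' Background-corrected intensity `max(raw - background, 0)` per channel,
#' mirroring per-cell background subtraction of integrated densities.
#' Negative corrected values clip to zero so downstream fractions stay in
#' `[0, 1]`.
#'
#' @param cells raw measurement data frame with `raw_<channel>` and
#'   `background_<channel>` columns (channels `red` and `green`, optionally
#'   `blue`).
#' @return `cells` with corrected columns `red`, `green` (and `blue`) added.
#' @export
subtract_background <- function(cells) {
  channels <- c("red", "green", "blue")
  present <- channels[paste0("raw_", channels) %in% names(cells)]
  if (!all(c("red", "green") %in% present)) {
    stop("`cells` must contain raw_red and raw_green columns", call. = FALSE)
  }
  for (ch in present) {
    bg_col <- paste0("background_", ch)
    if (!bg_col %in% names(cells)) {
      stop(sprintf("missing background column `%s`", bg_col), call. = FALSE)
    }
    cells[[ch]] <- pmax(cells[[paste0("raw_", ch)]] - cells[[bg_col]], 0)
  }
  cells
}

.reference_mean <- function(values, ids, n_ref, decreasing) {
  ord <- order(values, ids, decreasing = c(decreasing, FALSE),
               method = "radix")
  mean(values[ord][seq_len(min(n_ref, length(values)))])
}

#' Fixed-tissue red normalization against reference nuclei
#'
#' Expresses background-corrected red intensity as a percentage anchored on
#' reference nuclei in the same tissue: the mean of the `n_ref` darkest
#' nuclei (among all nuclei) is set to 0% and the mean of the `n_ref`
#' brightest red-only nuclei (marker flag `red_only`, i.e. non-recombined
#' cells with an undiluted old-tag pool) to 100%.  Values below the dark
#' anchor clip to 0; values above 100 are kept.  With fewer than `n_ref`
#' nuclei in a reference set, all available (at least 2) are used with a
#' warning.  Ties are broken by `cell_id` for determinism.
#'
#' @param cells data frame with corrected `red` (see [subtract_background()]),
#'   `cell_id`, and logical `red_only` columns.
#' @param n_ref reference-set size (default 10).
#' @return `cells` with a `red_pct` column added.
#' @export
normalize_red_fixed <- function(cells, n_ref = 10) {
  if (!all(c("red", "cell_id", "red_only") %in% names(cells))) {
    stop("`cells` must contain red, cell_id and red_only columns",
         call. = FALSE)
  }
  ref <- cells[as.logical(cells$red_only), , drop = FALSE]
  if (nrow(ref) < 2L) {
    stop("need at least 2 red-only reference nuclei", call. = FALSE)
  }
  if (nrow(ref) < n_ref || nrow(cells) < n_ref) {
    warning(sprintf("fewer than %d reference nuclei; using all available",
                    n_ref))
  }
  dark <- .reference_mean(cells$red, cells$cell_id, n_ref, decreasing = FALSE)
  bright <- .reference_mean(ref$red, ref$cell_id, n_ref, decreasing = TRUE)
  if (bright <= dark) {
    stop("degenerate reference: brightest red-only mean does not exceed ",
         "darkest mean", call. = FALSE)
  }
  cells$red_pct <- pmax(100 * (cells$red - dark) / (bright - dark), 0)
  cells
}

#' Fixed-tissue green normalization by the brightest value
#'
#' Sets the brightest background-corrected green value in the tissue to 100%
#' and scales all cells accordingly.
#'
#' @param cells data frame with a corrected `green` column.
#' @return `cells` with a `green_pct` column added.
#' @export
normalize_green_fixed <- function(cells) {
  if (!"green" %in% names(cells)) {
    stop("`cells` must contain a corrected `green` column", call. = FALSE)
  }
  top <- max(cells$green)
  if (!is.finite(top) || top <= 0) {
    stop("degenerate tissue: no cell with green fluorescence above zero",
         call. = FALSE)
  }
  cells$green_pct <- 100 * cells$green / top
  cells
}

#' Green-to-total fraction per cell
#'
#' `R = green_pct / (green_pct + red_pct)` from the normalized percentages.
#' Cells with both percentages zero have an undefined fraction: they are
#' flagged (`undefined = TRUE`, `R = NA`) rather than dropped.
#'
#' @param cells data frame with `red_pct` and `green_pct` columns.
#' @return `cells` with columns `R` and `undefined` added.
#' @export
green_fraction <- function(cells) {
  if (!all(c("red_pct", "green_pct") %in% names(cells))) {
    stop("`cells` must contain red_pct and green_pct columns", call. = FALSE)
  }
  total <- cells$red_pct + cells$green_pct
  cells$undefined <- total == 0
  cells$R <- ifelse(cells$undefined, NA_real_, cells$green_pct / total)
  cells
}

#' Fixed-tissue normalization pipeline
#'
#' Chains [subtract_background()], [normalize_red_fixed()],
#' [normalize_green_fixed()] and [green_fraction()], reproducing the
#' fixed-tissue order of operations.
#'
#' @inheritParams normalize_red_fixed
#' @return the input with `red`, `green`, `red_pct`, `green_pct`, `R` and
#'   `undefined` columns added.
#' @export
normalize_fixed <- function(cells, n_ref = 10) {
  green_fraction(normalize_green_fixed(normalize_red_fixed(
    subtract_background(cells), n_ref = n_ref)))
}

#' Live-imaging normalization of lineage time series
#'
#' Scales each fluorescence channel by its maximum over the whole time series
#' of a lineage, so normalized values lie in `[0, 1]` and are invariant to
#' channel gain.  An all-zero channel is left as zeros with a warning.
#'
#' @param series data frame with `lineage_id`, `time` and channel columns.
#' @param channels channel columns to normalize (default `red`, `green`, and
#'   `blue` when present).
#' @return `series` with the channel columns replaced by normalized values.
#' @export
normalize_live <- function(series, channels = NULL) {
  if (nrow(series) == 0L) stop("empty lineage time series", call. = FALSE)
  if (!all(c("lineage_id", "time") %in% names(series))) {
    stop("`series` must contain lineage_id and time columns", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- intersect(c("red", "green", "blue"), names(series))
  }
  for (ch in channels) {
    top <- stats::ave(series[[ch]], series$lineage_id,
                      FUN = function(v) max(v))
    zero <- top == 0
    if (any(zero)) {
      warning(sprintf("channel `%s` is all zero in %d lineage(s); left as 0",
                      ch, length(unique(series$lineage_id[zero]))))
      top[zero] <- 1
    }
    series[[ch]] <- series[[ch]] / top
  }
  series
}
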