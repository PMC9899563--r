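# Canonical variable schema shared by every module.
#
# The 32 baseline variables are, in fixed order: the 21 depressive-symptom
# items (BDI-II, each 0-3), the 8 anxiety subscale totals from the CIS-R
# (each 0-4), and three auxiliary totals (social support, life events,
# alcohol use).  Follow-up severity is a 0-63 total; remission is defined
# as a follow-up total <= 10.

#' Baseline variable labels
#'
#' Label vectors for the fixed 32-variable baseline schema used throughout
#' the package: 21 BDI-II depressive-symptom items, 8 CIS-R anxiety subscale
#' totals, and 3 auxiliary totals (social support, life events, alcohol use).
#'
#' @return Character vector of labels, in the canonical column order.
#' @export
bdi_item_labels <- function() sprintf("bdi_%02d", 1:21)

#' @rdname bdi_item_labels
#' @export
anx_subscale_labels <- function() {
  paste0("anx_", c("ga", "worry", "comp", "obs", "phobic",
                   "health", "somatic", "panic"))
}

#' @rdname bdi_item_labels
#' @export
aux_total_labels <- function() c("social_support", "life_events", "alcohol")

#' @rdname bdi_item_labels
#' @export
baseline_labels <- function() {
  c(bdi_item_labels(), anx_subscale_labels(), aux_total_labels())
}

# Remission threshold on the follow-up total.
REMISSION_CUTOFF <- 10

# Valid integer range per baseline variable (used when rounding imputations).
variable_ranges <- function() {
  labs <- baseline_labels()
  lo <- stats::setNames(rep(0L, length(labs)), labs)
  hi <- stats::setNames(c(rep(3L, 21), rep(4L, 8), 21L, 12L, 20L), labs)
  list(lower = lo, upper = hi)
}

# Instrument block of each baseline variable: weights are min-max rescaled
# within blocks so that one instrument's scale does not dominate another's.
variable_blocks <- function() {
  stats::setNames(
    rep(c("bdi", "anx", "aux"), c(21L, 8L, 3L)),
    baseline_labels()
  )
}

#' Min-max rescaling of a weight vector onto [0, 1]
#'
#' Affine map of `raw` onto `[0, 1]`; the minimum maps to 0 and the maximum
#' to 1. A constant vector is an error because the resulting weights would
#' be undefined.
#'
#' @param raw Numeric vector with at least two distinct values.
#' @return Numeric vector of the same length in `[0, 1]`.
#' @export
minmax_rescale <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw)) {
    stop("'raw' must be a numeric vector without missing values")
  }
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    stop("cannot rescale a constant vector: weights are undefined")
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

# Block-wise rescaling used for all weighting methods: each instrument block
# (BDI items / anxiety subscales / auxiliary totals) is mapped to [0, 1]
# separately.
rescale_by_block <- function(raw, labels) {
  blocks <- variable_blocks()[labels]
  out <- numeric(length(raw))
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    out[idx] <- minmax_rescale(raw[idx])
  }
  out
}

#' Construct a weight vector
#'
#' A `weight_vector` holds per-variable coefficient weights from one of the
#' four weighting methods (EI1, EI2, PCPR, CFA), both raw and min-max
#' rescaled to `[0, 1]` within instrument blocks.
#'
#' @param raw Named numeric vector of raw statistics (one per baseline
#'   variable).
#' @param method One of `"EI1"`, `"EI2"`, `"PCPR"`, `"CFA"`.
#' @return An object of class `weight_vector`: a data frame with columns
#'   `label`, `method`, `raw`, `rescaled`.
#' @export
weight_vector <- function(raw, method = c("EI1", "EI2", "PCPR", "CFA")) {
  method <- match.arg(method)
  labels <- names(raw)
  if (is.null(labels)) stop("'raw' must be a named vector")
  if (all(baseline_labels() %in% labels)) {
    # full baseline schema: canonical order, block-wise rescaling
    raw <- raw[baseline_labels()]
    rescaled <- rescale_by_block(unname(raw), names(raw))
  } else {
    rescaled <- minmax_rescale(unname(raw))
  }
  out <- data.frame(
    label = names(raw),
    method = method,
    raw = unname(raw),
    rescaled = rescaled,
    stringsAsFactors = FALSE
  )
  class(out) <- c("weight_vector", "data.frame")
  out
}

#' Write a weight vector to CSV
#'
#' @param w A [weight_vector()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(w, path) {
  stopifnot(inherits(w, "weight_vector"))
  utils::write.csv(as.data.frame(w), path, row.names = FALSE)
  invisible(path)
}

# Deterministic per-stage seeds derived from one master seed.  Offsets keep
# the result a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offsets <- c(generate = 11L, missing = 23L, impute_train = 37L,
               impute_test = 41L, fgl_cv = 53L, enr = 67L, cv = 79L,
               folds = 97L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 101 + offsets[[stage]]) %% .Machine$integer.max)
}
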