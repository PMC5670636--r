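# Data model and bookkeeping for batch respirometry: dissolved-oxygen traces,
# biomass calibration, and the sequential-addition substrate accounting.

#' Construct a respirogram trace
#'
#' A respirogram is the time course of dissolved oxygen (DO) in an aerated
#' batch reactor; substrate pulses show up as drop-and-recovery excursions.
#' DO is stored as a concentration (mg O2 L-1); probes that log percent
#' saturation are converted with [convert_saturation()].
#'
#' @param time Numeric vector of sampling times, hours, strictly increasing.
#' @param do_signal DO concentration at each time, mg O2 L-1.
#' @param do_sat Saturation DO concentration of the medium, mg O2 L-1.
#'   Defaults to 9.08 mg O2 L-1 (clean fresh water at 20 C).
#' @param temperature Broth temperature, degrees C.
#' @param substrate_label,replicate_id Free-text metadata.
#' @param additions Optional numeric vector of substrate-addition times
#'   (hours) when they are known, e.g. from the reactor log or a simulation.
#'
#' @return An object of class `respirogram_trace`: a list with the fields
#'   above, validated against the trace invariants.
#' @export
respirogram_trace <- function(time, do_signal, do_sat = 9.08,
                              temperature = 20,
                              substrate_label = NA_character_,
                              replicate_id = NA_character_,
                              additions = NULL) {
  time <- as.numeric(time)
  do_signal <- as.numeric(do_signal)
  if (length(time) != length(do_signal))
    stop("`time` and `do_signal` must have equal length", call. = FALSE)
  if (length(time) < 3L)
    stop("a respirogram needs at least 3 samples", call. = FALSE)
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop(sprintf("`time` must be strictly increasing; first violation at row %d",
                 bad[1] + 1L), call. = FALSE)
  if (!is.numeric(do_sat) || length(do_sat) != 1L || do_sat <= 0)
    stop("`do_sat` must be a single positive number", call. = FALSE)
  if (any(do_signal < 0))
    stop("`do_signal` must be nonnegative", call. = FALSE)
  if (any(do_signal > do_sat * 1.05))
    stop("`do_signal` exceeds do_sat by more than the 5% probe-noise allowance",
         call. = FALSE)
  structure(
    list(time = time, do_signal = do_signal, do_sat = do_sat,
         temperature = temperature, substrate_label = substrate_label,
         replicate_id = replicate_id,
         additions = if (is.null(additions)) NULL else as.numeric(additions)),
    class = "respirogram_trace")
}

#' @export
print.respirogram_trace <- function(x, ...) {
  cat(sprintf("<respirogram_trace> %d samples over %.3f h\n",
              length(x$time), diff(range(x$time))))
  cat(sprintf("  DO %.2f-%.2f mg O2/L (saturation %.2f), %g C\n",
              min(x$do_signal), max(x$do_signal), x$do_sat, x$temperature))
  if (!is.na(x$substrate_label))
    cat(sprintf("  substrate: %s  replicate: %s\n",
                x$substrate_label, x$replicate_id))
  if (!is.null(x$additions))
    cat(sprintf("  additions at: %s h\n",
                paste(format(x$additions, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Convert percent-saturation DO to a concentration
#'
#' @param pct DO as percent of saturation (0-100 and slightly above for
#'   probe noise); vectorized.
#' @param do_sat Saturation DO concentration, mg O2 L-1.
#' @return DO concentration, mg O2 L-1: `pct/100 * do_sat`.
#' @export
convert_saturation <- function(pct, do_sat) {
  if (any(pct < 0)) stop("percent saturation must be nonnegative", call. = FALSE)
  if (do_sat <= 0) stop("`do_sat` must be positive", call. = FALSE)
  pct / 100 * do_sat
}

#' Read a respirogram from a delimited text file
#'
#' Expects a header with a time column (`time_h` by default) and exactly one
#' DO column: `do_pct` (percent saturation, converted via
#' [convert_saturation()]) or `do_mgl` (already mg O2 L-1). An optional
#' `event_marker` column with nonzero entries flags addition instants.
#'
#' @param path Path to the file.
#' @param do_sat Saturation DO used for percent conversion, mg O2 L-1.
#' @param units `"auto"` picks the DO column present; force with `"pct"` or
#'   `"mgl"`.
#' @param sep Field delimiter.
#' @param columns Named list remapping column names, e.g.
#'   `list(time = "t", do = "oxygen")`.
#' @param ... Passed to [respirogram_trace()] (metadata fields).
#' @return A validated [respirogram_trace()].
#' @export
load_trace <- function(path, do_sat = 9.08, units = c("auto", "pct", "mgl"),
                       sep = ",", columns = list(), ...) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  time_col <- if (!is.null(columns$time)) columns$time else "time_h"
  if (!time_col %in% names(df))
    stop(sprintf("missing time column '%s'", time_col), call. = FALSE)
  do_col <- columns$do
  if (is.null(do_col)) {
    present <- intersect(c("do_pct", "do_mgl"), names(df))
    if (units == "pct") present <- intersect("do_pct", names(df))
    if (units == "mgl") present <- intersect("do_mgl", names(df))
    if (length(present) != 1L)
      stop("expected exactly one DO column (do_pct or do_mgl); found: ",
           paste(present, collapse = ", "), call. = FALSE)
    do_col <- present
  }
  is_pct <- if (units == "auto") identical(do_col, "do_pct") else units == "pct"
  do <- df[[do_col]]
  if (is_pct) do <- convert_saturation(do, do_sat)
  additions <- NULL
  if ("event_marker" %in% names(df)) {
    additions <- df[[time_col]][df$event_marker != 0]
    if (!length(additions)) additions <- NULL
  }
  respirogram_trace(time = df[[time_col]], do_signal = do, do_sat = do_sat, ...,
                    additions = additions)
}

#' Write a respirogram to CSV
#'
#' Writes `time_h`, `do_mgl` and, when addition times are recorded, an
#' `event_marker` column (1 at the sample nearest each addition).
#'
#' @param trace A [respirogram_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "respirogram_trace"))
  df <- data.frame(time_h = trace$time, do_mgl = trace$do_signal)
  if (!is.null(trace$additions)) {
    marker <- integer(length(trace$time))
    idx <- vapply(trace$additions,
                  function(a) which.min(abs(trace$time - a)), integer(1))
    marker[idx] <- 1L
    df$event_marker <- marker
  }
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Biomass calibration curve (OD600 to mg TSS per litre)
#'
#' Linear map from optical density at 600 nm to biomass dry mass measured as
#' total suspended solids: `X_T = slope * OD600 + intercept`. The default
#' constants are the calibration used throughout this package's worked
#' examples (R2 = 0.9995); supply your own for a different strain or
#' spectrophotometer.
#'
#' @param slope mg TSS L-1 per OD600 unit; must be positive.
#' @param intercept mg TSS L-1 (often negative: the line crosses zero at a
#'   small positive OD).
#' @param r_squared Coefficient of determination of the calibration fit.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope = 2140.3, intercept = -325.2,
                              r_squared = 0.9995) {
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (r_squared < 0 || r_squared > 1)
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared),
            class = "calibration_curve")
}

#' Convert OD600 readings to biomass concentration
#'
#' @param od600 Optical density at 600 nm; vectorized.
#' @param cal A [calibration_curve()].
#' @param clamp With a negative intercept the line predicts negative biomass
#'   below its root; `clamp = TRUE` (default) floors the result at 0 with a
#'   warning, `clamp = FALSE` raises an error instead.
#' @return Biomass concentration, mg TSS L-1.
#' @export
od_to_biomass <- function(od600, cal = calibration_curve(), clamp = TRUE) {
  stopifnot(inherits(cal, "calibration_curve"))
  x <- cal$slope * od600 + cal$intercept
  if (any(x < 0)) {
    if (!clamp)
      stop("OD600 below the zero-biomass root of the calibration line",
           call. = FALSE)
    warning("negative calibrated biomass clamped to 0", call. = FALSE)
    x <- pmax(x, 0)
  }
  x
}

#' Sequential-addition schedule for one substrate
#'
#' Describes the study design of a sequential-addition respirometric assay:
#' a concentrated substrate stock of known COD, diluted to a series of
#' strengths, with a fixed small volume of each dilution pulsed into the
#' reactor once the previous pulse is fully consumed.
#'
#' @param stock_cod COD of the undiluted stock, mg O2 L-1.
#' @param dilution_fractions Fraction of full strength for each pulse, each
#'   in (0, 1].
#' @param addition_volume Volume added per pulse, L.
#' @param initial_volume Reactor liquid volume before the first pulse, L
#'   (medium plus inoculum).
#' @param biomass_od_per_event Optional OD600 read before each pulse (same
#'   length as `dilution_fractions`).
#' @param substrate_label Free-text label.
#' @return An object of class `addition_schedule`.
#' @export
addition_schedule <- function(stock_cod, dilution_fractions,
                              addition_volume = 0.010, initial_volume = 1.010,
                              biomass_od_per_event = NULL,
                              substrate_label = NA_character_) {
  if (stock_cod < 0) stop("`stock_cod` must be nonnegative", call. = FALSE)
  if (any(dilution_fractions <= 0 | dilution_fractions > 1))
    stop("each dilution fraction must lie in (0, 1]", call. = FALSE)
  if (addition_volume <= 0 || initial_volume <= 0)
    stop("volumes must be positive", call. = FALSE)
  if (!is.null(biomass_od_per_event) &&
      length(biomass_od_per_event) != length(dilution_fractions))
    stop("`biomass_od_per_event` must match `dilution_fractions` in length",
         call. = FALSE)
  structure(
    list(stock_cod = stock_cod,
         dilution_fractions = as.numeric(dilution_fractions),
         addition_volume = addition_volume, initial_volume = initial_volume,
         biomass_od_per_event = biomass_od_per_event,
         substrate_label = substrate_label),
    class = "addition_schedule")
}

#' Reactor constants
#'
#' @param f_cv COD equivalent of biomass, mg COD per mg TSS. The default
#'   1.48 is the standard value for heterotrophic biomass.
#' @param kla Volumetric oxygen transfer coefficient, h-1, or `NA` to
#'   estimate it from a DO recovery tail ([estimate_kla()]).
#' @param endogenous_our Baseline endogenous oxygen uptake rate,
#'   mg O2 L-1 h-1 (absorbed into the pre-addition DO baseline).
#' @return An object of class `reactor_constants`.
#' @export
reactor_constants <- function(f_cv = 1.48, kla = NA_real_,
                              endogenous_our = 0) {
  if (f_cv <= 0) stop("`f_cv` must be positive", call. = FALSE)
  if (!is.na(kla) && kla < 0) stop("`kla` must be nonnegative", call. = FALSE)
  structure(list(f_cv = f_cv, kla = kla, endogenous_our = endogenous_our),
            class = "reactor_constants")
}

#' COD of a diluted substrate stock
#'
#' @param stock_cod COD of the full-strength stock, mg O2 L-1.
#' @param fraction Dilution strength in (0, 1]; vectorized.
#' @return `stock_cod * fraction`, mg O2 L-1.
#' @export
dilution_cod <- function(stock_cod, fraction) {
  if (any(fraction <= 0 | fraction > 1))
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  stock_cod * fraction
}

#' In-reactor substrate concentration after a pulse
#'
#' The pulse dose (diluted-stock COD times the added volume) divided by the
#' total reactor volume after the addition. Earlier pulses are assumed fully
#' consumed — additions are made only once DO has returned to a stable
#' maximum, the sign of total substrate consumption — so the k-th pulse sees
#' a volume of `initial_volume + k * addition_volume`.
#'
#' @param schedule An [addition_schedule()].
#' @param event_index Which pulse, 1-based.
#' @return Substrate concentration S in the reactor, mg O2 L-1 (as COD).
#' @export
in_reactor_substrate <- function(schedule, event_index) {
  stopifnot(inherits(schedule, "addition_schedule"))
  n <- length(schedule$dilution_fractions)
  if (any(event_index < 1 | event_index > n))
    stop(sprintf("event_index out of range 1..%d", n), call. = FALSE)
  frac <- schedule$dilution_fractions[event_index]
  dose <- dilution_cod(schedule$stock_cod, frac) * schedule$addition_volume
  dose / (schedule$initial_volume + event_index * schedule$addition_volume)
}

#' Tabulate a sequential-addition design
#'
#' One row per pulse: dilution label, diluted-stock COD, in-reactor substrate
#' concentration S, and (when OD readings are supplied) the pre-addition
#' biomass concentration X_T.
#'
#' @param schedule An [addition_schedule()].
#' @param cal A [calibration_curve()] used when the schedule carries OD600
#'   readings.
#' @return A data.frame with columns `substrate`, `dilution`, `cod`, `s`,
#'   `x_t`.
#' @export
events_table <- function(schedule, cal = calibration_curve()) {
  stopifnot(inherits(schedule, "addition_schedule"))
  k <- seq_along(schedule$dilution_fractions)
  x_t <- if (is.null(schedule$biomass_od_per_event)) NA_real_ else
    od_to_biomass(schedule$biomass_od_per_event, cal)
  data.frame(
    substrate = schedule$substrate_label,
    dilution = paste0("S", k),
    cod = dilution_cod(schedule$stock_cod, schedule$dilution_fractions),
    s = in_reactor_substrate(schedule, k),
    x_t = x_t,
    stringsAsFactors = FALSE)
}
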