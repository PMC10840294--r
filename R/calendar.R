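#' Crop calendar: phenological stages as day-of-year windows
#'
#' The decision rule uses four stages. Windows are half-open `[start, end)`,
#' so a date on a boundary belongs to the later stage; dates outside every
#' window (fallow season) are excluded from compositing. Defaults follow a
#' single-season rice calendar for the subtropical hill country the method
#' targets: sowing DOY 60-110 (fields flooded before transplanting),
#' transplanting 110-130, growing 130-230, maturity 230-270.
#'
#' @param stages data frame with columns `stage`, `start`, `end` (DOY);
#'   stage names must be sowing, transplanting, growing, maturity in order,
#'   with non-overlapping ordered windows.
#' @return A `crop_calendar`.
#' @export
crop_calendar <- function(stages = NULL) {
  if (is.null(stages)) {
    stages <- data.frame(
      stage = rice_stages(),
      start = c(60L, 110L, 130L, 230L),
      end   = c(110L, 130L, 230L, 270L),
      stringsAsFactors = FALSE
    )
  }
  stages <- as.data.frame(stages, stringsAsFactors = FALSE)
  if (!all(c("stage", "start", "end") %in% names(stages))) {
    stop("config error: calendar needs columns stage, start, end", call. = FALSE)
  }
  if (!identical(stages$stage, rice_stages())) {
    stop("config error: calendar stages must be exactly ",
         paste(rice_stages(), collapse = ", "), " in order", call. = FALSE)
  }
  if (any(stages$end <= stages$start) ||
      any(utils::head(stages$end, -1) > utils::tail(stages$start, -1))) {
    stop("config error: stage windows must be ordered and non-overlapping",
         call. = FALSE)
  }
  structure(stages, class = c("crop_calendar", "data.frame"))
}

#' @rdname crop_calendar
#' @export
rice_stages <- function() c("sowing", "transplanting", "growing", "maturity")

#' Assign an acquisition date to a phenological stage
#'
#' @param date a `Date` (or coercible), or a numeric day of year.
#' @param calendar a [crop_calendar()].
#' @return The stage name whose half-open DOY window `[start, end)` contains
#'   the date, or `NA_character_` if none does.
#' @export
assign_stage <- function(date, calendar) {
  doy <- if (is.numeric(date)) date else as.POSIXlt(as.Date(date))$yday + 1
  vapply(doy, function(d) {
    hit <- which(calendar$start <= d & d < calendar$end)
    if (length(hit) == 1L) calendar$stage[hit] else NA_character_
  }, character(1))
}
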