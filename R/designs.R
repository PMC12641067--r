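#' Construct a study design
#'
#' A design is a set of occasions shared by every subject of one study arm.
#' Each occasion carries an inhibitor regimen (possibly empty), biomarker
#' plasma sampling times, inhibitor plasma sampling times, and urine
#' collection intervals. Times are hours from the occasion origin, which for
#' dosed occasions is the first inhibitor dose (for the multi-day probenecid
#' regimen the sampling day starts 13 h after the first evening dose).
#'
#' @param name Design label.
#' @param n_subjects Number of subjects.
#' @param occasions List of occasions; each a list with elements `label`,
#'   `regimen` ([dose_events()] data frame or `NULL`), `biomarker_times`,
#'   `inhibitor_times` (numeric, possibly empty), `urine_intervals`
#'   (two-column matrix of (start, end] h, or `NULL`).
#' @param duration Simulation window end (h); must cover all sampling times.
#' @return An object of class `study_design`.
#' @export
study_design <- function(name, n_subjects, occasions, duration) {
  for (occ in occasions) {
    tt <- c(occ$biomarker_times, occ$inhibitor_times, occ$urine_intervals)
    if (length(tt) && (min(tt) < 0 || max(tt) > duration))
      stop("sampling times must lie within [0, duration]")
    ui <- occ$urine_intervals
    if (!is.null(ui)) {
      if (any(ui[, 2] <= ui[, 1])) stop("urine intervals must have end > start")
      if (nrow(ui) > 1 && any(ui[-1, 1] < ui[-nrow(ui), 2]))
        stop("urine intervals must be ordered and non-overlapping")
    }
  }
  structure(list(name = name, n_subjects = n_subjects,
                 occasions = occasions, duration = duration),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design '%s': %d subjects, %d occasion(s), %g h window\n",
              x$name, x$n_subjects, length(x$occasions), x$duration))
  for (occ in x$occasions) {
    nd <- if (is.null(occ$regimen)) 0 else nrow(occ$regimen)
    cat(sprintf("  %-10s %d dose(s), %d plasma, %d inhibitor, %d urine samples\n",
                occ$label, nd, length(occ$biomarker_times),
                length(occ$inhibitor_times),
                if (is.null(occ$urine_intervals)) 0 else nrow(occ$urine_intervals)))
  }
  invisible(x)
}

#' The multi-day probenecid regimen
#'
#' 500 mg orally at 6 pm and 11 pm on day 0, then at 7 am, 1 pm, 6 pm and
#' 11 pm on days 1 to `days`. Time zero is the first (6 pm, day 0) dose, so
#' the 7 am day-1 dose falls at 13 h.
#'
#' @param days Number of full dosing days after day 0.
#' @param amount Dose amount (mg).
#' @return A [dose_events()] data frame.
#' @export
probenecid_regimen <- function(days = 7, amount = 500) {
  times <- c(0, 5)
  for (d in seq_len(days)) times <- c(times, 13 + 24 * (d - 1) + c(0, 6, 11, 16))
  dose_events("probenecid", times, amount)
}

# Offset from the first probenecid dose (6 pm day 0) to the start of the
# sampling day (7 am day 1).
.prob_sampling_offset <- 13

#' Built-in study designs
#'
#' The three clinical designs used for model development plus the two
#' single-dose rifampicin designs used for model verification:
#' \describe{
#'   \item{study1}{n = 6, two occasions, 24 h plasma sampling, no urine;
#'     single 600 mg rifampicin dose on occasion 2.}
#'   \item{study2}{n = 6, cross-over, 168 h plasma and interval-urine
#'     sampling; multi-day 500 mg probenecid regimen on occasion 2.}
#'   \item{study3}{n = 12, cross-over, 24 h plasma and interval-urine
#'     sampling; same probenecid regimen.}
#'   \item{rif300, rif600}{single 300/600 mg rifampicin verification
#'     designs, 24 h cross-over, plasma only.}
#' }
#' Per-study sampling clock times are not part of the published designs;
#' the defaults reproduce the published sample counts and are configurable
#' by editing the returned objects.
#'
#' @return Named list of [study_design()] objects.
#' @export
builtin_designs <- function() {
  off <- .prob_sampling_offset
  # study 1: single-dose rifampicin cross-over, plasma only
  bm1 <- c(0, 1, 2, 4, 6, 9, 12, 24)
  rif1 <- c(1, 1.5, 2, 3, 4, 6, 9, 12, 24)
  study1 <- study_design("study1", 6, list(
    list(label = "control", regimen = NULL, biomarker_times = bm1,
         inhibitor_times = numeric(0), urine_intervals = NULL),
    list(label = "treatment", regimen = dose_events("rifampicin", 0, 600),
         biomarker_times = bm1, inhibitor_times = rif1,
         urine_intervals = NULL)), duration = 24)

  # study 2: multi-day probenecid cross-over, 168 h plasma + daily urine
  bm2 <- off + c(0, 1, 2, 4, 6, 9, 12, 18, 24, 96, 168)
  ur2 <- cbind(off + c(0, 6, 12, 24, 48, 72, 96, 120, 144),
               off + c(6, 12, 24, 48, 72, 96, 120, 144, 168))
  pr2 <- off + c(0.5, 2, 4, 6, 12, 24)
  study2 <- study_design("study2", 6, list(
    list(label = "control", regimen = NULL, biomarker_times = bm2,
         inhibitor_times = numeric(0), urine_intervals = ur2),
    list(label = "treatment", regimen = probenecid_regimen(7),
         biomarker_times = bm2, inhibitor_times = pr2,
         urine_intervals = ur2)), duration = off + 168)

  # study 3: same regimen, 24 h sampling day
  bm3 <- off + c(0, 1, 2, 4, 6, 8, 12, 18, 24)
  ur3 <- cbind(off + c(0, 6, 12), off + c(6, 12, 24))
  pr3 <- off + c(0.5, 2, 6, 12, 18, 24)
  study3 <- study_design("study3", 12, list(
    list(label = "control", regimen = NULL, biomarker_times = bm3,
         inhibitor_times = numeric(0), urine_intervals = ur3),
    list(label = "treatment", regimen = probenecid_regimen(2),
         biomarker_times = bm3, inhibitor_times = pr3,
         urine_intervals = ur3)), duration = off + 24)

  verif <- function(name, dose) study_design(name, 1000, list(
    list(label = "control", regimen = NULL, biomarker_times = bm1,
         inhibitor_times = numeric(0), urine_intervals = NULL),
    list(label = "treatment", regimen = dose_events("rifampicin", 0, dose),
         biomarker_times = bm1, inhibitor_times = rif1,
         urine_intervals = NULL)), duration = 24)

  list(study1 = study1, study2 = study2, study3 = study3,
       rif300 = verif("rif300", 300), rif600 = verif("rif600", 600))
}
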