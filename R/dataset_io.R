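#' Read and validate a dataset file
#'
#' The dataset dialect is a NONMEM-convention-inspired CSV with one row per
#' dose or observation: `ID` (integer subject), `OCC` (integer occasion),
#' `TIME` (h, occasion-relative), `EVID` (0 observation / 1 dose), `DVID`
#' (1 biomarker plasma uM, 2 biomarker urine umol, 3 rifampicin plasma uM,
#' 4 probenecid plasma uM; empty on dose rows), `DV` (value; empty on dose
#' rows), `AMT` (dose mg; empty on observation rows), `DRUG` (`RIF`/`PROB`
#' on dose rows), `USTART` (urine interval start h, `DVID == 2` rows only).
#' Rows must be sorted by (`ID`, `OCC`, `TIME`).
#'
#' @param path CSV file path.
#' @return Validated data frame of records.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(DRUG = "character"))
  d$DRUG[!is.na(d$DRUG) & d$DRUG == ""] <- NA_character_
  validate_dataset(d)
}

#' @rdname read_dataset
#' @param records Data frame of records to validate or write.
#' @export
validate_dataset <- function(records) {
  req <- c("ID", "OCC", "TIME", "EVID", "DVID", "DV", "AMT", "DRUG", "USTART")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing dataset column(s): ", paste(miss, collapse = ", "))
  rows <- function(sel) paste(which(sel), collapse = ", ")
  bad <- !is.na(records$DV) & !is.na(records$AMT)
  if (any(bad)) stop("rows with both DV and AMT populated: ", rows(bad))
  bad <- records$EVID == 0 & is.na(records$DV)
  if (any(bad)) stop("observation rows without DV: ", rows(bad))
  bad <- records$EVID == 1 & (is.na(records$AMT) | is.na(records$DRUG) |
                                !(records$DRUG %in% c("RIF", "PROB")))
  if (any(bad)) stop("dose rows need AMT and DRUG in {RIF, PROB}: ", rows(bad))
  bad <- records$EVID == 0 & !(records$DVID %in% 1:4)
  if (any(bad)) stop("observation rows with bad DVID: ", rows(bad))
  bad <- records$EVID == 0 & records$DVID == 2 &
    (is.na(records$USTART) | records$USTART >= records$TIME)
  if (any(bad)) stop("urine rows need USTART < TIME: ", rows(bad))
  bad <- !is.na(records$DV) & records$DV < 0
  if (any(bad)) stop("negative DV values: ", rows(bad))
  key <- cbind(records$ID, records$OCC, records$TIME)
  if (nrow(records) > 1) {
    prev <- key[-nrow(key), , drop = FALSE]
    nxt <- key[-1, , drop = FALSE]
    ok <- (nxt[, 1] > prev[, 1]) |
      (nxt[, 1] == prev[, 1] & (nxt[, 2] > prev[, 2] |
                                  (nxt[, 2] == prev[, 2] & nxt[, 3] >= prev[, 3])))
    if (!all(ok)) stop("rows not sorted by (ID, OCC, TIME); first violation at row ",
                       which(!ok)[1] + 1)
  }
  records
}

#' @rdname read_dataset
#' @export
write_dataset <- function(records, path) {
  records <- validate_dataset(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Dose rows for every subject of a design (dataset dialect).
.dose_rows <- function(design) {
  out <- list()
  for (io in seq_along(design$occasions)) {
    reg <- design$occasions[[io]]$regimen
    if (is.null(reg) || !nrow(reg)) next
    for (id in seq_len(design$n_subjects))
      out[[length(out) + 1L]] <- data.frame(
        ID = id, OCC = io, TIME = reg$time, EVID = 1L, DVID = NA_integer_,
        DV = NA_real_, AMT = reg$amount,
        DRUG = ifelse(reg$drug == "rifampicin", "RIF", "PROB"),
        USTART = NA_real_)
  }
  if (length(out)) do.call(rbind, out) else NULL
}
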