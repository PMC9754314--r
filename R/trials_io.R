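TRIAL_COLUMNS <- c("participant_id", "condition", "phase", "trial",
                   "dot_count", "estimate", "partner_estimate")

#' Write a trial table to CSV
#'
#' Fixed seven-column dialect shared by all tools in the package:
#' `participant_id,condition,phase,trial,dot_count,estimate,partner_estimate`.
#' Missing estimates are encoded as empty fields.
#'
#' @param records trial-record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  write.csv(records[TRIAL_COLUMNS], path, row.names = FALSE, na = "",
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the mandatory header and the integer columns; empty `estimate`
#' or `partner_estimate` fields are read as missing. Malformed rows raise an
#' error naming the offending data row.
#'
#' @param path CSV file path.
#' @return trial-record data.frame.
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  if (!identical(names(raw), TRIAL_COLUMNS)) {
    stop("malformed header in ", path, ": expected columns ",
         paste(TRIAL_COLUMNS, collapse = ","))
  }
  parse_int <- function(x, col, allow_na) {
    x <- trimws(x)
    out <- rep(NA_integer_, length(x))
    empty <- x == "" | is.na(x)
    if (!allow_na && any(empty)) {
      stop("missing ", col, " in row ", which(empty)[1])
    }
    bad <- !empty & !grepl("^-?[0-9]+$", x)
    if (any(bad)) {
      stop("non-integer ", col, " ('", x[which(bad)[1]], "') in row ",
           which(bad)[1])
    }
    out[!empty] <- as.integer(x[!empty])
    out
  }
  data.frame(
    participant_id = raw$participant_id,
    condition = raw$condition,
    phase = raw$phase,
    trial = parse_int(raw$trial, "trial", allow_na = FALSE),
    dot_count = parse_int(raw$dot_count, "dot_count", allow_na = FALSE),
    estimate = parse_int(raw$estimate, "estimate", allow_na = TRUE),
    partner_estimate = parse_int(raw$partner_estimate, "partner_estimate",
                                 allow_na = TRUE)
  )
}
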