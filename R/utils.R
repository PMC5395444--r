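# internal helpers shared across modules

.normName <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

.stop2 <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "TOPscreen_error")))
}

# split a semicolon-separated cell into a character vector; "" -> character(0)
.splitCell <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

# parse a flowering-months cell: "9-12", "1;2;12", "" (unknown), or "10"
.parseMonths <- function(x) {
  lapply(x, function(cell) {
    cell <- trimws(cell)
    if (!nzchar(cell)) return(integer(0))
    parts <- unlist(strsplit(cell, ";", fixed = TRUE))
    months <- unlist(lapply(parts, function(p) {
      p <- trimws(p)
      if (grepl("-", p, fixed = TRUE)) {
        ab <- as.integer(unlist(strsplit(p, "-", fixed = TRUE)))
        if (length(ab) != 2 || anyNA(ab))
          .stop2("format_error", "bad flowering_months cell: '%s'", cell)
        if (ab[1] <= ab[2]) ab[1]:ab[2] else c(ab[1]:12, 1:ab[2])
      } else {
        m <- as.integer(p)
        if (is.na(m))
          .stop2("format_error", "bad flowering_months cell: '%s'", cell)
        m
      }
    }))
    sort(unique(months))
  })
}

.formatMonths <- function(ms) {
  vapply(ms, function(m) paste(m, collapse = ";"), character(1))
}

.enumOrUnknown <- function(x, allowed, column) {
  x <- tolower(trimws(x))
  x[!nzchar(x)] <- "unknown"
  bad <- setdiff(unique(x), allowed)
  if (length(bad))
    .stop2("format_error", "invalid value(s) in column '%s': %s", column,
           paste(bad, collapse = ", "))
  x
}

.parseLogical <- function(x, column) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "")] <- FALSE
  if (anyNA(out))
    .stop2("format_error", "invalid logical value in column '%s'", column)
  out
}
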