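# internal validation helpers

stop_tpsad <- function(msg, class = "tpsad_error") {
  rlang::abort(msg, class = c(class, "tpsad_error"))
}

check_numeric <- function(x, name, min = -Inf, allow_na = FALSE) {
  if (!is.numeric(x)) stop_tpsad(sprintf("`%s` must be numeric.", name), "tpsad_validation_error")
  if (!allow_na && anyNA(x)) stop_tpsad(sprintf("`%s` contains missing values.", name), "tpsad_validation_error")
  bad <- !is.na(x) & x < min
  if (any(bad)) {
    stop_tpsad(sprintf("`%s` must be >= %s (offending value: %s).", name, format(min), format(x[which(bad)[1]])),
               "tpsad_validation_error")
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_tpsad(sprintf("%s is missing required column(s): %s.", what, paste(missing, collapse = ", ")),
               "tpsad_validation_error")
  }
  invisible(data)
}

# logical coercion for 0/1 columns coming from CSV
as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x %in% c("1", "TRUE", "true", "yes")
}

# Moore-Penrose fallback used when a variance matrix is singular
safe_solve <- function(A, b = NULL) {
  out <- tryCatch(if (is.null(b)) solve(A) else solve(A, b), error = function(e) NULL)
  if (is.null(out)) {
    gi <- MASS::ginv(A)
    out <- if (is.null(b)) gi else gi %*% b
  }
  out
}

paste_flags <- function(...) {
  flags <- list(...)
  apply(do.call(cbind, flags), 1L, function(row) {
    row <- row[!is.na(row) & nzchar(row)]
    if (length(row) == 0) "" else paste(row, collapse = ";")
  })
}
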