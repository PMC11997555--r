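# internal validation helpers; all user-facing errors go through rlang::abort
# with a dropvcn_* class so callers can condition on them

stop_dropvcn <- function(message, class) {
  abort(message, class = c(paste0("dropvcn_", class), "dropvcn_error"))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_dropvcn(sprintf("`%s` must be supplied.", name), "invalid_argument")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_dropvcn(sprintf("`%s` must be a single finite number.", name),
                 "invalid_argument")
  }
  low_ok <- if (strict_min) x > min else x >= min
  if (!low_ok || x > max) {
    stop_dropvcn(sprintf("`%s` = %g is outside its valid range.", name, x),
                 "invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != round(x)) {
    stop_dropvcn(sprintf("`%s` must be a whole number.", name),
                 "invalid_argument")
  }
  invisible(as.integer(x))
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_dropvcn(sprintf("`%s` must be TRUE or FALSE.", name),
                 "invalid_argument")
  }
  invisible(x)
}

# tibble with an extra S3 class in front; `class` holds only the subclasses
new_record <- function(data, class) {
  new_tibble(data, nrow = nrow(data), class = setdiff(class, class(tibble())))
}
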