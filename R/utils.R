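# Shared internal helpers.

# round() in R rounds half to even; ladder construction needs arithmetic
# half-up rounding so scaled ladders are reproducible integers.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_effdisc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "effdisc_error")))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_effdisc(sprintf("'%s' must be a single finite number", name),
                 "effdisc_invalid_spec")
  }
}

# Columns required of the two CSV interchange tables.
choices_cols <- c("participant_id", "domain", "amount", "effort_level",
                  "row_index", "effortless_value", "choice")
ip_cols <- c("participant_id", "domain", "amount", "effort_level", "ip")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_effdisc(sprintf("%s is missing column(s): %s", what,
                         paste(missing, collapse = ", ")),
                 "effdisc_schema_error")
  }
  invisible(df)
}
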