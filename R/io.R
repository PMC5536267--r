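# CSV interchange: choice-level records and indifference-point tables.
#
# choices.csv: participant_id,domain,amount,effort_level,row_index,
#              effortless_value,choice   (choice in {effortless, effortful})
# ips.csv:     participant_id,domain,amount,effort_level,ip

#' Read choice-level records
#'
#' Reads a choices CSV and validates its schema, the choice tokens, and the
#' single-switch invariant: within one participant x condition, reading the
#' ladder top to bottom, preferences may shift at most once, from the
#' effortless to the effortful alternative. Violating sequences (impossible
#' under the questionnaire's stop-at-switch rule) are reported via warning and
#' returned in the `violations` attribute.
#'
#' @param path Path to a CSV file with header
#'   `participant_id,domain,amount,effort_level,row_index,effortless_value,choice`.
#' @return A data.frame of choice records, with attribute `violations` (a
#'   data.frame of participant x condition keys that violate the
#'   single-switch rule; empty if none).
#' @export
read_choices <- function(path) {
  if (!file.exists(path)) {
    stop_effdisc(sprintf("file not found: %s", path), "effdisc_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, choices_cols, "choices file")
  df <- df[, choices_cols]
  bad <- setdiff(unique(df$choice), c("effortless", "effortful"))
  if (length(bad)) {
    stop_effdisc(sprintf("unknown choice token(s): %s",
                         paste(bad, collapse = ", ")),
                 "effdisc_parse_error")
  }
  viol <- find_switch_violations(df)
  if (nrow(viol)) {
    warning(sprintf("%d participant x condition sequence(s) violate the single-switch rule",
                    nrow(viol)))
  }
  attr(df, "violations") <- viol
  df
}

#' Locate choice sequences violating the single-switch rule
#'
#' @param choices A choices data.frame (see [read_choices()]).
#' @return A data.frame with one row per violating
#'   participant x domain x amount x effort_level cell.
#' @export
find_switch_violations <- function(choices) {
  check_columns(choices, choices_cols, "choices table")
  if (!nrow(choices)) {
    return(data.frame(participant_id = character(), domain = character(),
                      amount = numeric(), effort_level = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(choices$participant_id, choices$domain, choices$amount,
                     choices$effort_level, drop = TRUE)
  groups <- split(seq_len(nrow(choices)), key)
  bad_first <- unlist(lapply(groups, function(idx) {
    seqc <- choices$choice[idx][order(choices$row_index[idx])]
    if (is_single_switch(seqc)) integer() else idx[1L]
  }), use.names = FALSE)
  if (!length(bad_first)) {
    return(data.frame(participant_id = character(), domain = character(),
                      amount = numeric(), effort_level = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- choices[bad_first, c("participant_id", "domain", "amount", "effort_level")]
  rownames(out) <- NULL
  out
}

# TRUE if the top-to-bottom choice sequence has at most one switch and that
# switch goes effortless -> effortful.
is_single_switch <- function(choice_seq) {
  x <- choice_seq == "effortful"
  n_switch <- sum(diff(x) != 0)
  if (n_switch == 0L) return(TRUE)
  n_switch == 1L && !x[1L]
}

#' Write choice-level records
#'
#' @param records A choices data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_choices <- function(records, path) {
  check_columns(records, choices_cols, "choices table")
  utils::write.csv(records[, choices_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an indifference-point table
#'
#' @param path CSV with header `participant_id,domain,amount,effort_level,ip`.
#'   Each `ip` must lie within `[0, amount]`.
#' @return A data.frame of indifference points.
#' @export
read_ip_table <- function(path) {
  if (!file.exists(path)) {
    stop_effdisc(sprintf("file not found: %s", path), "effdisc_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, ip_cols, "indifference-point file")
  df <- df[, ip_cols]
  validate_ip_table(df)
  df
}

validate_ip_table <- function(df) {
  bad <- which(!is.finite(df$ip) | df$ip < 0 | df$ip > df$amount)
  if (length(bad)) {
    stop_effdisc(sprintf("ip out of [0, amount] range in row(s): %s",
                         paste(utils::head(bad, 10L), collapse = ", ")),
                 "effdisc_range_error")
  }
  invisible(df)
}

#' Write an indifference-point table
#'
#' @param table An indifference-point data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ip_table <- function(table, path) {
  check_columns(table, ip_cols, "indifference-point table")
  validate_ip_table(table)
  utils::write.csv(table[, ip_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
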