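# Indifference-point extraction from titration choice sequences.

#' Extract one indifference point from a choice sequence
#'
#' The indifference point is the last effortless amount chosen before the
#' preference switched to the effortful alternative. Conventions at the
#' limits: choosing effortful already in row 1 gives `ip = A` (no
#' discounting measurable above the top row); never switching gives `ip = 0`
#' (the participant preferred even PLN 0 without effort).
#'
#' @param choice_seq Character vector of choices ("effortless"/"effortful"),
#'   ordered top to bottom.
#' @param ladder Numeric ladder of effortless values, same length or longer
#'   than `choice_seq` (the questionnaire stops after the switch, so
#'   sequences may be truncated).
#' @return The indifference point in PLN.
#' @examples
#' lad <- build_ladder(80)
#' extract_ip(c(rep("effortless", 10), rep("effortful", 20)), lad)  # 56
#' @export
extract_ip <- function(choice_seq, ladder) {
  n <- length(choice_seq)
  if (n < 1L || n > length(ladder)) {
    stop_effdisc("choice sequence length must be in [1, length(ladder)]",
                 "effdisc_invalid_sequence")
  }
  if (!is_single_switch(choice_seq)) {
    stop_effdisc("ambiguous choice sequence: more than one preference switch",
                 "effdisc_ambiguous_sequence")
  }
  effortless <- choice_seq == "effortless"
  if (!any(effortless)) return(ladder[1L])
  ladder[max(which(effortless))]
}

#' Extract indifference points for every participant x condition
#'
#' Applies [extract_ip()] across a choices table. Sequences with multiple
#' switches are excluded and reported via warning and the `excluded`
#' attribute.
#'
#' @param choices A choices data.frame (see [read_choices()]).
#' @param spec An [edq_design()] object used to rebuild each condition's
#'   ladder.
#' @return An indifference-point data.frame (`participant_id`, `domain`,
#'   `amount`, `effort_level`, `ip`) with attribute `excluded`.
#' @export
extract_ips <- function(choices, spec = edq_design()) {
  check_columns(choices, choices_cols, "choices table")
  if (!nrow(choices)) {
    out <- data.frame(participant_id = character(), domain = character(),
                      amount = numeric(), effort_level = numeric(),
                      ip = numeric(), stringsAsFactors = FALSE)
    attr(out, "excluded") <- out[, 1:4]
    return(out)
  }
  key <- interaction(choices$participant_id, choices$domain, choices$amount,
                     choices$effort_level, drop = TRUE)
  groups <- split(seq_len(nrow(choices)), key)
  rows <- lapply(groups, function(idx) {
    ord <- idx[order(choices$row_index[idx])]
    first <- ord[1L]
    amt <- choices$amount[first]
    lad <- build_ladder(amt, spec)
    ip <- tryCatch(extract_ip(choices$choice[ord], lad), error = function(e) NA_real_)
    data.frame(participant_id = choices$participant_id[first],
               domain = choices$domain[first], amount = amt,
               effort_level = choices$effort_level[first], ip = ip,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excl <- out[is.na(out$ip), 1:4]
  rownames(excl) <- NULL
  if (nrow(excl)) {
    warning(sprintf("excluded %d ambiguous (multi-switch) sequence(s)", nrow(excl)))
  }
  out <- out[!is.na(out$ip), ]
  rownames(out) <- NULL
  out <- out[order(out$participant_id, out$domain, out$amount, out$effort_level), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}

#' Drop the excluded first indifference point
#'
#' Removes zero-effort rows (the delay-only "first indifference point"
#' measured at effort level 0), which are excluded from all analyses because
#' the fixed 30-minute delay is common to every condition and most
#' participants show no discounting there.
#'
#' @param ip_table An indifference-point data.frame.
#' @return The table without `effort_level == 0` rows (idempotent).
#' @export
apply_exclusions <- function(ip_table) {
  check_columns(ip_table, ip_cols, "indifference-point table")
  out <- ip_table[ip_table$effort_level != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-median indifference points
#'
#' Computes the median indifference point per design cell
#' (domain x amount x effort level) across participants; the group-level
#' analysis fits models to these medians. Even participant counts use the
#' usual midpoint convention.
#'
#' @param ip_table An indifference-point data.frame (individual level).
#' @param spec Optional [edq_design()]; when supplied, every design cell must
#'   be populated by at least one participant, otherwise a missing-cell error
#'   names the empty cells.
#' @return A data.frame with `participant_id = "MEDIAN"` and one row per
#'   design cell.
#' @export
group_median_ips <- function(ip_table, spec = NULL) {
  check_columns(ip_table, ip_cols, "indifference-point table")
  if (!nrow(ip_table)) {
    stop_effdisc("cannot compute medians of an empty table",
                 "effdisc_missing_cell")
  }
  if (!is.null(spec)) {
    cells <- enumerate_conditions(spec)
    cells <- cells[!cells$zero_effort, ]
    have <- paste(ip_table$domain, ip_table$amount, ip_table$effort_level)
    want <- paste(cells$domain, cells$amount, cells$effort_level)
    missing <- setdiff(want, have)
    if (length(missing)) {
      stop_effdisc(sprintf("no indifference points in design cell(s): %s",
                           paste(missing, collapse = "; ")),
                   "effdisc_missing_cell")
    }
  }
  agg <- stats::aggregate(ip ~ domain + amount + effort_level, data = ip_table,
                          FUN = stats::median)
  out <- data.frame(participant_id = "MEDIAN", domain = agg$domain,
                    amount = agg$amount, effort_level = agg$effort_level,
                    ip = agg$ip, stringsAsFactors = FALSE)
  out <- out[order(out$domain, out$amount, out$effort_level), ]
  rownames(out) <- NULL
  out
}
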