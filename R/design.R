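# Experimental design: effort domains x reward amounts x effort intensities,
# and the descending titration ladders presented on each questionnaire page.

# The 30 effortless amounts printed on the PLN 80 page, top to bottom.
# All other ladders are this profile expressed as fractions of 80, rescaled.
.ladder80 <- c(80, 79, 77, 74, 71, 68, 65, 62, 59, 56, 53, 50, 47, 44, 41,
               38, 35, 32, 29, 26, 23, 20, 17, 14, 11, 8, 5, 2, 1, 0)

#' Define a titration questionnaire design
#'
#' Describes one effort-discounting questionnaire: which effort domains are
#' tested, the fixed reward amounts of the effortful alternative, the effort
#' intensity levels, and the fixed delay attached to every effortful payoff.
#' The default reproduces the canonical 2 x 3 x 5 design: physical and
#' cognitive effort, amounts of PLN 80, 400 and 3000, and 30 to 150 effort
#' units, giving 30 conditions.
#'
#' @param effort_domains Character vector of effort-domain labels.
#' @param amounts Numeric vector of reward amounts (PLN), strictly increasing.
#' @param effort_levels Numeric vector of effort intensities (task units,
#'   e.g. grip squeezes or arithmetic problems), strictly increasing.
#' @param delay_minutes Fixed delay (minutes) attached to every effortful
#'   alternative; constant across conditions so effort is not confounded with
#'   varying delay.
#' @param include_zero_effort_pages If `TRUE`, zero-effort pages (delay-only
#'   choices) are generated alongside the design. They measure the excluded
#'   "first indifference point" and never count towards the condition total.
#' @return An object of class `edq_design`.
#' @examples
#' d <- edq_design()
#' nrow(enumerate_conditions(d))  # 30
#' @export
edq_design <- function(effort_domains = c("physical", "cognitive"),
                       amounts = c(80, 400, 3000),
                       effort_levels = c(30, 60, 90, 120, 150),
                       delay_minutes = 30,
                       include_zero_effort_pages = TRUE) {
  if (!is.character(effort_domains) || length(effort_domains) < 1L ||
      anyDuplicated(effort_domains) || any(!nzchar(effort_domains))) {
    stop_effdisc("effort_domains must be one or more distinct non-empty labels",
                 "effdisc_invalid_spec")
  }
  for (nm in c("amounts", "effort_levels")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)) ||
        any(v <= 0) || is.unsorted(v, strictly = TRUE)) {
      stop_effdisc(sprintf("%s must be strictly positive and strictly increasing", nm),
                   "effdisc_invalid_spec")
    }
  }
  assert_scalar_number(delay_minutes, "delay_minutes")
  structure(list(effort_domains = effort_domains,
                 amounts = amounts,
                 effort_levels = effort_levels,
                 delay_minutes = delay_minutes,
                 include_zero_effort_pages = isTRUE(include_zero_effort_pages)),
            class = "edq_design")
}

#' @export
print.edq_design <- function(x, ...) {
  cat("Effort Discounting Questionnaire design\n")
  cat("  domains:      ", paste(x$effort_domains, collapse = ", "), "\n")
  cat("  amounts (PLN):", paste(x$amounts, collapse = ", "), "\n")
  cat("  effort levels:", paste(x$effort_levels, collapse = ", "), "\n")
  cat("  delay (min):  ", x$delay_minutes, "\n")
  cat("  conditions:   ", length(x$effort_domains) * length(x$amounts) *
        length(x$effort_levels),
      if (x$include_zero_effort_pages) "(+ zero-effort pages)" else "", "\n")
  invisible(x)
}

#' Enumerate the conditions of a design
#'
#' Returns the full cross product of domains, amounts and effort levels, one
#' row per questionnaire page. Zero-effort pages, when enabled in the design,
#' are appended with `effort_level = 0` and flagged `zero_effort = TRUE`; they
#' are excluded from the condition count proper.
#'
#' @param spec An [edq_design()] object.
#' @return A data.frame with columns `domain`, `amount`, `effort_level`,
#'   `zero_effort` and `page_index`.
#' @export
enumerate_conditions <- function(spec = edq_design()) {
  stopifnot(inherits(spec, "edq_design"))
  grid <- expand.grid(effort_level = spec$effort_levels,
                      amount = spec$amounts,
                      domain = spec$effort_domains,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("domain", "amount", "effort_level")]
  grid$zero_effort <- FALSE
  if (spec$include_zero_effort_pages) {
    zero <- expand.grid(amount = spec$amounts, domain = spec$effort_domains,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    zero <- data.frame(domain = zero$domain, amount = zero$amount,
                       effort_level = 0, zero_effort = TRUE,
                       stringsAsFactors = FALSE)
    grid <- rbind(grid, zero)
  }
  grid$page_index <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid
}

#' Build the titration ladder for one reward amount
#'
#' The ladder is the ordered list of effortless alternatives shown on one
#' questionnaire page, descending from 100% to 0% of the effortful amount.
#' For PLN 80 it is exactly the canonical printed 30-value list; for any other
#' amount the canonical percentage profile is rescaled and rounded half-up to
#' integer PLN.
#'
#' @param amount Reward amount of the effortful alternative (PLN, > 0).
#' @param spec An [edq_design()] object (reserved for alternative ladder
#'   profiles; the canonical profile does not depend on it).
#' @return Numeric vector of 30 effortless values, first = `amount`, last = 0.
#' @examples
#' build_ladder(80)[10]   # 56
#' build_ladder(400)[10]  # 280
#' @export
build_ladder <- function(amount, spec = edq_design()) {
  assert_scalar_number(amount, "amount")
  if (amount <= 0) {
    stop_effdisc("amount must be positive", "effdisc_invalid_amount")
  }
  round_half_up(.ladder80 / 80 * amount)
}

#' Canonical ladder percentage profile
#'
#' The 30 ladder steps expressed as fractions of the reward amount
#' (1, 0.9875, ..., 0.0125, 0).
#' @return Numeric vector of length 30.
#' @export
ladder_percent <- function() .ladder80 / 80

#' Read a design configuration file
#'
#' Reads a JSON (or YAML, if the `yaml` package is available) file whose keys
#' mirror the arguments of [edq_design()]. Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return An `edq_design` object.
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) {
    stop_effdisc(sprintf("config file not found: %s", path), "effdisc_io_error")
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_effdisc("YAML config requires the 'yaml' package", "effdisc_io_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(edq_design))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop_effdisc(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 "effdisc_schema_error")
  }
  do.call(edq_design, cfg)
}

#' Write a design configuration file (JSON)
#'
#' @param spec An `edq_design` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(spec, path) {
  stopifnot(inherits(spec, "edq_design"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
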