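#' Tidy a verdict table
#'
#' @param x an `mg_verdicts` object.
#' @param ... unused.
#' @return a plain tibble of verdict rows.
#' @method tidy mg_verdicts
#' @export
tidy.mg_verdicts <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a verdict table
#'
#' @param x an `mg_verdicts` object.
#' @param ... unused.
#' @return tibble with the number of verdicts, how many are plausible, and
#'   the range of finite log-unit gaps over the headline verdicts.
#' @method glance mg_verdicts
#' @export
glance.mg_verdicts <- function(x, ...) {
  df <- as_tibble(as.data.frame(x))
  hg <- df$log_unit_gap[df$headline & is.finite(df$log_unit_gap)]
  tibble(
    n_verdicts = nrow(df),
    n_plausible = sum(df$plausible),
    min_headline_gap = if (length(hg)) min(hg) else NA_real_,
    max_headline_gap = if (length(hg)) max(hg) else NA_real_,
    mode = attr(x, "mode") %||% NA_character_
  )
}

#' Tidy a reproduction table
#'
#' @param x an `mg_reproduction` object.
#' @param ... unused.
#' @return a plain tibble of reproduction rows.
#' @method tidy mg_reproduction
#' @export
tidy.mg_reproduction <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a reproduction table
#'
#' @param x an `mg_reproduction` object.
#' @param ... unused.
#' @return tibble counting reproduced and flagged rows.
#' @method glance mg_reproduction
#' @export
glance.mg_reproduction <- function(x, ...) {
  df <- as_tibble(as.data.frame(x))
  tibble(
    n_values = nrow(df),
    n_match = sum(df$match),
    n_flagged = sum(df$flagged),
    n_headline = sum(df$tier == "headline"),
    n_headline_match = sum(df$match[df$tier == "headline"]),
    mode = attr(x, "mode") %||% NA_character_
  )
}
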