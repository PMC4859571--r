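
# Default reference values for the Purkinje cell survival pattern, on a
# 0 (complete loss, anterior zone) to 1 (full resistance, lobule X) scale.
# Survival is strong in lobule X, absent in lobules II/III, and graded in
# between: patchy persistence through the intermediate and posterior zones
# with additional sparing toward caudal lobule IX. The intermediate values
# are a modeling choice (the qualitative pattern gives no numbers) and can be
# overridden per segment.
default_survival_values <- c(
  "II" = 0, "III" = 0,
  "VI" = 0.3, "VII" = 0.3,
  "VIII" = 0.4, "IX" = 0.6,
  "X" = 1
)

#' Reference Purkinje cell survival pattern over lobule segments
#'
#' Returns the reference spatial pattern of Purkinje cell persistence used as
#' the concordance template in candidate curation: 1 in lobule X (the most
#' resistant population), 0 in lobules II and III (the most vulnerable), and
#' graded intermediate values through lobules VI-IX.
#'
#' @param lobule_map A `lobule_map`; the pattern covers every non-background
#'   label it defines.
#' @param values Optional named numeric vector overriding the default
#'   per-segment values (all in \[0, 1\]).
#' @return A tibble with columns `label` and `survival`.
#' @examples
#' survival_pattern(default_lobule_map(c(20, 8, 6)))
#' @export
survival_pattern <- function(lobule_map, values = NULL) {
  if (!inherits(lobule_map, "lobule_map")) {
    ls_abort("lobule_map must be a lobule_map object", "bad_config")
  }
  segs <- setdiff(lobule_map$labels$label, "background")
  vals <- default_survival_values
  if (!is.null(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values)))) {
      ls_abort("survival values must be named by lobule segment", "bad_pattern")
    }
    vals[names(values)] <- values
  }
  missing <- setdiff(segs, names(vals))
  if (length(missing) > 0) {
    ls_abort(paste0("no survival value for segment(s): ",
                    paste(missing, collapse = ", ")), "missing_label")
  }
  out <- vals[segs]
  if (any(out < 0 | out > 1)) {
    ls_abort("survival values must lie in [0, 1]", "bad_pattern")
  }
  tibble(label = segs, survival = unname(out))
}
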