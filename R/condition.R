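# Plasma nutrient conditions.
#
# A condition is a named profile of plasma concentrations (mmol/L) for
# glucose, the two fatty acids and the 20 amino acids. Under the
# concentration-as-flux-proxy assumption each value is applied directly
# as the upper bound of the matching uptake exchange reaction, so all
# fluxes carry the same arbitrary time unit.

#' Create a nutrient condition
#'
#' @param name condition label (`"fasting"`, `"post_absorptive"`, or
#'   custom)
#' @param uptake_bounds named non-negative numeric vector, exchanged
#'   metabolite -> plasma concentration (mmol/L)
#' @param sd optional named vector of reported variability (recorded,
#'   never applied as a bound)
#' @return an `mf_condition`
#' @export
condition <- function(name, uptake_bounds, sd = NULL) {
  stopifnot(is.numeric(uptake_bounds), !is.null(names(uptake_bounds)))
  if (any(uptake_bounds < 0)) stop("uptake bounds must be non-negative")
  structure(list(name = name, uptake_bounds = uptake_bounds, sd = sd),
            class = "mf_condition")
}

#' @export
print.mf_condition <- function(x, ...) {
  cat("Condition '", x$name, "': ", length(x$uptake_bounds),
      " uptake bounds (mmol/L)\n", sep = "")
  invisible(x)
}

#' Canonical fasting and post-absorptive plasma profiles
#'
#' Mean plasma concentrations of glucose, palmitate, tetradecanoate and
#' the 20 amino acids in the overnight-fasted and the post-absorptive
#' (about 2 h after a protein meal) state, as shipped in
#' `inst/extdata/plasma_conditions.tsv`. Reported variability is kept in
#' the `sd` field but only the means are used as bounds.
#'
#' @param state `"fasting"` or `"post_absorptive"`
#' @param path override the packaged TSV
#' @return an `mf_condition`
#' @examples
#' plasma_condition("fasting")$uptake_bounds["methionine"]  # 0.025
#' @export
plasma_condition <- function(state = c("fasting", "post_absorptive"),
                             path = NULL) {
  state <- match.arg(state)
  if (is.null(path))
    path <- system.file("extdata", "plasma_conditions.tsv",
                        package = "muscleflux", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  condition(state,
            setNames(df[[state]], df$metabolite),
            sd = setNames(df[[paste0(state, "_sd")]], df$metabolite))
}

#' Apply a condition's uptake bounds to a model
#'
#' Sets the upper bound of each uptake exchange reaction `EX_<met>` to
#' the condition's concentration value. Exchanges the condition does not
#' list stay untouched. The uptake lower bounds stay at zero (no forced
#' uptake); secretion, where the model allows it, runs through separate
#' `SEC_` reactions.
#'
#' @param model an `mf_model`
#' @param cond an `mf_condition`
#' @param exchange_prefix prefix linking metabolites to their uptake
#'   reactions, default `"EX_"`
#' @return the bounded model
#' @export
apply_condition <- function(model, cond, exchange_prefix = "EX_") {
  stopifnot(inherits(model, "mf_model"), inherits(cond, "mf_condition"))
  for (met in names(cond$uptake_bounds)) {
    rid <- paste0(exchange_prefix, met)
    if (!(rid %in% model$reactions$id))
      stop("no uptake exchange reaction for metabolite '", met,
           "' (expected reaction id '", rid, "')")
    model <- set_bounds(model, rid, upper = cond$uptake_bounds[[met]])
  }
  model
}
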