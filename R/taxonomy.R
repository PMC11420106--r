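# Behavioral class taxonomy shared by every stage of the pipeline.

#' Core behavioral classes
#'
#' The six broad classes of the wild-boar ethogram: `Walk`, `Forage`, `Rest`,
#' `Run`, `Stand`, and `Other`. `Other` is a heterogeneous catch-all used when
#' a behavior fits none of the five classes of interest.
#'
#' @return Character vector of the six core class names, in canonical order.
#' @seealso [subclass_parents()], [collapse_classes()]
#' @export
core_classes <- function() {
  c("Walk", "Forage", "Rest", "Run", "Stand", "Other")
}

#' Higher-resolution subclasses and their parents
#'
#' Three higher-resolution classes are nested within core classes:
#' `Root` within `Forage`, `Trot` within `Run`, and `Vigilance` within
#' `Stand`. Collapsing a subclass always yields its parent.
#'
#' @return Named character vector mapping subclass name to parent class name.
#' @export
subclass_parents <- function() {
  c(Root = "Forage", Trot = "Run", Vigilance = "Stand")
}

#' All recognized behavioral class names
#'
#' @param expanded If `FALSE`, only the six core classes.
#' @return Character vector of class names.
#' @export
all_classes <- function(expanded = TRUE) {
  if (expanded) c(core_classes(), names(subclass_parents())) else core_classes()
}

#' Test whether names are valid behavioral classes
#'
#' @param x Character vector of candidate class names.
#' @return Logical vector.
#' @export
is_behavior_class <- function(x) {
  x %in% all_classes()
}

#' Collapse subclasses into their parent classes
#'
#' Maps `Root` to `Forage`, `Trot` to `Run`, and `Vigilance` to `Stand`;
#' core classes pass through unchanged.
#'
#' @param x Character vector of class names.
#' @return Character vector of the same length with subclasses replaced by
#'   their parents.
#' @export
collapse_classes <- function(x) {
  map <- subclass_parents()
  out <- as.character(x)
  hit <- out %in% names(map)
  out[hit] <- unname(map[out[hit]])
  out
}

#' Default minimum event durations (seconds)
#'
#' Minimum durations enforced during event post-processing, per class:
#' Forage 5 (Root 3), Rest 120, Run 3 (Trot 3), Stand 2 (Vigilance 2),
#' Other 1. Walk has no published minimum; the default of 1 s is a
#' package choice and is configurable.
#'
#' @return Named numeric vector of seconds per class.
#' @export
default_min_durations <- function() {
  c(Walk = 1, Forage = 5, Root = 3, Rest = 120, Run = 3, Trot = 3,
    Stand = 2, Vigilance = 2, Other = 1)
}

#' Default dead-reckoning speed coefficients (m/s)
#'
#' Per-class travel speeds used to scale dead-reckoning step vectors.
#' Speed coefficients are user-defined quantities; these defaults are
#' plausible magnitudes for adult wild boar and should be replaced with
#' ground-truthed values whenever available.
#'
#' @return Named numeric vector of speeds (m/s) per class.
#' @export
default_speed_coefficients <- function() {
  c(Walk = 1.0, Forage = 0.1, Root = 0.1, Rest = 0, Run = 3.0, Trot = 2.0,
    Stand = 0, Vigilance = 0, Other = 0.3)
}

# Internal: order a set of class names canonically (core order, then
# subclasses in their canonical order), dropping unknowns is the caller's job.
canonical_class_order <- function(x) {
  ref <- all_classes()
  x[order(match(x, ref))]
}
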