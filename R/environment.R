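## Experimental environments.
##
## The simulated extracellular milieu is specified per stimulus as a
## qualitative category; per-simulation activity levels are drawn from the
## category's subrange ("randomized" mode, reflecting levels randomly
## selected between 0 and 100) or pinned to a representative value
## ("fixed" mode, used for single-variable dose-response sweeps).

CATEGORY_RANGES <- list(
  Zero      = c(0, 0),
  Low       = c(0, 100 / 3),
  Med       = c(100 / 3, 200 / 3),
  MedHigh   = c(50, 250 / 3),
  High      = c(200 / 3, 100),
  FullRange = c(0, 100)
)

CATEGORY_FIXED <- c(
  Zero = 0, Low = 25, Med = 50, MedHigh = 75, High = 90, FullRange = 50
)

## The three tissue conditions: stimulus categories per condition.
## Disease A is a globally immunosuppressive milieu; disease B varies the
## degree of immunosuppression through the full range of IL-10.
TISSUE_CONDITIONS <- local({
  tab <- c(
    # stimulus,     WT,   DiseaseA,  DiseaseB
    "Alpha_13L",   "Med", "High",    "High",
    "GalphaS_L",   "Med", "High",    "High",
    "APC",         "Med", "High",    "High",
    "CGC",         "Med", "MedHigh", "MedHigh",
    "ECM",         "High","High",    "High",
    "GP130",       "Zero","Zero",    "Zero",
    "IFNB",        "Med", "Med",     "Med",
    "IFNG",        "Med", "Med",     "Med",
    "IFNGR1",      "Med", "Med",     "Med",
    "IFNGR2",      "Med", "Med",     "Med",
    "IL10",        "Med", "High",    "FullRange",
    "IL10RA",      "Med", "High",    "High",
    "IL10RB",      "Med", "Med",     "Med",
    "IL12",        "Med", "High",    "High",
    "IL15",        "Med", "High",    "High",
    "IL15RA",      "Med", "High",    "High",
    "IL18",        "Med", "High",    "High",
    "IL21",        "Med", "High",    "High",
    "IL22",        "Med", "High",    "High",
    "IL23",        "Med", "High",    "High",
    "IL27",        "Med", "High",    "High",
    "IL27RA",      "Med", "Med",     "Med",
    "IL2",         "Med", "High",    "High",
    "IL2RB",       "Med", "High",    "High",
    "IL4",         "Low", "Low",     "Low",
    "IL6",         "Low", "Low",     "Low",
    "IL6RA",       "Low", "Low",     "Low",
    "IL9",         "Low", "Low",     "Low",
    "TGFB",        "Low", "Low",     "Low"
  )
  m <- matrix(tab, ncol = 4, byrow = TRUE)
  out <- list(
    Tissue_WT = stats::setNames(m[, 2], m[, 1]),
    Tissue_DiseaseA = stats::setNames(m[, 3], m[, 1]),
    Tissue_DiseaseB = stats::setNames(m[, 4], m[, 1])
  )
  out
})

#' Available tissue conditions
#'
#' @return Character vector of condition names accepted by
#'   [build_environment()].
#' @export
tissue_conditions <- function() names(TISSUE_CONDITIONS)

#' Build an environment specification for a tissue condition
#'
#' Returns the per-stimulus activity categories of the requested condition:
#' wild-type tissue, or one of the two simulated immunosuppressive disease
#' milieus (disease A: broadly elevated suppressive stimuli; disease B:
#' IL-10 varied over the full 0-100 range).
#'
#' @param condition_name One of [tissue_conditions()].
#' @param node_map Optional named character vector renaming stimuli onto
#'   network input nodes (default maps the `Alpha_13L` stimulus onto the
#'   `Galpha12_13_L` input of the reference model).
#' @return A list of class `environment_spec` with `condition`,
#'   `categories` (stimulus -> category) and `node_map`.
#' @export
build_environment <- function(condition_name,
                              node_map = c(Alpha_13L = "Galpha12_13_L")) {
  if (!condition_name %in% names(TISSUE_CONDITIONS)) {
    stop(sprintf("unknown condition '%s'; valid conditions: %s",
                 condition_name,
                 paste(names(TISSUE_CONDITIONS), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(
    condition = condition_name,
    categories = TISSUE_CONDITIONS[[condition_name]],
    node_map = node_map
  ), class = "environment_spec")
}

#' Category level ranges
#'
#' @param category Category name (`Zero`, `Low`, `Med`, `MedHigh`, `High`,
#'   `FullRange`).
#' @return Numeric `c(lower, upper)` of the randomized-mode subrange.
#' @export
category_range <- function(category) {
  r <- CATEGORY_RANGES[[category]]
  if (is.null(r)) stop(sprintf("unknown category '%s'", category),
                       call. = FALSE)
  r
}

#' Draw activity levels from an environment specification
#'
#' In `"randomized"` mode (the default used for experiments) each
#' stimulus's level is drawn uniformly from its category subrange; in
#' `"fixed"` mode the category's representative value is used. Stimulus
#' names are mapped onto network input names through the spec's `node_map`.
#'
#' @param spec An `environment_spec` from [build_environment()].
#' @param level_mode `"randomized"` or `"fixed"`.
#' @return Named numeric vector of levels in `[0, 100]` (names are network
#'   input node names). Uses the current RNG state; seed with `set.seed()`.
#' @export
sample_environment <- function(spec, level_mode = c("randomized", "fixed")) {
  stopifnot(inherits(spec, "environment_spec"))
  level_mode <- match.arg(level_mode)
  cats <- spec$categories
  levels <- vapply(cats, function(cat) {
    if (level_mode == "fixed") {
      CATEGORY_FIXED[[cat]]
    } else {
      r <- category_range(cat)
      if (r[[1]] == r[[2]]) r[[1]] else stats::runif(1, r[[1]], r[[2]])
    }
  }, numeric(1))
  nm <- names(cats)
  mapped <- names(spec$node_map)
  hit <- nm %in% mapped
  nm[hit] <- unname(spec$node_map[nm[hit]])
  names(levels) <- nm
  levels
}

#' Complete an environment assignment for a network
#'
#' Restricts/extends drawn stimulus levels to the external nodes of a
#' network: external nodes without a drawn level default to `default`
#' (stimuli absent from the network are dropped).
#'
#' @param levels Named numeric vector from [sample_environment()].
#' @param network A `logical_network`.
#' @param default Level for unmapped external nodes (default 0).
#' @return Named numeric vector covering exactly the network's external
#'   nodes.
#' @export
env_assignment_for_network <- function(levels, network, default = 0) {
  ext <- network_nodes(network, "external")
  out <- stats::setNames(rep(default, length(ext)), ext)
  hit <- intersect(names(levels), ext)
  out[hit] <- levels[hit]
  out
}
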