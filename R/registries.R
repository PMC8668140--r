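#' Brain region registry
#'
#' The eleven brain regions sampled for Fos immunoreactivity, in canonical
#' order: ventromedial prefrontal cortex (vmPFC), agranular insular cortex
#' (aIC), granular insular cortex layers 5/6 (gIC5/6) and layer 4 (gIC4),
#' nucleus accumbens core (NAcC) and shell (NAcS), supraoptic nucleus (SON),
#' basolateral amygdala (BLA), central nucleus of the amygdala (CeA),
#' paraventricular nucleus of the hypothalamus (PVN), and ventral tegmental
#' area (VTA). All matrices, edge lists and tables emitted by the package
#' order regions by this registry.
#'
#' @return Character vector of 11 region codes.
#' @export
#' @examples
#' region_registry()
region_registry <- function() {
  c("vmPFC", "aIC", "gIC5/6", "gIC4", "NAcC", "NAcS",
    "SON", "BLA", "CeA", "PVN", "VTA")
}

# input aliases seen in the literature for the same structures
.region_synonyms <- c(
  "gICL4"   = "gIC4",
  "gICL5/6" = "gIC5/6",
  "gIC5-6"  = "gIC5/6",
  "VTA/PBP" = "VTA",
  "NACc"    = "NAcC",
  "NACs"    = "NAcS"
)

#' Normalize region codes
#'
#' Maps known synonyms (e.g. `"gICL4"`) onto the canonical registry codes.
#' Unknown codes are returned unchanged so that validation can report them.
#'
#' @param region Character vector of region codes.
#' @return Character vector of the same length with synonyms replaced.
#' @export
normalize_region <- function(region) {
  hit <- region %in% names(.region_synonyms)
  region[hit] <- unname(.region_synonyms[region[hit]])
  region
}

#' Experimental condition registry
#'
#' The six experimental conditions and the experimental arm each belongs to.
#' The acute arm probes responses to single stimuli: AN (acute NaCl
#' injection, control), AB (acute Boost), AL (acute LiCl). The task arm
#' probes conditioned responses on test day: COT (context-only task control),
#' BOT (Boost previously paired with NaCl), BLT (Boost previously paired with
#' LiCl, i.e. the conditioned-taste-aversion expression condition).
#'
#' @return A tibble with columns `condition` and `arm` (`"acute"` or
#'   `"task"`), six rows in canonical order.
#' @export
#' @examples
#' condition_registry()
condition_registry <- function() {
  tibble::tibble(
    condition = c("AN", "AB", "AL", "COT", "BOT", "BLT"),
    arm = c("acute", "acute", "acute", "task", "task", "task")
  )
}

#' @rdname condition_registry
#' @export
condition_codes <- function() condition_registry()$condition

#' Task conditions typically compared against the context-only control
#' @return Character vector `c("BOT", "BLT")`.
#' @export
task_conditions <- function() c("BOT", "BLT")

# Default LiCl doses (mg/kg) used in the dose-response design; 38 mg/kg is
# the conditioning dose for the task arm.
.default_doses <- c(0, 19, 38, 80)
.conditioning_dose <- 38

#' Conditioning and dose-response constants
#'
#' @return `licl_doses()` gives the dose-response LiCl doses in mg/kg
#'   (0 denotes the NaCl control injection); `conditioning_dose()` gives the
#'   dose used to condition the task arm.
#' @export
licl_doses <- function() .default_doses

#' @rdname licl_doses
#' @export
conditioning_dose <- function() .conditioning_dose
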