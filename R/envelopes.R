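#' Environmental envelopes of the major tropical Atlantic water masses
#'
#' Per-layer ranges of the physical and chemical variables used by the
#' synthetic transect generator.  Each water-mass layer carries three labels:
#' `layer` (the sampled depth horizon), `water_mass` (the hydrographic unit
#' used for succession analysis, pooling the upper/middle/lower North
#' Atlantic Deep Water sub-layers into "NADW"), and `group` (the coarser
#' grouping used for OTU incidence summaries: Subsurface, Intermediate,
#' NADW, AABW).  Nutrient values reported as below detection are coded 0.
#'
#' @return A data.frame with one row per depth layer and columns
#'   `layer`, `water_mass`, `group`, `depth_min`, `depth_max` (m) and
#'   `<var>_min` / `<var>_max` for temperature (degrees C), salinity (PSS),
#'   oxygen, nitrate, nitrite, ammonia, phosphate and silicate
#'   (all in umol kg^-1).
#' @export
#' @examples
#' water_mass_envelopes()[, 1:5]
water_mass_envelopes <- function() {
  data.frame(
    layer       = c("Subsurface", "SACW-OMZ", "SACW", "AAIW",
                    "uNADW", "mNADW", "lNADW", "AABW"),
    water_mass  = c("Subsurface", "SACW-OMZ", "SACW", "AAIW",
                    "NADW", "NADW", "NADW", "AABW"),
    group       = c("Subsurface", "Intermediate", "Intermediate",
                    "Intermediate", "NADW", "NADW", "NADW", "AABW"),
    depth_min   = c(100, 250, 500, 750, 1750, 2750, 3750, 4500),
    depth_max   = c(100, 250, 500, 750, 1750, 2750, 4000, 7000),
    temperature_min = c(14.2, 11.0, 6.4, 4.7, 3.8, 2.4, 2.1, 1.0),
    temperature_max = c(15.9, 12.5, 7.7, 5.1, 4.0, 2.8, 2.4, 1.4),
    salinity_min    = c(35.4, 35.1, 34.5, 34.4, 35.0, 34.9, 34.9, 34.8),
    salinity_max    = c(35.7, 35.2, 34.6, 34.5, 35.0, 35.0, 34.9, 34.8),
    oxygen_min      = c(100.9, 84.3, 131.1, 145.5, 235.2, 238.1, 245.2, 222.9),
    oxygen_max      = c(170.3, 106.2, 168.6, 165.1, 247.6, 246.6, 254.2, 229.0),
    nitrate_min     = c(11.03, 24.20, 29.81, 33.20, 19.28, 20.76, 19.56, 27.19),
    nitrate_max     = c(22.09, 29.43, 30.93, 34.42, 20.21, 21.71, 21.42, 29.26),
    nitrite_min     = c(0.03, 0.01, 0.01, 0.00, 0.00, 0.00, 0.00, 0.01),
    nitrite_max     = c(0.13, 0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.12),
    ammonia_min     = c(0.00, 0.00, 0.01, 0.01, 0.00, 0.01, 0.01, 0.01),
    ammonia_max     = c(0.01, 0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    phosphate_min   = c(0.84, 1.55, 2.01, 2.23, 1.27, 1.37, 1.32, 1.86),
    phosphate_max   = c(1.41, 1.83, 2.03, 2.32, 1.33, 1.45, 1.48, 2.01),
    silicate_min    = c(4.31, 9.30, 18.22, 27.65, 16.21, 30.94, 32.61, 82.74),
    silicate_max    = c(7.14, 11.79, 19.08, 29.31, 17.71, 40.92, 45.18, 94.47),
    stringsAsFactors = FALSE
  )
}

# environmental variables drawn from the envelope table
env_variables <- function() {
  c("temperature", "salinity", "oxygen", "nitrate", "nitrite",
    "ammonia", "phosphate", "silicate")
}
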