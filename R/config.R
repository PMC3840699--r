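#' Configuration of a synthetic transect scenario
#'
#' Bundles and validates all parameters of the synthetic deep-ocean transect
#' generator.  Defaults describe an 18-station trans-oceanic fracture-zone
#' transect plus 9 off-path stations, seven to eight depth layers with
#' water-mass-specific environmental envelopes, a bacterial OTU pool of 116
#' terminal-restriction-fragment types of which 18\% are shared by all
#' water-mass groups and 22\% are confined to a single group, and a gradual
#' along-path community turnover restricted to the NADW layers.
#'
#' @param n_stations_transect Number of stations along the fracture-zone
#'   transect (default 18).
#' @param n_stations_offpath Number of stations continuing the flow path
#'   beyond the eastern exit (default 9).
#' @param layers Ordered character vector of depth-layer labels; must be a
#'   subset of `water_mass_envelopes()$layer`.
#' @param otu_pool_size Total number of OTUs (distinct T-RF types) in the
#'   regional pool (default 116, the bacterial pool size; use 25 for an
#'   archaeal analogue).
#' @param frac_ubiquitous Fraction of the pool present in every water-mass
#'   group (default 0.18).
#' @param frac_unique Fraction of the pool confined to exactly one
#'   water-mass group (default 0.22).
#' @param succession_layer Water-mass label whose community turns over along
#'   the flow path (default "NADW", which covers the uNADW/mNADW/lNADW
#'   sub-layers jointly).
#' @param succession_rate Fraction of the succession-layer community
#'   replaced per km of along-path distance (>= 0; default 3e-4, i.e. 60\%
#'   turnover across a 2000-km transect).
#' @param abundance_model "lognormal" (default) or "logseries" relative
#'   abundance distribution for the layer base communities.
#' @param abundance_sigma sdlog of the lognormal abundance model
#'   (default 1).
#' @param logseries_p Parameter of the logarithmic-series abundance model in
#'   (0, 1) (default 0.95), used when `abundance_model = "logseries"`.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   peak-height noise applied per sample (default 0.2).
#' @param transect_length_km Along-path length of the transect (default
#'   2000 km); off-path stations continue at the same spacing.
#' @param amplicon_length Length in bp of the synthetic amplicons
#'   (default 1000).
#' @param trf_range Integer range (min, max) of achievable forward terminal
#'   restriction fragment lengths in bp (default c(34, 966)).
#' @param seed Integer seed from which all of the scenario's randomness is
#'   derived (default 1).
#' @return An object of class `scenario_config` (a validated list).
#' @export
#' @examples
#' cfg <- scenario_config(otu_pool_size = 30, seed = 42)
#' cfg$frac_ubiquitous
scenario_config <- function(n_stations_transect = 18L,
                            n_stations_offpath = 9L,
                            layers = water_mass_envelopes()$layer,
                            otu_pool_size = 116L,
                            frac_ubiquitous = 0.18,
                            frac_unique = 0.22,
                            succession_layer = "NADW",
                            succession_rate = 3e-4,
                            abundance_model = c("lognormal", "logseries"),
                            abundance_sigma = 1,
                            logseries_p = 0.95,
                            noise_cv = 0.2,
                            transect_length_km = 2000,
                            amplicon_length = 1000L,
                            trf_range = c(34L, 966L),
                            seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  cfg <- list(
    n_stations_transect = as.integer(n_stations_transect),
    n_stations_offpath  = as.integer(n_stations_offpath),
    layers              = as.character(layers),
    otu_pool_size       = as.integer(otu_pool_size),
    frac_ubiquitous     = as.numeric(frac_ubiquitous),
    frac_unique         = as.numeric(frac_unique),
    succession_layer    = as.character(succession_layer),
    succession_rate     = as.numeric(succession_rate),
    abundance_model     = abundance_model,
    abundance_sigma     = as.numeric(abundance_sigma),
    logseries_p         = as.numeric(logseries_p),
    noise_cv            = as.numeric(noise_cv),
    transect_length_km  = as.numeric(transect_length_km),
    amplicon_length     = as.integer(amplicon_length),
    trf_range           = as.integer(trf_range),
    seed                = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  env <- water_mass_envelopes()
  if (cfg$n_stations_transect < 2)
    stop("need at least 2 transect stations", call. = FALSE)
  if (cfg$n_stations_offpath < 0)
    stop("n_stations_offpath must be >= 0", call. = FALSE)
  if (!all(cfg$layers %in% env$layer))
    stop("unknown layer label(s): ",
         paste(setdiff(cfg$layers, env$layer), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cfg$layers))
    stop("duplicated layer labels", call. = FALSE)
  if (cfg$frac_ubiquitous < 0 || cfg$frac_ubiquitous > 1 ||
      cfg$frac_unique < 0 || cfg$frac_unique > 1)
    stop("sharing fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$frac_ubiquitous + cfg$frac_unique > 1)
    stop("infeasible sharing fractions: frac_ubiquitous + frac_unique > 1",
         call. = FALSE)
  if (cfg$otu_pool_size < length(cfg$layers))
    stop("otu_pool_size must be >= number of layers", call. = FALSE)
  wm <- env$water_mass[match(cfg$layers, env$layer)]
  if (!cfg$succession_layer %in% wm)
    stop("succession_layer '", cfg$succession_layer,
         "' matches none of the configured layers", call. = FALSE)
  if (cfg$succession_rate < 0 || cfg$noise_cv < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (cfg$abundance_sigma < 0)
    stop("abundance_sigma must be >= 0", call. = FALSE)
  if (cfg$logseries_p <= 0 || cfg$logseries_p >= 1)
    stop("logseries_p must lie in (0, 1)", call. = FALSE)
  if (cfg$transect_length_km <= 0)
    stop("transect_length_km must be positive", call. = FALSE)
  if (length(cfg$trf_range) != 2L || cfg$trf_range[1] >= cfg$trf_range[2])
    stop("trf_range must be (min, max) with min < max", call. = FALSE)
  if (cfg$trf_range[2] > cfg$amplicon_length)
    stop("trf_range must lie within the amplicon length", call. = FALSE)
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic transect scenario configuration\n")
  cat("  stations: ", x$n_stations_transect, " transect + ",
      x$n_stations_offpath, " off-path\n", sep = "")
  cat("  layers:   ", paste(x$layers, collapse = ", "), "\n", sep = "")
  cat("  OTU pool: ", x$otu_pool_size,
      " (ubiquitous ", round(100 * x$frac_ubiquitous), "%, unique ",
      round(100 * x$frac_unique), "%)\n", sep = "")
  cat("  succession: ", x$succession_layer, " at ", x$succession_rate,
      " per km; noise CV ", x$noise_cv, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Derive a stream-specific 31-bit sub-seed from the scenario seed.
# Fixed ordering of streams keeps all draws reproducible across platforms.
derive_seed <- function(seed, stream) {
  offsets <- c(otus = 11L, sequences = 23L, communities = 37L,
               metadata = 53L, noise = 71L, clones = 89L,
               relate = 101L, bootstrap = 131L, ancova = 151L,
               pipeline = 173L)
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483647)
}
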