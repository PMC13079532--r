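# Catchment configuration: two reaches in series (C1 upstream, snow-affected;
# C2 downstream, urbanized, receiving a continuous WWTP point source), five
# land-cover types, and per-land-cover hydrological and carbon parameters.

.LAND_COVERS <- c("urban", "agriculture", "broadleaf_forest",
                  "coniferous_forest", "sparse")
.HYDRO_PARS <- c("T_snow", "DDF", "a_pet", "C_soil", "beta_q", "tau_q", "tau_s")
.CARBON_PARS <- c("k_p", "Q10", "T_ref", "k_sorb", "k_min", "k_min_m",
                  "I_litter")
.POOLS <- c("SOC_o", "SOC_m", "D")
.STATE_VARS <- c("snow", "S", "Sq", "Ss", "SOC_o", "SOC_m", "D")

#' Default two-reach catchment configuration
#'
#' A fixture configuration for a mixed rainfall-snowmelt Mediterranean
#' catchment: reach C1 (upstream, forested, colder) drains into reach C2
#' (downstream, more urban/agricultural) which receives a continuous WWTP
#' point source of 12 mg L^-1 DOC at 0.13 m^3 s^-1. Parameters are chosen to
#' reproduce qualitative dynamics (summer low flow, autumn DOC flush, slow
#' carbon-pool memory), not any specific river's calibrated values. Carbon
#' pools represent the labile, DOC-producing fraction of soil organic carbon.
#'
#' Hydrological parameters per land cover: `T_snow` (degC rain/snow split),
#' `DDF` (degree-day melt factor, mm degC^-1 d^-1), `a_pet` (PET coefficient,
#' mm degC^-1 d^-1), `C_soil` (soil water capacity, mm), `beta_q` (quickflow
#' fraction of effective rainfall), `tau_q`, `tau_s` (linear-reservoir
#' residence times, days, >= 1). Carbon parameters: `k_p` (DOC production
#' rate, d^-1), `Q10`/`T_ref` (temperature sensitivity), `k_sorb` (sorption
#' to the mineral layer, d^-1), `k_min` (dissolved mineralization, d^-1),
#' `k_min_m` (slow mineral-layer mineralization, d^-1), `I_litter` (litter
#' input to the labile organic pool, g C m^-2 d^-1).
#'
#' @return list of class `catchment_config`.
#' @export
default_catchment_config <- function() {
  hydro <- data.frame(
    T_snow = c(0, 0, 0, 0, 0),
    DDF    = c(3, 3, 3, 3, 4),
    a_pet  = c(0.12, 0.16, 0.18, 0.17, 0.14),
    C_soil = c(60, 150, 200, 180, 80),
    beta_q = c(0.85, 0.55, 0.40, 0.40, 0.70),
    tau_q  = c(1.5, 3, 4, 4, 2),
    tau_s  = c(30, 50, 70, 70, 40),
    row.names = .LAND_COVERS)
  carbon <- data.frame(
    k_p      = rep(0.004, 5),
    Q10      = rep(2, 5),
    T_ref    = rep(12, 5),
    k_sorb   = rep(0.05, 5),
    k_min    = rep(0.03, 5),
    k_min_m  = rep(2e-4, 5),
    I_litter = c(0.006, 0.018, 0.030, 0.035, 0.010),
    row.names = .LAND_COVERS)
  # near the model equilibrium for the default parameters under the default
  # synthetic climate, so warm-up drift diagnostics start close to converged
  init_pools <- data.frame(
    SOC_o = c(2.0, 5.9, 10.0, 11.5, 3.4),
    SOC_m = c(16, 54, 91, 105, 28),
    D     = c(0.05, 0.15, 0.27, 0.31, 0.08),
    row.names = .LAND_COVERS)
  cfg <- list(
    land_covers = .LAND_COVERS,
    reaches = list(
      C1 = list(area_km2 = 1200,
                shares = c(urban = 0.02, agriculture = 0.10,
                           broadleaf_forest = 0.25, coniferous_forest = 0.45,
                           sparse = 0.18),
                point_sources = list(),
                c_gw = 2.0, instream_loss = 0.0),
      C2 = list(area_km2 = 1810,
                shares = c(urban = 0.10, agriculture = 0.40,
                           broadleaf_forest = 0.20, coniferous_forest = 0.25,
                           sparse = 0.05),
                point_sources = list(list(conc_mg_l = 12, flow_m3_s = 0.13)),
                c_gw = 2.5, instream_loss = 0.05)),
    hydro = hydro, carbon = carbon, init_pools = init_pools)
  class(cfg) <- "catchment_config"
  validate_catchment_config(cfg)
  cfg
}

#' Validate a catchment configuration
#'
#' Checks areas, land-cover shares (sum to 1 within 1e-9), point sources and
#' parameter admissibility; errors on violation.
#' @param config a `catchment_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_catchment_config <- function(config) {
  stopifnot(is.list(config$reaches), length(config$reaches) >= 1)
  lc <- config$land_covers
  for (nm in names(config$reaches)) {
    r <- config$reaches[[nm]]
    if (!(r$area_km2 > 0)) stop("reach area must be > 0: ", nm)
    s <- r$shares[lc]
    if (any(is.na(s)) || any(s < 0) || any(s > 1) ||
        abs(sum(s) - 1) > 1e-9)
      stop("land-cover shares of ", nm, " must lie in [0,1] and sum to 1")
    for (ps in r$point_sources)
      if (ps$flow_m3_s < 0 || ps$conc_mg_l < 0)
        stop("point-source flow and concentration must be >= 0")
    if (r$instream_loss < 0 || r$instream_loss > 1)
      stop("instream_loss must lie in [0,1]")
  }
  h <- config$hydro[lc, ]
  if (any(h$C_soil <= 0) || any(h$DDF < 0) || any(h$a_pet < 0) ||
      any(h$beta_q < 0 | h$beta_q > 1) || any(h$tau_q < 1) ||
      any(h$tau_s < 1))
    stop("hydrological parameter out of admissible range")
  cb <- config$carbon[lc, ]
  if (any(cb$Q10 <= 0) || any(cb$k_p < 0) || any(cb$k_sorb < 0) ||
      any(cb$k_min < 0) || any(cb$k_min_m < 0) || any(cb$I_litter < 0))
    stop("carbon parameter out of admissible range")
  if (any(as.matrix(config$init_pools[lc, ]) < 0))
    stop("initial pools must be >= 0")
  invisible(config)
}

#' Write/read a catchment configuration as YAML
#' @param config a `catchment_config`.
#' @param path file path.
#' @export
write_catchment_config <- function(config, path) {
  enc <- list(
    land_covers = config$land_covers,
    reaches = lapply(config$reaches, function(r)
      list(area_km2 = r$area_km2, shares = as.list(r$shares),
           point_sources = r$point_sources, c_gw = r$c_gw,
           instream_loss = r$instream_loss)),
    hydro = lapply(split(config$hydro, rownames(config$hydro)), as.list),
    carbon = lapply(split(config$carbon, rownames(config$carbon)), as.list),
    init_pools = lapply(split(config$init_pools, rownames(config$init_pools)),
                        as.list))
  yaml::write_yaml(enc, path)
  invisible(path)
}

#' @rdname write_catchment_config
#' @export
read_catchment_config <- function(path) {
  enc <- yaml::read_yaml(path)
  lc <- unlist(enc$land_covers)
  df_from <- function(x) {
    d <- do.call(rbind, lapply(lc, function(l) as.data.frame(x[[l]])))
    rownames(d) <- lc
    d
  }
  cfg <- list(
    land_covers = lc,
    reaches = lapply(enc$reaches, function(r)
      list(area_km2 = r$area_km2, shares = unlist(r$shares)[lc],
           point_sources = r$point_sources, c_gw = r$c_gw,
           instream_loss = r$instream_loss)),
    hydro = df_from(enc$hydro), carbon = df_from(enc$carbon),
    init_pools = df_from(enc$init_pools))
  class(cfg) <- "catchment_config"
  validate_catchment_config(cfg)
  cfg
}

#' Default (cold-start) model state
#'
#' One row per reach x land-cover unit; columns `snow, S, Sq, Ss` (mm) and
#' `SOC_o, SOC_m, D` (g C m^-2). Soil water starts half full; carbon pools at
#' the configuration's initial values.
#'
#' @param config a `catchment_config`.
#' @return a `model_state` matrix with rownames `reach.landcover`.
#' @export
default_model_state <- function(config) {
  lc <- config$land_covers
  rn <- unlist(lapply(names(config$reaches), function(r) paste(r, lc, sep = ".")))
  st <- matrix(0, nrow = length(rn), ncol = length(.STATE_VARS),
               dimnames = list(rn, .STATE_VARS))
  st[, "S"] <- rep(config$hydro[lc, "C_soil"] * 0.5, length(config$reaches))
  st[, "Sq"] <- 1
  st[, "Ss"] <- 20
  st[, .POOLS] <- as.matrix(config$init_pools[lc, ])[
    rep(seq_along(lc), length(config$reaches)), ]
  class(st) <- c("model_state", class(st))
  st
}
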