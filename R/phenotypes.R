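#' Names of the eight plot-level maize traits
#' @return character vector of trait column names
#' @export
trait_names <- function() {
  c("dry_stalk_biomass", "cob_biomass", "dry_grain_yield", "harvest_index",
    "grain_nute", "grain_n", "total_plant_n", "grain_density")
}

#' Derive plot-level maize phenotypes from per-plant field measurements
#'
#' Implements the standard end-of-season trait formulas. Per-plant biomass
#' components (g/plant) are scaled to area densities (kg/ha) by the number of
#' standing plants and the plot area; grain protein is converted to grain
#' nitrogen with the Jones factor 6.25; total plant nitrogen is the sum of
#' stalk and grain nitrogen; grain nitrogen utilization efficiency (NutE) is
#' grain biomass per unit of whole-plant nitrogen mass.
#'
#' All arguments are vectorized over plots.
#'
#' @param stalk_g_per_plant,cob_g_per_plant,grain_g_per_plant dry biomass
#'   components, g/plant (>= 0)
#' @param stalk_n_pct stalk nitrogen concentration, percent of dry mass
#' @param grain_protein_pct grain protein concentration, percent of dry mass
#' @param standing_plants number of plants in the plot (> 0)
#' @param plot_area_ha plot area in hectares (> 0)
#' @param grain_density optional measured grain density (unitless); not
#'   derivable from biomass, carried through as-is
#' @return data.frame with the eight trait columns of [trait_names()]
#' @export
derive_phenotypes <- function(stalk_g_per_plant, cob_g_per_plant,
                              grain_g_per_plant, stalk_n_pct,
                              grain_protein_pct, standing_plants,
                              plot_area_ha, grain_density = NA_real_) {
  args <- list(stalk_g_per_plant, cob_g_per_plant, grain_g_per_plant,
               stalk_n_pct, grain_protein_pct, standing_plants)
  if (any(vapply(args, function(a) any(a < 0), logical(1))))
    stop("all inputs must be >= 0")
  if (any(plot_area_ha <= 0)) stop("plot_area_ha must be > 0")
  total_g <- stalk_g_per_plant + cob_g_per_plant + grain_g_per_plant
  if (any(total_g == 0))
    stop("harvest index undefined: total per-plant biomass is zero")

  # g/plant -> kg/ha
  to_kg_ha <- standing_plants / plot_area_ha / 1000
  grain_n_g <- (grain_protein_pct / 6.25) / 100 * grain_g_per_plant
  stalk_n_g <- (stalk_n_pct / 100) * stalk_g_per_plant
  plant_n_g <- stalk_n_g + grain_n_g

  data.frame(
    dry_stalk_biomass = stalk_g_per_plant * to_kg_ha,
    cob_biomass = cob_g_per_plant * to_kg_ha,
    dry_grain_yield = grain_g_per_plant * to_kg_ha,
    harvest_index = grain_g_per_plant / total_g,
    grain_nute = ifelse(plant_n_g > 0, grain_g_per_plant / plant_n_g, NA_real_),
    grain_n = grain_n_g * to_kg_ha,
    total_plant_n = plant_n_g * to_kg_ha,
    grain_density = grain_density
  )
}

#' Default treatment-effect specification for the trait sampler
#'
#' Per-plant latent components are drawn from a multivariate normal with
#' treatment-specific means, a shared correlation structure among the biomass
#' components and nitrogen concentrations, and truncation at biologically
#' sensible floors. The defaults are calibrated so a ~370-plot trial exhibits
#' the canonical end-of-season structure: bimodal yield and nitrogen traits
#' (driven by the fertilizer contrast), positively correlated biomass
#' components, and a narrow left-skewed grain density.
#'
#' @param effect_scale multiplier on the low-vs-high treatment separation;
#'   0 removes the treatment effect entirely
#' @return list with elements `mean_low`, `mean_high`, `sd`, `corr`,
#'   `standing_plants`, `plot_area_ha`, `grain_density` (gamma shape/scale
#'   and offset of the left-skew construction)
#' @export
default_effect_spec <- function(effect_scale = 1) {
  nm <- c("stalk_g", "cob_g", "grain_g", "stalk_n_pct", "protein_pct")
  base <- c(stalk_g = 94, cob_g = 21.3, grain_g = 104,
            stalk_n_pct = 0.60, protein_pct = 8.3)
  half <- c(stalk_g = 16, cob_g = 3.75, grain_g = 42,
            stalk_n_pct = 0.15, protein_pct = 1.5) * effect_scale
  corr <- matrix(c(
    1.00, 0.60, 0.55, 0.25, 0.20,
    0.60, 1.00, 0.60, 0.20, 0.20,
    0.55, 0.60, 1.00, 0.25, 0.35,
    0.25, 0.20, 0.25, 1.00, 0.50,
    0.20, 0.20, 0.35, 0.50, 1.00), 5, 5, dimnames = list(nm, nm))
  list(mean_low = base - half, mean_high = base + half,
       sd = c(stalk_g = 25, cob_g = 5.5, grain_g = 18,
              stalk_n_pct = 0.08, protein_pct = 0.60),
       corr = corr,
       standing_plants = 28L,
       plot_area_ha = 4.05e-4,
       grain_density = list(offset = 1.36, shape = 5.6, scale = 0.016,
                            lo = 1.00, hi = 1.355))
}

#' Sample a correlated trait population for a plot design
#'
#' Draws per-plant latent measurements (stalk, cob and grain biomass, stalk
#' nitrogen, grain protein) from the treatment-conditional multivariate
#' normal of `effect_spec`, then derives the eight plot traits with
#' [derive_phenotypes()]. Grain density is sampled independently as a
#' reflected gamma (narrow, left-skewed) and carries no treatment signal,
#' making it a natural pure-noise benchmark trait.
#'
#' @param design a `plot_design`
#' @param effect_spec see [default_effect_spec()]
#' @param seed integer seed
#' @return data.frame of class `phenotype_record`: `plot_id`, `treatment`,
#'   the eight traits, and the latent per-plant columns (prefixed `latent_`)
#'   that downstream rendering links to
#' @export
sample_trait_population <- function(design, effect_spec = default_effect_spec(),
                                    seed = 1) {
  es <- effect_spec
  ev <- eigen(es$corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("correlation matrix is not positive semi-definite")
  n <- nrow(design)
  set.seed(substream_seed(seed, "traits"))
  nm <- names(es$mean_low)
  Sigma <- diag(es$sd[nm]) %*% es$corr[nm, nm] %*% diag(es$sd[nm])
  lat <- MASS::mvrnorm(n, mu = rep(0, length(nm)), Sigma = Sigma)
  lat <- matrix(lat, nrow = n, dimnames = list(NULL, nm))
  mu <- ifelse(matrix(design$treatment == "high_N", n, length(nm)),
               matrix(es$mean_high[nm], n, length(nm), byrow = TRUE),
               matrix(es$mean_low[nm], n, length(nm), byrow = TRUE))
  lat <- lat + mu
  floors <- c(stalk_g = 5, cob_g = 1, grain_g = 1, stalk_n_pct = 0.05,
              protein_pct = 3)
  lat <- pmax(lat, matrix(floors[nm], n, length(nm), byrow = TRUE))

  gd <- es$grain_density
  dens <- pmin(pmax(gd$offset - stats::rgamma(n, shape = gd$shape,
                                              scale = gd$scale), gd$lo), gd$hi)
  ph <- derive_phenotypes(lat[, "stalk_g"], lat[, "cob_g"], lat[, "grain_g"],
                          lat[, "stalk_n_pct"], lat[, "protein_pct"],
                          standing_plants = es$standing_plants,
                          plot_area_ha = es$plot_area_ha,
                          grain_density = dens)
  out <- cbind(data.frame(plot_id = design$plot_id,
                          treatment = design$treatment,
                          stringsAsFactors = FALSE),
               ph,
               setNames(as.data.frame(lat), paste0("latent_", nm)))
  out$latent_plant_n_g <- (lat[, "stalk_n_pct"] / 100) * lat[, "stalk_g"] +
    (lat[, "protein_pct"] / 6.25) / 100 * lat[, "grain_g"]
  class(out) <- c("phenotype_record", "data.frame")
  out
}
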