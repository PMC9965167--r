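#' Reflectance at a requested wavelength
#'
#' Returns the value of the band whose center wavelength is nearest to the
#' request (ties go to the lower wavelength). Requests outside the sensed
#' range by more than half a sampling interval are an error naming the index
#' that asked for them.
#'
#' @param spectrum numeric vector of plot-mean reflectances
#' @param wavelengths band center wavelengths (nm), ascending
#' @param wl requested wavelength (nm)
#' @param index optional name of the requesting vegetation index (for error
#'   messages)
#' @return scalar reflectance
#' @export
reflectance_at <- function(spectrum, wavelengths, wl, index = NULL) {
  half <- if (length(wavelengths) > 1) median(diff(wavelengths)) / 2 else Inf
  if (wl < min(wavelengths) - half || wl > max(wavelengths) + half)
    stop(sprintf("wavelength %g nm out of sensed range%s", wl,
                 if (is.null(index)) "" else paste0(" (requested by ", index, ")")))
  d <- abs(wavelengths - wl)
  spectrum[which(d == min(d))[1]]   # ties resolve to the lower wavelength
}

#' The 34 hyperspectral vegetation indices
#'
#' Evaluates the standard hyperspectral vegetation-index library on one
#' plot-mean spectrum, exactly as tabulated (including the asymmetric SIPI
#' variant with R450 in the numerator and R650 in the denominator, the
#' three-band GNDVI variant, and FCI = R683^2 / (R675 * R691)). A ratio
#' index whose denominator is ~0 yields `NA` for that index only.
#'
#' @param spectrum plot-mean reflectance vector
#' @param wavelengths band centers (nm)
#' @return named numeric vector of length 34
#' @export
hyperspectral_indices <- function(spectrum, wavelengths) {
  spectrum <- unname(spectrum)
  R <- function(wl, index) reflectance_at(spectrum, wavelengths, wl, index)
  rat <- function(num, den) if (abs(den) < 1e-12) NA_real_ else num / den
  out <- c(
    Ant_Gitelson = (rat(1, R(550, "Ant_Gitelson")) - rat(1, R(700, "Ant_Gitelson"))) * R(780, "Ant_Gitelson"),
    CI    = rat(R(750, "CI") - R(705, "CI"), R(750, "CI") + R(705, "CI")),
    OSAVI = (1 + 0.16) * rat(R(800, "OSAVI") - R(670, "OSAVI"),
                             R(800, "OSAVI") + R(670, "OSAVI") + 0.16),
    RGI   = rat(R(690, "RGI"), R(550, "RGI")),
    SIPI  = rat(R(800, "SIPI") - R(450, "SIPI"), R(800, "SIPI") + R(650, "SIPI")),
    TCARI = 3 * ((R(700, "TCARI") - R(670, "TCARI")) -
                   0.2 * (R(700, "TCARI") - R(550, "TCARI")) *
                   rat(R(700, "TCARI"), R(670, "TCARI"))),
    NRI   = rat(R(570, "NRI") - R(670, "NRI"), R(570, "NRI") + R(670, "NRI")),
    mCARI = 1.2 * (2.5 * (R(761, "mCARI") - R(651, "mCARI")) -
                     1.3 * (R(761, "mCARI") - R(581, "mCARI"))),
    PRI   = rat(R(531, "PRI") - R(570, "PRI"), R(531, "PRI") + R(570, "PRI")),
    RARSa = rat(R(675, "RARSa"), R(700, "RARSa")),
    RARSb = rat(R(675, "RARSb"), R(700, "RARSb") * R(650, "RARSb")),
    RARSc = rat(R(760, "RARSc"), R(500, "RARSc")),
    PSSR  = rat(R(800, "PSSR"), R(680, "PSSR")),
    PSRI  = rat(R(660, "PSRI") - R(510, "PSRI"), R(760, "PSRI")),
    NCPI  = rat(R(670, "NCPI") - R(450, "NCPI"), R(670, "NCPI") + R(450, "NCPI")),
    PPR   = rat(R(550, "PPR") - R(450, "PPR"), R(550, "PPR") + R(450, "PPR")),
    NDVI  = rat(R(860, "NDVI") - R(670, "NDVI"), R(860, "NDVI") + R(670, "NDVI")),
    GI    = rat(R(554, "GI"), R(677, "GI")),
    GNDVI = rat(R(750, "GNDVI") - R(540, "GNDVI") + R(570, "GNDVI"),
                R(750, "GNDVI") + R(540, "GNDVI") - R(570, "GNDVI")),
    SR    = rat(R(900, "SR"), R(680, "SR")),
    RNDVI = rat(R(750, "RNDVI") - R(705, "RNDVI"), R(750, "RNDVI") + R(705, "RNDVI")),
    MTVI  = 1.2 * (1.2 * (R(800, "MTVI") - R(550, "MTVI")) -
                     2.5 * (R(670, "MTVI") - R(550, "MTVI"))),
    TVI   = 0.5 * (120 * (R(761, "TVI") - R(581, "TVI")) -
                     200 * (R(651, "TVI") - R(581, "TVI"))),
    FRI1  = rat(R(690, "FRI1"), R(630, "FRI1")),
    FRI2  = rat(R(750, "FRI2"), R(800, "FRI2")),
    FRI3  = rat(R(690, "FRI3"), R(600, "FRI3")),
    FRI4  = rat(R(740, "FRI4"), R(800, "FRI4")),
    FCI   = rat(R(683, "FCI")^2, R(675, "FCI") * R(691, "FCI")),
    mRESR = rat(R(750, "mRESR") - R(445, "mRESR"), R(705, "mRESR") + R(445, "mRESR")),
    NPQI  = rat(R(415, "NPQI") - R(435, "NPQI"), R(415, "NPQI") + R(435, "NPQI")),
    RVS1  = (R(651, "RVS1") + R(750, "RVS1")) / 2 - R(733, "RVS1"),
    RVS2  = (R(651, "RVS2") + R(750, "RVS2")) / 2 - R(751, "RVS2"),
    WI    = rat(R(900, "WI"), R(970, "WI")),
    WSCT  = rat(R(970, "WSCT") - R(850, "WSCT"), R(970, "WSCT") + R(850, "WSCT"))
  )
  out
}

#' The 30 distribution metrics of a canopy variable
#'
#' Summary statistics of masked plot pixel values (canopy height or LiDAR
#' intensity): max, min, mean, mode (midpoint of the densest histogram bin),
#' sd, cv, scaled median absolute deviation (x 1.4826), average absolute
#' deviation, the 10th-90th/95th/98th/99th percentiles (linear
#' interpolation), interquartile range, moment skewness, excess kurtosis,
#' five canopy-return densities (proportion of values strictly above the
#' plot's own 10/30/50/70/90th quantiles), the canopy relief ratio
#' (mean - min)/(max - min), and the canopy-to-ground return ratio.
#'
#' @param values numeric vector of masked plot pixel values (length >= 2)
#' @param prefix "H" (height, metres) or "I" (intensity, unitless); chooses
#'   the metric names and the default mode histogram bin width (0.05 m / 5)
#' @param n_canopy,n_ground vegetation / non-vegetation pixel (or return)
#'   counts for the canopy-to-ground ratio; when the ground count is zero
#'   the canopy count is used as the ratio
#' @param mode_binwidth override for the mode histogram bin width
#' @return named numeric vector of length 30
#' @export
distribution_metrics <- function(values, prefix = c("H", "I"),
                                 n_canopy = NA_real_, n_ground = NA_real_,
                                 mode_binwidth = NULL) {
  prefix <- match.arg(prefix)
  if (length(values) < 2) stop("need at least 2 values")
  bw <- mode_binwidth %||% if (prefix == "H") 0.05 else 5
  m <- mean(values); s <- sd(values)
  mx <- max(values); mn <- min(values)
  if (s == 0) warning("constant input: cv and relief ratio set to 0")
  # mode via fixed-width histogram
  br <- seq(floor(mn / bw) * bw, mx + bw, by = bw)
  hh <- graphics::hist(values, breaks = br, plot = FALSE)
  mode_v <- hh$mids[which.max(hh$counts)]
  q <- quantile(values, c(.10, .20, .30, .40, .50, .60, .70, .80, .90,
                          .95, .98, .99, .25, .75), names = FALSE, type = 7)
  md <- median(values)
  m2 <- mean((values - m)^2); m3 <- mean((values - m)^3); m4 <- mean((values - m)^4)
  dens <- vapply(c(.10, .30, .50, .70, .90), function(p)
    mean(values > quantile(values, p, names = FALSE, type = 7)), numeric(1))
  cg <- if (is.na(n_canopy) || is.na(n_ground)) NA_real_
        else if (n_ground == 0) n_canopy else n_canopy / n_ground
  out <- c(mx, mn, m, mode_v, s,
           if (m != 0 && s > 0) s / m else 0,
           1.4826 * median(abs(values - md)),
           mean(abs(values - m)),
           q[1:12],
           q[14] - q[13],
           if (m2 > 0) m3 / m2^1.5 else 0,
           if (m2 > 0) m4 / m2^2 - 3 else 0,
           dens,
           if (mx > mn) (m - mn) / (mx - mn) else 0,
           cg)
  names(out) <- paste0(prefix,
                       c("max", "min", "mean", "mode", "sd", "cv", "mad", "aad",
                         "10", "20", "30", "40", "50", "60", "70", "80", "90",
                         "95", "98", "99", "iqr", "skn", "kurt",
                         "d10", "d30", "d50", "d70", "d90", "crr", "cg"))
  out
}

#' Normalized relative canopy temperature index
#'
#' The default evaluates the tabulated formula exactly as printed,
#' `(Ti - Tmin) / (Ti - Tmax)`, which is negative for plots between the
#' field extremes; `form = "normalized"` selects the conventional
#' `(Ti - Tmin) / (Tmax - Tmin)` in [0, 1].
#'
#' @param t_plot plot-mean canopy temperature, degrees C
#' @param t_min,t_max field-wide minimum / maximum plot temperature
#' @param form "printed" or "normalized"
#' @return scalar index; `NA` when the denominator is zero
#' @export
thermal_index <- function(t_plot, t_min, t_max, form = c("printed", "normalized")) {
  form <- match.arg(form)
  if (t_max <= t_min) stop("t_max must exceed t_min")
  den <- if (form == "printed") t_plot - t_max else t_max - t_min
  if (abs(den) < 1e-12) return(NA_real_)
  (t_plot - t_min) / den
}

#' Full 95-feature table for all plots
#'
#' Assembles the complete handcrafted feature library per plot: 34
#' hyperspectral vegetation indices from the plot-mean spectrum, 30
#' height-distribution and 30 intensity-distribution metrics from the
#' vegetation-masked chip pixels, and 1 thermal index (plot mean against the
#' field-wide extremes of the plot means).
#'
#' The field-wide thermal extremes are taken over the canopy pixels of all
#' plots (as a flown thermal raster provides them), so the plot means lie
#' strictly inside them and the printed index form is defined everywhere.
#'
#' @param prep a `plot_prep` from [prep_plots()]
#' @param thermal_form passed to [thermal_index()]
#' @return numeric matrix (plots x 95) with unique feature names
#' @export
plot_features <- function(prep, thermal_form = "printed") {
  d <- prep$design
  n <- nrow(d)
  bs <- prep$band_stack
  scene <- prep$scene
  t_raw <- numeric(n)
  t_px_min <- Inf; t_px_max <- -Inf
  feats <- NULL
  for (i in seq_len(n)) {
    cs <- chip_set(scene, d$plot_id[i], margin = prep$margin)
    mask <- prep$masks[[i]]
    hv <- cs$height[mask]; iv <- cs$intensity[mask]
    t_raw[i] <- masked_mean(cs$thermal, mask)
    t_px_min <- min(t_px_min, min(cs$thermal[mask]))
    t_px_max <- max(t_px_max, max(cs$thermal[mask]))
    n_can <- sum(mask); n_gnd <- sum(!mask)
    spec_means <- bs$M[i, seq_len(bs$n_spectral)]
    row <- c(hyperspectral_indices(spec_means, bs$wavelengths),
             distribution_metrics(hv, "H", n_canopy = n_can, n_ground = n_gnd),
             distribution_metrics(iv, "I", n_canopy = n_can, n_ground = n_gnd))
    if (is.null(feats)) feats <- matrix(NA_real_, n, length(row) + 1,
                                        dimnames = list(d$plot_id,
                                                        c(names(row), "Tir")))
    feats[i, seq_along(row)] <- row
  }
  feats[, "Tir"] <- vapply(t_raw, thermal_index, numeric(1),
                           t_min = t_px_min, t_max = t_px_max,
                           form = thermal_form)
  stopifnot(!anyDuplicated(colnames(feats)), ncol(feats) == 95)
  feats
}

#' Machine-readable registry of the 95 features
#' @return data.frame with columns `name`, `modality`, `formula`
#' @export
feature_registry <- function() {
  hyper <- names(hyperspectral_indices(rep(0.5, 61), seq(400, 1000, 10)))
  dm <- names(distribution_metrics(c(1, 2, 3), "H"))
  im <- names(distribution_metrics(c(1, 2, 3), "I"))
  data.frame(
    name = c(hyper, dm, im, "Tir"),
    modality = c(rep("hyperspectral", length(hyper)), rep("height", length(dm)),
                 rep("intensity", length(im)), "thermal"),
    formula = c(rep("see ?hyperspectral_indices", length(hyper)),
                rep("see ?distribution_metrics", length(dm) + length(im)),
                "(Ti - Tmin)/(Ti - Tmax)"),
    stringsAsFactors = FALSE
  )
}
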