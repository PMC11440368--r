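# Synthetic transect generator: tidal-mixing front, upwelling-downwelling
# dipole and zero-inflated plankton patchiness, with ground-truth habitat
# labels for recovery experiments.
#
# The generator emulates the hydrographic structures the habitat-mapping
# analysis assumes: a seasonally stratified water column (warm surface
# layer over a cold bottom layer, separated by a sharp thermocline), a
# transition band with upward-doming bottom-front isolines and a cool
# along-front jet, a tidally mixed coastal column with lower salinity
# around 34 psu, and (dipole scenarios) a saline downwelling lens next to
# a cool, low-oxygen upwelling dome.

# ground-truth label codes
GT_SURFACE <- 0L; GT_BOTTOM <- 1L; GT_MIXED <- 2L; GT_FRONT <- 3L
GT_DOWNWELLING <- 4L; GT_UPWELLING <- 5L

#' Tidal-mixing front scenario
#'
#' Parameters of a synthetic transect crossing a tidal-mixing front.
#' Defaults bracket the hydrography of a early-summer North Sea section:
#' a 16 / 11.5 deg C two-layer column offshore, a 34.3 -> 33.9 psu
#' coastal salinity gradient, oxygen decreasing from 250 to 225 umol/L
#' with depth, and a subsurface chlorophyll maximum.
#'
#' @param n_cols,n_rows Grid size (along-track columns, depth rows).
#' @param surface_temp,bottom_temp Stratified-side temperatures (deg C);
#'   `surface_temp` must exceed `bottom_temp`.
#' @param thermocline_depth_m Depth of the thermocline (m).
#' @param front_center_col,front_width_cols Centre and width (columns) of
#'   the front transition band.
#' @param offshore_salinity,coastal_salinity Salinities (psu) of the
#'   stratified offshore and mixed coastal ends.
#' @param surface_oxygen,bottom_oxygen Oxygen (umol/L) above/below the
#'   thermocline on the stratified side.
#' @param chl_max_depth_m Depth of the subsurface chlorophyll maximum (m).
#' @param chl_background,chl_peak Background and peak chlorophyll (RFU).
#' @param jet_temp_anomaly Cooling (deg C, positive value subtracted) of
#'   the along-front jet inside the transition band.
#' @param noise_sd Named list of per-field Gaussian noise standard
#'   deviations (`temperature`, `salinity`, `oxygen`, `chlorophyll`).
#' @param cell_length_m,cell_depth_m Cell dimensions (m).
#' @param seed Integer seed; the generated grid is deterministic given it.
#' @return A `front_scenario` list.
#' @export
front_scenario <- function(n_cols = 400, n_rows = 40,
                           surface_temp = 16, bottom_temp = 11.5,
                           thermocline_depth_m = 15,
                           front_center_col = 260, front_width_cols = 24,
                           offshore_salinity = 34.3,
                           coastal_salinity = 33.9,
                           surface_oxygen = 250, bottom_oxygen = 225,
                           chl_max_depth_m = 15, chl_background = 0.4,
                           chl_peak = 2.5, jet_temp_anomaly = 0.8,
                           noise_sd = list(temperature = 0.05,
                                           salinity = 0.02,
                                           oxygen = 1.0,
                                           chlorophyll = 0.05),
                           cell_length_m = 25, cell_depth_m = 1,
                           seed = 1L) {
  sc <- as.list(environment())
  class(sc) <- "front_scenario"
  validate_front_scenario(sc)
  sc
}

validate_front_scenario <- function(sc) {
  if (sc$surface_temp <= sc$bottom_temp)
    stop("surface_temp must exceed bottom_temp")
  if (any(unlist(sc$noise_sd) < 0)) stop("noise sd must be >= 0")
  half <- ceiling(sc$front_width_cols / 2)
  if (sc$front_center_col - half < 2 ||
      sc$front_center_col + half > sc$n_cols - 1)
    stop("grid too small: front band must fit inside the transect with ",
         "stratified and mixed columns on either side")
  if (sc$thermocline_depth_m <= sc$cell_depth_m ||
      sc$thermocline_depth_m >= (sc$n_rows - 1) * sc$cell_depth_m)
    stop("grid too small: thermocline must lie inside the depth range")
  invisible(sc)
}

#' Upwelling-downwelling dipole scenario
#'
#' Extends [front_scenario()] with a paired vertical-motion anomaly on the
#' stratified side: a saline downwelling lens and a cool, low-oxygen
#' upwelling dome (the wind-farm-wake dipole signature).  Anomalies are
#' applied with a compact quadratic bump that reaches the full configured
#' amplitude at the anomaly centre.
#'
#' @param ... Arguments passed to [front_scenario()].
#' @param upwelling_center_col,downwelling_center_col Anomaly centres
#'   (columns).
#' @param anomaly_radius_cols Horizontal radius of each anomaly (columns).
#' @param anomaly_depth_m Vertical centre of the anomalies (m).
#' @param anomaly_radius_m Vertical radius of the anomalies (m).
#' @param downwelling_salinity_anomaly Salinity increase (psu, >= 0) at
#'   the downwelling centre.
#' @param upwelling_oxygen_anomaly Oxygen change (umol/L, <= 0) at the
#'   upwelling centre.
#' @param upwelling_temp_anomaly Temperature change (deg C, <= 0) at the
#'   upwelling centre.
#' @return A `dipole_scenario` list (also a `front_scenario`).
#' @export
dipole_scenario <- function(..., upwelling_center_col = 80,
                            downwelling_center_col = 150,
                            anomaly_radius_cols = 30,
                            anomaly_depth_m = 8, anomaly_radius_m = 8,
                            downwelling_salinity_anomaly = 0.25,
                            upwelling_oxygen_anomaly = -30,
                            upwelling_temp_anomaly = -1.5) {
  sc <- front_scenario(...)
  sc$upwelling_center_col <- upwelling_center_col
  sc$downwelling_center_col <- downwelling_center_col
  sc$anomaly_radius_cols <- anomaly_radius_cols
  sc$anomaly_depth_m <- anomaly_depth_m
  sc$anomaly_radius_m <- anomaly_radius_m
  sc$downwelling_salinity_anomaly <- downwelling_salinity_anomaly
  sc$upwelling_oxygen_anomaly <- upwelling_oxygen_anomaly
  sc$upwelling_temp_anomaly <- upwelling_temp_anomaly
  if (anomaly_radius_cols <= 0) stop("anomaly_radius_cols must be > 0")
  if (downwelling_salinity_anomaly < 0)
    stop("downwelling_salinity_anomaly must be >= 0")
  if (upwelling_oxygen_anomaly > 0 || upwelling_temp_anomaly > 0)
    stop("upwelling anomalies must be <= 0")
  for (cc in c(upwelling_center_col, downwelling_center_col))
    if (cc < 1 || cc > sc$n_cols) stop("anomaly centre outside the grid")
  class(sc) <- c("dipole_scenario", "front_scenario")
  sc
}

# logistic vertical transition across the thermocline; width ~ 2 m gives
# a sharp but smooth interface
.strat_profile <- function(depth, top_val, bottom_val, tc_depth,
                           width_m = 2) {
  w <- 1 / (1 + exp(-(tc_depth - depth) / (width_m / 2)))
  bottom_val + (top_val - bottom_val) * w
}

# mixing fraction per column: 0 = stratified, 1 = fully mixed, linear in
# column index across the front band
.mix_fraction <- function(sc) {
  half <- sc$front_width_cols / 2
  j <- seq_len(sc$n_cols)
  pmin(1, pmax(0, (j - (sc$front_center_col - half)) / sc$front_width_cols))
}

# triangular along-front jet weight, peaking at the band centre
.jet_weight <- function(sc) {
  half <- sc$front_width_cols / 2
  j <- seq_len(sc$n_cols)
  pmax(0, 1 - abs(j - sc$front_center_col) / half)
}

.add_noise <- function(m, sd, lower = -Inf) {
  if (sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, sd), nrow(m))
  if (is.finite(lower)) m <- pmax(m, lower)
  m
}

#' Generate a tidal-mixing-front transect
#'
#' Builds the deterministic field structure from the scenario, adds seeded
#' Gaussian sensor noise, and returns the grid together with the
#' ground-truth habitat labels `0` (stratified surface layer), `1`
#' (stratified bottom layer), `2` (mixed coastal column) and `3`
#' (front/jet transition band).
#'
#' @param scenario A [front_scenario()].
#' @return A list with elements `grid` ([transect_grid()]) and
#'   `ground_truth` ([habitat_map()]).
#' @export
make_front_transect <- function(scenario) {
  validate_front_scenario(scenario)
  sc <- scenario
  nr <- sc$n_rows; nc <- sc$n_cols
  depth <- (seq_len(nr) - 1) * sc$cell_depth_m
  mixf <- .mix_fraction(sc)
  jetw <- .jet_weight(sc)

  # stratified vertical profiles
  t_strat <- .strat_profile(depth, sc$surface_temp, sc$bottom_temp,
                            sc$thermocline_depth_m)
  o_strat <- .strat_profile(depth, sc$surface_oxygen, sc$bottom_oxygen,
                            sc$thermocline_depth_m)
  chl_strat <- sc$chl_background + (sc$chl_peak - sc$chl_background) *
    exp(-0.5 * ((depth - sc$chl_max_depth_m) / 5)^2)

  # mixed-column values: depth averages of the stratified profiles
  t_mixed <- mean(t_strat); o_mixed <- mean(o_strat)
  chl_mixed <- mean(chl_strat)

  # doming: the effective thermocline shoals linearly through the band
  temp <- matrix(0, nr, nc); oxy <- matrix(0, nr, nc)
  sal <- matrix(0, nr, nc); chl <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    m <- mixf[j]
    tc_eff <- sc$thermocline_depth_m * (1 - m)
    tj <- .strat_profile(depth, sc$surface_temp, sc$bottom_temp, tc_eff)
    oj <- .strat_profile(depth, sc$surface_oxygen, sc$bottom_oxygen, tc_eff)
    cj <- sc$chl_background + (sc$chl_peak - sc$chl_background) *
      exp(-0.5 * ((depth - sc$chl_max_depth_m * (1 - m)) / 5)^2)
    temp[, j] <- (1 - m) * tj + m * t_mixed - sc$jet_temp_anomaly * jetw[j]
    oxy[, j] <- (1 - m) * oj + m * o_mixed
    chl[, j] <- (1 - m) * cj + m * chl_mixed
    sal[, j] <- sc$offshore_salinity +
      m * (sc$coastal_salinity - sc$offshore_salinity)
  }

  set.seed(scenario$seed)
  temp <- .add_noise(temp, sc$noise_sd$temperature)
  sal <- .add_noise(sal, sc$noise_sd$salinity)
  oxy <- .add_noise(oxy, sc$noise_sd$oxygen)
  chl <- .add_noise(chl, sc$noise_sd$chlorophyll, lower = 0)

  gt <- matrix(GT_FRONT, nr, nc)
  strat_cols <- mixf == 0
  gt[, strat_cols] <- ifelse(depth < sc$thermocline_depth_m,
                             GT_SURFACE, GT_BOTTOM)
  gt[, mixf == 1] <- GT_MIXED

  list(grid = transect_grid(paste0("front_", sc$seed),
                            temperature = temp, salinity = sal,
                            oxygen = oxy, chlorophyll = chl,
                            cell_length_m = sc$cell_length_m,
                            cell_depth_m = sc$cell_depth_m),
       ground_truth = habitat_map(paste0("front_", sc$seed), gt,
                                  cell_length_m = sc$cell_length_m,
                                  cell_depth_m = sc$cell_depth_m))
}

# compact quadratic bump, 1 at the centre, 0 outside the unit radius
.bump <- function(nr, nc, depth, center_col, radius_cols, depth_m,
                  radius_m) {
  j <- matrix(rep(seq_len(nc), each = nr), nr)
  z <- matrix(rep(depth, times = nc), nr)
  d2 <- ((j - center_col) / radius_cols)^2 + ((z - depth_m) / radius_m)^2
  pmax(0, 1 - d2)
}

#' Generate an upwelling-downwelling dipole transect
#'
#' As [make_front_transect()], plus a saline downwelling lens and a cool,
#' low-oxygen upwelling dome on the stratified side.  Ground-truth labels
#' add `4` (downwelling) and `5` (upwelling) where the anomaly bump
#' exceeds one half.  With all anomaly amplitudes zero the output equals
#' [make_front_transect()] on the shared fields.
#'
#' @param scenario A [dipole_scenario()].
#' @return A list with elements `grid` and `ground_truth`.
#' @export
make_dipole_transect <- function(scenario) {
  stopifnot(inherits(scenario, "dipole_scenario"))
  sc <- scenario
  base <- make_front_transect(scenario)
  g <- base$grid; gt <- base$ground_truth$labels
  depth <- (seq_len(sc$n_rows) - 1) * sc$cell_depth_m
  up <- .bump(sc$n_rows, sc$n_cols, depth, sc$upwelling_center_col,
              sc$anomaly_radius_cols, sc$anomaly_depth_m,
              sc$anomaly_radius_m)
  down <- .bump(sc$n_rows, sc$n_cols, depth, sc$downwelling_center_col,
                sc$anomaly_radius_cols, sc$anomaly_depth_m,
                sc$anomaly_radius_m)
  g$salinity <- g$salinity + sc$downwelling_salinity_anomaly * down
  g$oxygen <- g$oxygen + sc$upwelling_oxygen_anomaly * up
  g$temperature <- g$temperature + sc$upwelling_temp_anomaly * up
  if (sc$downwelling_salinity_anomaly > 0) gt[down > 0.5] <- GT_DOWNWELLING
  if (sc$upwelling_oxygen_anomaly < 0 || sc$upwelling_temp_anomaly < 0)
    gt[up > 0.5] <- GT_UPWELLING
  g$transect_id <- paste0("dipole_", sc$seed)
  list(grid = g,
       ground_truth = habitat_map(g$transect_id, gt,
                                  cell_length_m = sc$cell_length_m,
                                  cell_depth_m = sc$cell_depth_m))
}

#' Plankton patch specification
#'
#' Describes one zero-inflated lognormal patch of a plankton group inside
#' a ground-truth habitat region.  `mean_density` is the mean of the
#' lognormal component, so the overall expected density in the patch is
#' `(1 - zero_inflation) * mean_density`.
#'
#' @param group Plankton group name (e.g. `"pluteus"`).
#' @param habitat_label Ground-truth region code the patch occupies.
#' @param mean_density Mean of the lognormal component (ind per
#'   microhabitat).
#' @param zero_inflation Probability of a structural zero in `[0, 1]`.
#' @param lognormal_sigma Log-scale standard deviation (dimensionless).
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(group, habitat_label, mean_density,
                       zero_inflation = 0.6, lognormal_sigma = 1) {
  if (zero_inflation < 0 || zero_inflation > 1)
    stop("zero_inflation must be in [0, 1]")
  if (mean_density < 0) stop("mean_density must be >= 0")
  structure(list(group = group, habitat_label = as.integer(habitat_label),
                 mean_density = mean_density,
                 zero_inflation = zero_inflation,
                 lognormal_sigma = lognormal_sigma),
            class = "patch_spec")
}

# one zero-inflated lognormal draw per cell; sigma -> 0 degenerates to a
# point mass at mean_density
.rzilnorm <- function(n, mean_density, zero_inflation, sigma) {
  if (mean_density == 0) return(numeric(n))
  nz <- stats::rbinom(n, 1L, 1 - zero_inflation)
  mu <- log(mean_density) - sigma^2 / 2
  nz * stats::rlnorm(n, meanlog = mu, sdlog = sigma)
}

#' Add zero-inflated plankton patches to a transect grid
#'
#' Inside each patch's ground-truth region, cell densities follow a
#' zero-inflated lognormal with the configured component mean; everywhere
#' else the group receives a zero-inflated background.  Groups without a
#' patch covering a cell share the background parameters.
#'
#' @param grid A [transect_grid()].
#' @param ground_truth The matching ground-truth [habitat_map()].
#' @param patches List of [patch_spec()] objects.
#' @param background_density Lognormal-component mean of the background
#'   (ind per microhabitat).
#' @param background_zero_inflation Background structural-zero
#'   probability.
#' @param background_sigma Background log-scale sd.
#' @param seed Integer seed.
#' @return The grid with the plankton rasters added.
#' @export
add_plankton_patches <- function(grid, ground_truth, patches,
                                 background_density = 0.5,
                                 background_zero_inflation = 0.8,
                                 background_sigma = 1, seed = 1L) {
  stopifnot(inherits(grid, "transect_grid"),
            inherits(ground_truth, "habitat_map"))
  gt <- ground_truth$labels
  if (!identical(dim(gt), c(grid$n_rows, grid$n_cols)))
    stop("ground truth shape does not match the grid")
  for (p in patches) {
    if (!inherits(p, "patch_spec")) stop("patches must be patch_spec objects")
    if (!any(gt == p$habitat_label, na.rm = TRUE))
      stop("patch habitat label ", p$habitat_label,
           " absent from the ground truth")
    if (p$group %in% names(grid$plankton))
      stop("group '", p$group, "' collides with an existing raster")
  }
  set.seed(seed)
  n <- grid$n_rows * grid$n_cols
  for (g in unique(vapply(patches, `[[`, "", "group"))) {
    dens <- .rzilnorm(n, background_density, background_zero_inflation,
                      background_sigma)
    for (p in patches[vapply(patches, `[[`, "", "group") == g]) {
      inside <- which(as.vector(gt) == p$habitat_label)
      dens[inside] <- .rzilnorm(length(inside), p$mean_density,
                                p$zero_inflation, p$lognormal_sigma)
    }
    m <- matrix(dens, grid$n_rows)
    m[!grid$valid_mask] <- NA_real_
    grid$plankton[[g]] <- m
  }
  grid
}

#' Analytic mean of the zero-inflated lognormal patch distribution
#'
#' @param mean_density,zero_inflation Patch parameters as in
#'   [patch_spec()].
#' @return The expected per-cell density.
#' @export
zilnorm_mean <- function(mean_density, zero_inflation) {
  (1 - zero_inflation) * mean_density
}
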