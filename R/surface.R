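#' Additive (psi = 1) response surface over a concentration grid
#'
#' Evaluates the competitive interaction model under the additivity null
#' (psi = 1) at every pair of grid concentrations, giving the reference
#' surface against which observed combination effects are judged.
#'
#' @param hill_a,hill_b Fixed [hill_params()] for the two drugs (from the
#'   single-agent fits).
#' @param grid_a,grid_b Ascending concentration grids in uM (zeros permitted
#'   only as explicit control levels).
#' @param r0 Baseline viability (default 100%).
#' @return An object of class `surface_grid`: list with `conc_a`, `conc_b`
#'   and a `viability` matrix (rows = drug A levels, cols = drug B levels).
#' @export
build_additive_surface <- function(hill_a, hill_b, grid_a, grid_b,
                                   r0 = 100) {
  stopifnot(inherits(hill_a, "hill_params"), inherits(hill_b, "hill_params"))
  if (any(grid_a < 0) || any(grid_b < 0)) stop("grid values must be >= 0")
  if (is.unsorted(grid_a, strictly = TRUE) ||
      is.unsorted(grid_b, strictly = TRUE)) {
    stop("grids must be strictly ascending")
  }
  p <- interaction_params(hill_a, hill_b, psi = 1, r0 = r0)
  g <- expand.grid(conc_a = grid_a, conc_b = grid_b, KEEP.OUT.ATTRS = FALSE)
  v <- matrix(competitive_interaction_response(p, g$conc_a, g$conc_b),
              nrow = length(grid_a), ncol = length(grid_b))
  structure(list(conc_a = grid_a, conc_b = grid_b, viability = v),
            class = "surface_grid")
}

#' Classify observed combination points against the additive surface
#'
#' Each observed combination well is compared to the additive-model
#' prediction at its exact concentrations (never grid interpolation): points
#' with `observed - predicted > tolerance` sit above the surface (the
#' antagonistic side); all others are at or below it (additive/synergistic
#' side).
#'
#' @param hill_a,hill_b Fixed single-agent [hill_params()].
#' @param observations `data.frame` with columns `conc_a`, `conc_b` (both
#'   > 0) and `viability` — see [as_combination()].
#' @param tolerance Percentage-point margin for calling a point above the
#'   surface (default 0, a strict inequality; set to about half the
#'   replicate SD for noisy data).
#' @param r0 Baseline viability of the additive surface.
#' @return A list with `calls` (`data.frame`: `conc_a`, `conc_b`,
#'   `observed`, `predicted_additive`, `call`) and `summary` (counts and
#'   `frac_above`).
#' @export
classify_points <- function(hill_a, hill_b, observations, tolerance = 0,
                            r0 = 100) {
  stopifnot(all(c("conc_a", "conc_b", "viability") %in% names(observations)))
  if (any(observations$conc_a <= 0) || any(observations$conc_b <= 0)) {
    stop("classification requires both concentrations > 0 for every point")
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  p <- interaction_params(hill_a, hill_b, psi = 1, r0 = r0)
  pred <- competitive_interaction_response(p, observations$conc_a,
                                           observations$conc_b)
  above <- (observations$viability - pred) > tolerance
  calls <- data.frame(
    conc_a = observations$conc_a,
    conc_b = observations$conc_b,
    observed = observations$viability,
    predicted_additive = pred,
    call = ifelse(above, "above", "at_or_below"),
    stringsAsFactors = FALSE
  )
  list(calls = calls,
       summary = list(n = nrow(calls),
                      n_above = sum(above),
                      n_at_or_below = sum(!above),
                      frac_above = mean(above)))
}

#' Plot the additive response surface with overlaid observations
#'
#' Perspective plot of the additive (psi = 1) surface on log-concentration
#' axes; observed combination wells are drawn red when above the surface
#' (antagonism) and blue when at or below it (additivity/synergy).
#'
#' @param surface A [build_additive_surface()] result (a dense log-spaced
#'   grid, e.g. 50 x 50, renders smoothly).
#' @param calls Optional `calls` data.frame from [classify_points()].
#' @param file Optional PNG path; when given the plot is written there.
#' @param main Plot title.
#' @return The perspective transformation matrix, invisibly.
#' @export
plot_surface <- function(surface, calls = NULL, file = NULL,
                         main = "Additive response surface") {
  stopifnot(inherits(surface, "surface_grid"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 750, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  la <- log10(surface$conc_a)
  lb <- log10(surface$conc_b)
  zlim <- range(surface$viability, if (!is.null(calls)) calls$observed)
  tm <- graphics::persp(la, lb, surface$viability,
                        theta = -35, phi = 22, expand = 0.7,
                        col = "grey90", border = "grey60",
                        ticktype = "detailed", zlim = zlim,
                        xlab = "log10 CIS (uM)", ylab = "log10 CIM (uM)",
                        zlab = "viability (%)", main = main)
  if (!is.null(calls)) {
    pt <- grDevices::trans3d(log10(calls$conc_a), log10(calls$conc_b),
                             calls$observed, tm)
    graphics::points(pt, pch = 19, cex = 0.8,
                     col = ifelse(calls$call == "above", "red2", "blue3"))
  }
  invisible(tm)
}
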