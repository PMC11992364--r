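#' Rectangular solver domain for the 2D reaction-diffusion problem
#'
#' Geometry of the finite (x, z) rectangle on which the steady state is
#' solved: x runs along the assay axis over `[-L_x/2, L_x/2]` with the
#' light-dark border at 0, z runs from the glass surface (z = 0, where the
#' cells sit) up through the gel to `L_z`.
#'
#' The default gel thickness of 2600 um corresponds to the experimental
#' configuration of 0.5 cm^3 of agarose in a well of diameter 1.554 cm.
#'
#' @param L_x stripe length (um).
#' @param L_z gel thickness (um); default 2600.
#' @param dx,dz grid spacings (um); default 10.
#' @return An object of class `domain_geometry` with node coordinates `x`,
#'   `z`.
#' @export
domain_geometry <- function(L_x, L_z = 2600, dx = 10, dz = 10) {
  vals <- c(L_x = L_x, L_z = L_z, dx = dx, dz = dz)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be finite and positive")
  x <- seq(-L_x / 2, L_x / 2, by = dx)
  z <- seq(0, L_z, by = dz)
  if (length(x) < 16 || length(z) < 16)
    stop("grid too coarse: need at least 16 nodes per dimension")
  structure(list(L_x = L_x, L_z = L_z, dx = dx, dz = dz, x = x, z = z),
            class = "domain_geometry")
}

#' @export
print.domain_geometry <- function(x, ...) {
  cat(sprintf("Domain: %g x %g um, grid %d x %d (dx = %g, dz = %g um)\n",
              x$L_x, x$L_z, length(x$x), length(x$z), x$dx, x$dz))
  invisible(x)
}

#' Surface activity masks
#'
#' Indicator (or coverage-fraction) functions of x describing where each
#' surface process acts at z = 0: pheromone production, cell uptake, and
#' an optional Dirichlet sink that clamps the surface concentration to
#' zero (the perfect-sink idealization of saturating Bar1 secretion; it
#' overrides production and uptake where active).
#'
#' Masks are functions of the node x coordinates returning values in
#' `[0, 1]` -- fractional values express partial coverage of a grid cell,
#' which matters for locating a mask edge between nodes. The production
#' mask may also take values in `[-1, 1]`: a negative value is a
#' constant-rate surface sink of the corresponding strength, the
#' construction under which the closed-form perfect-sink profile
#' [sink_profile()] is the exact superposition solution.
#'
#' @param production function of x; where the source term `r rho_alpha`
#'   acts (values in `[-1, 1]`).
#' @param uptake function of x; where the uptake term `Omega rho_A c`
#'   acts (values in `[0, 1]`).
#' @param dirichlet_sink function of x or NULL; where the surface
#'   concentration is clamped to 0.
#' @return An object of class `surface_masks`.
#' @seealso [half_domain_mask()], [uniform_mask()], [balanced_sink_mask()]
#' @export
surface_masks <- function(production, uptake, dirichlet_sink = NULL) {
  stopifnot(is.function(production), is.function(uptake))
  if (!is.null(dirichlet_sink)) stopifnot(is.function(dirichlet_sink))
  structure(list(production = production, uptake = uptake,
                 dirichlet_sink = dirichlet_sink),
            class = "surface_masks")
}

#' Half-domain indicator with a half-weighted border node
#'
#' Indicator of `x < 0` for use as a surface mask. The node lying exactly
#' on the border receives weight 1/2 (its grid cell is half-covered),
#' which keeps the effective mask edge at x = 0 rather than at
#' `-dx/2` and removes a first-order discretization offset.
#'
#' @param side `"left"` (active on x < 0) or `"right"`.
#' @return A function of x.
#' @export
half_domain_mask <- function(side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") {
    function(x) ifelse(x < 0, 1, ifelse(x == 0, 0.5, 0))
  } else {
    function(x) ifelse(x > 0, 1, ifelse(x == 0, 0.5, 0))
  }
}

#' Uniform surface mask
#' @return A function of x that is 1 everywhere.
#' @export
uniform_mask <- function() function(x) rep(1, length(x))

#' Antisymmetric production mask for the perfect-sink superposition
#'
#' Production at full rate on `x < 0`, constant-rate removal at the same
#' rate on `x > 0` (0 at the border node). By linear superposition the
#' resulting surface profile equals `c_far * (f(x) - f(-x))`, which on the
#' diffusion side is exactly the closed-form perfect-sink profile
#' `2 f(x) - 1`.
#'
#' @return A function of x with values in `{-1, 0, 1}`.
#' @export
balanced_sink_mask <- function() function(x) ifelse(x < 0, 1, ifelse(x == 0, 0, -1))

#' Steady-state solution of the surface reaction-diffusion problem
#'
#' Solves the steady state of the 2D diffusion problem in the gel with all
#' reactions confined to the glass surface: pure diffusion
#' (\eqn{\nabla^2 c = 0}) in the bulk, no-flux walls on the two sides and
#' the top, and at z = 0 the Robin flux condition
#' \deqn{D \,\partial_z c |_{z=0} = \Omega \rho_A\, U(x)\, c -
#'   r \rho_\alpha\, P(x),}
#' which is the surface-delta production/uptake term of the continuum
#' model expressed as a boundary condition. Where the Dirichlet sink mask
#' is active the surface value is clamped to 0 instead.
#'
#' Discretization is the 5-point Laplacian with ghost-node elimination for
#' all Neumann/Robin boundaries (second-order accurate); the resulting
#' sparse linear system is solved directly (sparse LU via the Matrix
#' package), so the discrete residual is at round-off level.
#'
#' @param geometry a [domain_geometry()].
#' @param phys a [physical_params()].
#' @param masks a [surface_masks()].
#' @return An object of class `concentration_field`: list with matrix `c`
#'   (rows = x nodes, columns = z nodes; column 1 is the surface),
#'   `geometry`, and the evaluated masks.
#' @examples
#' geom <- domain_geometry(L_x = 800, L_z = 400, dx = 25, dz = 25)
#' pp <- physical_params(D = 300, r = 10, rho_alpha = 0.05,
#'                       rho_A = 0.05, Omega = 100)
#' fld <- solve_steady(geom, pp, surface_masks(uniform_mask(), uniform_mask()))
#' max(abs(fld$c - pp$c_far))   # homogeneous limit: constant c_far
#' @export
solve_steady <- function(geometry, phys, masks) {
  stopifnot(inherits(geometry, "domain_geometry"),
            inherits(phys, "physical_params"),
            inherits(masks, "surface_masks"))
  lam <- phys$decay_length
  if (geometry$dx > lam / 5)
    warning(sprintf("dx = %g um is coarse relative to lambda/5 = %g um; profile near the border will be under-resolved",
                    geometry$dx, lam / 5))
  x <- geometry$x
  z <- geometry$z
  Nx <- length(x)
  Nz <- length(z)
  N <- Nx * Nz
  dx <- geometry$dx
  dz <- geometry$dz
  P <- masks$production(x)
  U <- masks$uptake(x)
  if (any(U < 0 | U > 1)) stop("uptake mask must take values in [0, 1]")
  if (any(abs(P) > 1)) stop("production mask must take values in [-1, 1]")
  S <- if (is.null(masks$dirichlet_sink)) rep(0, Nx) else masks$dirichlet_sink(x)

  ii <- rep(seq_len(Nx), Nz)
  jj <- rep(seq_len(Nz), each = Nx)
  k <- (jj - 1L) * Nx + ii
  ax <- 1 / dx^2
  az <- 1 / dz^2
  # ghost-node mirror at walls; at the surface row the "upper" neighbor is
  # the ghost eliminated through the Robin condition below
  il <- ifelse(ii == 1L, 2L, ii - 1L)
  ir <- ifelse(ii == Nx, Nx - 1L, ii + 1L)
  jd <- ifelse(jj == Nz, Nz - 1L, jj + 1L)
  ju <- ifelse(jj == 1L, 2L, jj - 1L)
  rows <- c(k, k, k, k, k)
  cols <- c(k, (jj - 1L) * Nx + il, (jj - 1L) * Nx + ir,
            (jd - 1L) * Nx + ii, (ju - 1L) * Nx + ii)
  vals <- c(rep(-2 * ax - 2 * az, N), rep(ax, N), rep(ax, N),
            rep(az, N), rep(az, N))
  b <- numeric(N)
  surf <- which(jj == 1L)
  # ghost value c_{i,0} = c_{i,2} + (2 dz / D)(r rho_alpha P - Omega rho_A U c_{i,1})
  b[surf] <- b[surf] - az * (2 * dz / phys$D) * phys$r * phys$rho_alpha * P[ii[surf]]
  rows <- c(rows, surf)
  cols <- c(cols, surf)
  vals <- c(vals, -az * (2 * dz / phys$D) * phys$Omega * phys$rho_A * U[ii[surf]])

  isdir <- rep(FALSE, N)
  isdir[surf[S[ii[surf]] > 0]] <- TRUE
  keep <- !isdir[rows]
  rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
  ndir <- which(isdir)
  rows <- c(rows, ndir); cols <- c(cols, ndir); vals <- c(vals, rep(1, length(ndir)))
  b[ndir] <- 0

  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
  sol <- as.numeric(Matrix::solve(A, b))
  res <- max(abs(A %*% sol - b)) / max(max(abs(b)), 1e-300)
  if (!all(is.finite(sol)) || res > 1e-8)
    stop(sprintf("sparse solve did not converge: relative residual %.3g", res))

  structure(list(c = matrix(sol, Nx, Nz), geometry = geometry,
                 production = P, uptake = U, sink = S, residual = res),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("Steady-state concentration field on %d x %d grid; surface range [%.4g, %.4g]\n",
              nrow(x$c), ncol(x$c), min(x$c[, 1]), max(x$c[, 1])))
  invisible(x)
}

#' Surface concentration profile of a solved field
#'
#' @param field a `concentration_field` from [solve_steady()].
#' @return A data.frame with columns `x` (um) and `c` (the z = 0 row of
#'   the field).
#' @export
surface_slice <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  data.frame(x = field$geometry$x, c = field$c[, 1])
}

#' Sharpness of the border transition at increasing heights
#'
#' Magnitude of the centered finite-difference slope of c with respect to
#' x at the border (x = 0), evaluated at each requested height z. The
#' transition is sharpest at the glass surface and smooths with distance
#' into the gel.
#'
#' @param field a `concentration_field`.
#' @param z_values heights (um) within the domain.
#' @return Numeric vector of slope magnitudes (concentration units per
#'   um), one per `z_values`.
#' @export
transition_sharpness <- function(field, z_values) {
  stopifnot(inherits(field, "concentration_field"))
  g <- field$geometry
  if (any(z_values < 0 | z_values > g$L_z)) stop("z values outside the domain")
  i0 <- which.min(abs(g$x))
  if (i0 == 1 || i0 == length(g$x)) stop("border not interior to the x grid")
  vapply(z_values, function(zv) {
    j <- which.min(abs(g$z - zv))
    abs(field$c[i0 + 1, j] - field$c[i0 - 1, j]) / (2 * g$dx)
  }, numeric(1))
}

#' Export a solved field as a long-format table
#'
#' @param field a `concentration_field`.
#' @param path optional file path; if given, the table is written as CSV.
#' @return (Invisibly, if written) a data.frame with columns `x`, `z`, `c`.
#' @export
field_table <- function(field, path = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  g <- field$geometry
  df <- data.frame(x = rep(g$x, length(g$z)),
                   z = rep(g$z, each = length(g$x)),
                   c = as.numeric(field$c))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Flux balance diagnostics of a solved field
#'
#' Integrates the surface production flux, the surface uptake flux and
#' (for Dirichlet-sink nodes) the diffusive flux into the sink along the
#' surface. At steady state production balances uptake plus sink
#' absorption. For configurations without a Dirichlet sink the discrete
#' balance is exact to solver round-off; sink flux is reconstructed with
#' a second-order one-sided difference and carries discretization error.
#'
#' @param field a `concentration_field`.
#' @param phys the [physical_params()] used for the solve.
#' @return List with `production`, `uptake`, `sink` (molecules/s per um of
#'   stripe width) and `imbalance` (relative).
#' @export
flux_balance <- function(field, phys) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(phys, "physical_params"))
  g <- field$geometry
  dx <- g$dx
  dz <- g$dz
  csurf <- field$c[, 1]
  dir <- field$sink > 0
  prod_flux <- sum(phys$r * phys$rho_alpha * field$production[!dir]) * dx
  upt_flux <- sum(phys$Omega * phys$rho_A * field$uptake[!dir] * csurf[!dir]) * dx
  sink_flux <- 0
  if (any(dir)) {
    # flux into the surface at clamped nodes: D dc/dz, one-sided 2nd order
    dcdz <- (-3 * field$c[dir, 1] + 4 * field$c[dir, 2] - field$c[dir, 3]) / (2 * dz)
    sink_flux <- sum(phys$D * dcdz) * dx
  }
  imb <- (prod_flux - upt_flux - sink_flux) / max(abs(prod_flux), 1e-300)
  list(production = prod_flux, uptake = upt_flux, sink = sink_flux,
       imbalance = imb)
}
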