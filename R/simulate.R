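#' Population layout configuration
#'
#' Spatial extent and composition of a simulated cell population,
#' defaulting to the scale of the half-domain assay: about 6,686 receiver
#' cells spread over a stripe spanning roughly 5,400 um around the border
#' (stripe width 330 um, recorded as metadata).
#'
#' @param x_range numeric length-2, min/max position (um, border at 0).
#' @param n_receivers number of receiver (MATa reporter) cells.
#' @param n_emitters number of emitter (MATalpha) cells.
#' @param stripe_width stripe width (um), metadata only.
#' @return An object of class `population_config`.
#' @export
population_config <- function(x_range = c(-2700, 2700), n_receivers = 6686,
                              n_emitters = 2000, stripe_width = 330) {
  if (length(x_range) != 2 || !all(is.finite(x_range)) || x_range[2] <= x_range[1])
    stop("`x_range` must be (min, max) with max > min")
  if (n_receivers < 0 || n_emitters < 0) stop("counts must be >= 0")
  structure(list(x_range = x_range, n_receivers = n_receivers,
                 n_emitters = n_emitters, stripe_width = stripe_width),
            class = "population_config")
}

#' Noise and morphology-model configuration
#'
#' Single-cell noise magnitudes for the simulated readouts. GFP noise is
#' multiplicative lognormal with unit mean and the given coefficient of
#' variation; length noise is additive Gaussian. The morphological
#' response can be simulated either as a graded mean-field readout or as
#' a bimodal mixture of round and elongated cells whose elongated
#' fraction follows the Hill response (binned means agree between the two
#' modes by construction).
#'
#' @param gfp_cv coefficient of variation of the multiplicative GFP noise;
#'   default 0.30, typical of yeast gene-expression variability.
#' @param length_sd additive SD of cell length (um); default 1.5.
#' @param morphology_mode `"mean_field"` or `"bimodal"`.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(gfp_cv = 0.30, length_sd = 1.5,
                         morphology_mode = c("mean_field", "bimodal")) {
  if (!is.finite(gfp_cv) || gfp_cv < 0) stop("`gfp_cv` must be >= 0")
  if (!is.finite(length_sd) || length_sd < 0) stop("`length_sd` must be >= 0")
  morphology_mode <- match.arg(morphology_mode)
  structure(list(gfp_cv = gfp_cv, length_sd = length_sd,
                 morphology_mode = morphology_mode),
            class = "noise_config")
}

#' Draw cell positions and identities
#'
#' Positions are i.i.d. uniform over the configured range (the cell layer
#' is spatially homogeneous); identities are assigned by the requested
#' counts. Emitters carry no readouts -- the analysis quantifies
#' receivers.
#'
#' @param pop a [population_config()].
#' @param seed integer RNG seed; all downstream randomness should flow
#'   from explicit seeds so identical seeds give identical tables.
#' @return A data.frame of class `cell_table` with columns `cell_id`,
#'   `identity`, `x_um`, `area_px`, `gfp_au`, `length_um`,
#'   `orientation_deg` (readout columns NA until simulated).
#' @export
generate_cells <- function(pop, seed) {
  stopifnot(inherits(pop, "population_config"))
  set.seed(as.integer(seed))
  n <- pop$n_receivers + pop$n_emitters
  if (n == 0) stop("empty population")
  df <- data.frame(
    cell_id = seq_len(n),
    identity = rep(c("receiver", "emitter"), c(pop$n_receivers, pop$n_emitters)),
    x_um = runif(n, pop$x_range[1], pop$x_range[2]),
    area_px = NA_real_,
    gfp_au = NA_real_,
    length_um = NA_real_,
    orientation_deg = NA_real_,
    stringsAsFactors = FALSE
  )
  attr(df, "pop") <- pop
  attr(df, "seed") <- as.integer(seed)
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Simulate the gene-expression readout
#'
#' Mean GFP fluorescence of each receiver:
#' `gfp = (A_g * theta(c(x)) + b_g) * eta`, with `theta` the n = 1
#' (non-cooperative) Hill response to the modeled concentration and `eta`
#' a unit-mean lognormal factor with CV `noise$gfp_cv`, so the
#' expectation equals the model mean.
#'
#' @param records a `cell_table`.
#' @param shape a [gradient_shape()].
#' @param resp_g [response_params()] for the gene-expression channel;
#'   must have `n = 1`.
#' @param noise a [noise_config()].
#' @param geometry `"source"` or `"sink"` concentration profile.
#' @return The table with `gfp_au` filled in for receivers.
#' @export
simulate_gfp <- function(records, shape, resp_g, noise,
                         geometry = c("source", "sink")) {
  stopifnot(inherits(records, "cell_table"), inherits(resp_g, "response_params"),
            inherits(noise, "noise_config"))
  if (resp_g$n != 1)
    stop("the gene-expression channel is non-cooperative: `resp_g$n` must be 1")
  geometry <- match.arg(geometry)
  rec <- records$identity == "receiver"
  mu <- observed_response(records$x_um[rec], shape, resp_g, geometry)
  if (noise$gfp_cv > 0) {
    sdl <- sqrt(log(1 + noise$gfp_cv^2))
    mu <- mu * rlnorm(sum(rec), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  records$gfp_au[rec] <- mu
  records
}

#' Simulate the morphological (cell length) readout
#'
#' In `mean_field` mode each receiver's length is the graded model mean
#' plus Gaussian noise, truncated at a small positive floor. In `bimodal`
#' mode each receiver is elongated with probability `theta_m(x)` (drawing
#' its length from a Gaussian around `b_m + A_m`, i.e. the fully shmooed
#' length) and round otherwise (length around the round-cell baseline
#' `b_m`); per-bin mean lengths then still equal `A_m * theta_m + b_m`.
#' A cell area (pixels) consistent with the drawn length is filled in for
#' all cells, so area-based elongation filters have something to act on.
#'
#' @param records a `cell_table`.
#' @param shape a [gradient_shape()].
#' @param resp_m [response_params()] for the morphology channel.
#' @param noise a [noise_config()].
#' @param geometry `"source"` or `"sink"`.
#' @return The table with `length_um` and `area_px` filled in.
#' @export
simulate_length <- function(records, shape, resp_m, noise,
                            geometry = c("source", "sink")) {
  stopifnot(inherits(records, "cell_table"), inherits(resp_m, "response_params"),
            inherits(noise, "noise_config"))
  geometry <- match.arg(geometry)
  rec <- records$identity == "receiver"
  nrec <- sum(rec)
  th <- hill_response(concentration(records$x_um[rec], shape, geometry), resp_m$n)
  if (noise$morphology_mode == "mean_field") {
    len <- resp_m$A * th + resp_m$b
    if (noise$length_sd > 0) len <- len + rnorm(nrec, 0, noise$length_sd)
    len <- pmax(len, 0.1)
  } else {
    elong <- runif(nrec) < th
    len <- ifelse(elong, resp_m$b + resp_m$A, resp_m$b)
    if (noise$length_sd > 0) len <- len + rnorm(nrec, 0, noise$length_sd)
    len <- pmax(len, 0.1)
  }
  records$length_um[rec] <- len
  # area from an ellipse of the drawn length and ~3.5 um width, imaged at
  # 0.33 um/px (20x objective): a round 5-um cell lands near 180 px
  width_um <- 3.5
  px <- 0.33
  all_len <- records$length_um
  all_len[!rec] <- 5
  records$area_px <- round(pi * (all_len / 2) * (width_um / 2) / px^2)
  records
}

#' Simulate cell orientation angles
#'
#' Orientation of each receiver's fitted ellipse relative to the gradient
#' axis, i.i.d. uniform on (0, 180]: the simulated population shows no
#' gradient alignment, reflecting the absence of chemotropic orientation
#' under shallow large-scale gradients.
#'
#' @param records a `cell_table`.
#' @return The table with `orientation_deg` filled in for receivers.
#' @export
simulate_orientation <- function(records) {
  stopifnot(inherits(records, "cell_table"))
  rec <- records$identity == "receiver"
  records$orientation_deg[rec] <- 180 - runif(sum(rec), 0, 180)
  records
}

#' Simulate a complete half-domain experiment
#'
#' Convenience wrapper: positions, GFP, length/area and orientation in one
#' call, with the fixture defaults (decay length 735 um, far-field
#' concentration 1.45 EC50, morphology Hill coefficient 3, gene-expression
#' coefficient 1).
#'
#' @param seed integer RNG seed.
#' @param pop a [population_config()].
#' @param shape a [gradient_shape()].
#' @param resp_g,resp_m [response_params()] for the two channels.
#' @param noise a [noise_config()].
#' @param geometry `"source"` or `"sink"`.
#' @return A `cell_table` with all readouts simulated.
#' @examples
#' tab <- simulate_experiment(seed = 1, pop = population_config(n_receivers = 500,
#'                                                              n_emitters = 0))
#' head(tab)
#' @export
simulate_experiment <- function(seed,
                                pop = population_config(),
                                shape = gradient_shape(735, 1.45),
                                resp_g = response_params(1, 1, 0.1),
                                resp_m = response_params(3, 25, 5),
                                noise = noise_config(),
                                geometry = c("source", "sink")) {
  geometry <- match.arg(geometry)
  tab <- generate_cells(pop, seed)
  tab <- simulate_gfp(tab, shape, resp_g, noise, geometry)
  tab <- simulate_length(tab, shape, resp_m, noise, geometry)
  tab <- simulate_orientation(tab)
  attr(tab, "params") <- list(shape = shape, resp_g = resp_g, resp_m = resp_m,
                              noise = noise, geometry = geometry)
  tab
}

.cell_cols <- c("cell_id", "identity", "x_um", "area_px", "gfp_au",
                "length_um", "orientation_deg")

#' Write a cell table to CSV with a metadata header
#'
#' Writes the standard seven-column table. Generation metadata (seed and
#' parameters, when present as attributes) is stored in `#`-prefixed
#' comment lines above the header so the file remains a single
#' self-describing artifact.
#'
#' @param records a `cell_table` or compatible data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  missing_cols <- setdiff(.cell_cols, names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(records, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  pars <- attr(records, "params")
  if (!is.null(pars)) {
    writeLines(sprintf("# shape: lambda=%g C=%g", pars$shape$lambda, pars$shape$C), con)
    writeLines(sprintf("# resp_g: n=%d A=%g b=%g", pars$resp_g$n, pars$resp_g$A, pars$resp_g$b), con)
    writeLines(sprintf("# resp_m: n=%d A=%g b=%g", pars$resp_m$n, pars$resp_m$A, pars$resp_m$b), con)
    writeLines(sprintf("# noise: gfp_cv=%g length_sd=%g mode=%s",
                       pars$noise$gfp_cv, pars$noise$length_sd, pars$noise$morphology_mode), con)
    writeLines(sprintf("# geometry: %s", pars$geometry), con)
  }
  write.csv(records[, .cell_cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Accepts the package's seven-column format or the four-column
#' segmentation-pipeline variant (`identity`, position, area, GFP); in
#' the latter case the length and orientation columns are added as NA.
#' Malformed rows raise an error naming the offending line.
#'
#' @param path CSV file path (comment lines starting with `#` allowed).
#' @return A `cell_table` data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  four <- c("identity", "x_um", "area_px", "gfp_au")
  if (all(.cell_cols %in% names(df))) {
    df <- df[, .cell_cols]
  } else if (all(four %in% names(df))) {
    if (!("cell_id" %in% names(df))) df$cell_id <- seq_len(nrow(df))
    df$length_um <- NA_real_
    df$orientation_deg <- NA_real_
    df <- df[, .cell_cols]
  } else {
    stop("unrecognized schema: need columns ", paste(four, collapse = ", "),
         " (length_um/orientation_deg optional)")
  }
  num_cols <- setdiff(.cell_cols, "identity")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("malformed value in column '%s' at data row %d", cl, bad[1]))
      df[[cl]] <- conv
    }
  }
  if (!all(df$identity %in% c("receiver", "emitter", "diploid")))
    stop("identity must be receiver/emitter/diploid; first bad row: ",
         which(!df$identity %in% c("receiver", "emitter", "diploid"))[1])
  class(df) <- c("cell_table", "data.frame")
  df
}
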