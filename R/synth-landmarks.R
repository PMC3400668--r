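# Synthetic landmark configurations: a fixed template deformed by a
# smooth thin-plate-spline mode scaled by a per-specimen covariate,
# digitising noise, and a random similarity transform per specimen so
# that Procrustes alignment has real work to do.

#' Generate landmark configurations with known shape signal
#'
#' Each specimen is the template warped along a smooth deformation mode
#' built from the template's lowest-bending principal warps, with the
#' warp amplitude proportional to a per-specimen covariate times
#' `deformation_magnitude`, plus isotropic landmark noise. Every
#' configuration is then randomly rotated, scaled and translated. The
#' covariate is recorded as ground truth so shape-regression power can
#' be tested.
#'
#' @param n Number of specimens (>= 2).
#' @param k Number of landmarks (>= 4). `k = 17` uses the packaged fish
#'   template; other values use a deterministic closed outline.
#' @param deformation_magnitude Scale of the covariate-linked smooth
#'   deformation, in units of the unit-centroid-size template (0 =
#'   identical shapes).
#' @param noise_sd Isotropic landmark noise SD, same units.
#' @param seed Optional integer seed.
#' @param covariate Optional per-specimen covariate; standard-normal
#'   draws by default.
#' @return k x 2 x n array of class `landmark_set` with attributes
#'   `covariate` and `truth`.
#' @export
gen_landmarks <- function(n, k = 17, deformation_magnitude = 0.02,
                          noise_sd = 0.005, seed = NULL,
                          covariate = NULL) {
  n <- check_count(n, "n", min = 2L)
  k <- check_count(k, "k", min = 4L)
  check_nonneg(deformation_magnitude, "deformation_magnitude")
  check_nonneg(noise_sd, "noise_sd")
  maybe_seed(seed)

  template <- if (k == 17L) {
    template_landmarks()
  } else {
    # deterministic closed outline: an ellipse with a third-harmonic
    # modulation that breaks its symmetries
    th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
    cbind(cos(th) * (1 + 0.15 * sin(3 * th)),
          0.5 * sin(th) * (1 + 0.1 * cos(2 * th)))
  }
  template <- center_scale(template)$coords

  # smooth deformation mode: random mix of the three lowest-bending
  # non-affine principal warps (fixed once per call, shared by all
  # specimens)
  if (deformation_magnitude > 0) {
    Be <- bending_energy(template)
    eg <- eigen(Be, symmetric = TRUE)
    nw <- k - 3L
    low <- eg$vectors[, seq(max(1L, nw - 2L), nw), drop = FALSE]
    wx <- stats::rnorm(ncol(low)); wy <- stats::rnorm(ncol(low))
    mode <- cbind(low %*% wx, low %*% wy)
    mode <- mode / sqrt(sum(mode^2))
  } else {
    mode <- matrix(0, k, 2L)
  }
  if (is.null(covariate)) covariate <- stats::rnorm(n)
  if (length(covariate) != n) {
    stop("`covariate` must have length `n`", call. = FALSE)
  }

  arr <- array(NA_real_, c(k, 2L, n),
               dimnames = list(rownames(template), c("x", "y"),
                               sprintf("spec%02d", seq_len(n))))
  for (i in seq_len(n)) {
    shape <- template + deformation_magnitude * covariate[i] * mode
    if (noise_sd > 0) {
      shape <- shape + matrix(stats::rnorm(2L * k, 0, noise_sd), k, 2L)
    }
    ang <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
    sc <- exp(stats::rnorm(1, 0, 0.1)) * 10      # image-scale units
    shift <- stats::runif(2, -5, 5)
    arr[, , i] <- sweep(shape %*% R * sc, 2L, -shift)
  }
  structure(arr, covariate = covariate,
            truth = list(deformation_magnitude = deformation_magnitude,
                         noise_sd = noise_sd, mode = mode,
                         template = template),
            class = c("landmark_set", "array"))
}

#' Write landmark configurations as a TPS file
#'
#' Standard TPS layout: for each specimen a `LM=k` line, `k` lines of
#' space-separated x y coordinates, an `ID=` line and optionally a
#' `SCALE=` line.
#'
#' @param configs k x 2 x n array (or list of matrices).
#' @param path Output path.
#' @param scale Optional numeric scale factor(s) written as `SCALE=`.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path, scale = NULL) {
  arr <- as_shape_array(configs)
  n <- dim(arr)[3L]; k <- dim(arr)[1L]
  ids <- dimnames(arr)[[3L]] %||% sprintf("spec%02d", seq_len(n))
  if (!is.null(scale)) scale <- rep_len(scale, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.10g %.10g", arr[, 1L, i], arr[, 2L, i]), con)
    writeLines(sprintf("ID=%s", ids[i]), con)
    if (!is.null(scale)) writeLines(sprintf("SCALE=%.10g", scale[i]), con)
  }
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Accepts the `LM=` / coordinate-pair / `ID=` / optional `SCALE=`
#' layout written by [write_tps()] and by standard digitising tools.
#' Coordinates are multiplied by `SCALE=` when present.
#'
#' @param path TPS file path.
#' @return k x 2 x n array with specimen IDs as third-dimension names.
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= records found", call. = FALSE)
  configs <- list()
  for (si in seq_along(starts)) {
    i0 <- starts[si]
    i1 <- if (si < length(starts)) starts[si + 1L] - 1L else length(lines)
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i0], ignore.case = TRUE))
    coord_lines <- lines[(i0 + 1L):(i0 + k)]
    m <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), function(p) {
      as.numeric(p[1:2])
    }))
    rest <- lines[(i0 + k + 1L):i1]
    id <- sub("^ID\\s*=\\s*", "", grep("^ID\\s*=", rest,
                                       ignore.case = TRUE, value = TRUE))
    sc <- sub("^SCALE\\s*=\\s*", "", grep("^SCALE\\s*=", rest,
                                          ignore.case = TRUE, value = TRUE))
    if (length(sc) == 1L) m <- m * as.numeric(sc)
    configs[[if (length(id) == 1L) id else sprintf("spec%02d", si)]] <- m
  }
  as_shape_array(configs)
}
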