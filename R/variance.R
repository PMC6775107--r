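# Spatial-variance analysis: separates true spatial heterogeneity of a
# property map from instrument variance by randomized box-averaged
# sampling. A spatially structured map keeps excess variance at large box
# sizes; an iid-noise map decays like 1/edge.

#' Spatial variance curve by randomized box averaging
#'
#' For each box edge length, draws `n_samples` random axis-aligned square
#' boxes fully inside the valid region of the map, averages the map within
#' each box, and reports the standard deviation of those box means.
#' Boxes touching invalid pixels are rejected (avoiding edge bias).
#' Deterministic under `seed`.
#'
#' @param map Numeric property map (e.g. a `D` map).
#' @param box_edges_um Box edge lengths in micrometers.
#' @param pixel_pitch_um Lateral pixel pitch of the map.
#' @param n_samples Random box draws per edge length (>= 30).
#' @param seed RNG seed (mandatory).
#' @param valid Logical validity mask (default: finite map values).
#' @param max_tries Rejection-sampling budget per draw.
#' @return An object of class `variance_curve`: data frame fields
#'   `edge_um`, `std_D`, `n` plus the seed.
#' @export
spatial_variance_curve <- function(map, box_edges_um, pixel_pitch_um = 5,
                                   n_samples = 200L, seed,
                                   valid = is.finite(map),
                                   max_tries = 50L) {
  if (missing(seed)) stop("`seed` is mandatory for the randomized sampling")
  stopifnot(n_samples >= 30L)
  nx <- nrow(map); ny <- ncol(map)
  edges_px <- pmax(1L, round(box_edges_um / pixel_pitch_um))
  if (any(edges_px > min(nx, ny)))
    stop("box larger than the map")
  set.seed(seed)
  out <- data.frame(edge_um = box_edges_um, std_D = NA_real_,
                    n = 0L)
  for (ei in seq_along(edges_px)) {
    e <- edges_px[ei]
    means <- numeric(0)
    for (s in seq_len(n_samples)) {
      for (tr in seq_len(max_tries)) {
        x0 <- sample.int(nx - e + 1L, 1L)
        y0 <- sample.int(ny - e + 1L, 1L)
        vv <- valid[x0:(x0 + e - 1L), y0:(y0 + e - 1L)]
        if (all(vv)) {
          means <- c(means,
                     mean(map[x0:(x0 + e - 1L), y0:(y0 + e - 1L)]))
          break
        }
      }
    }
    out$std_D[ei] <- stats::sd(means)
    out$n[ei] <- length(means)
  }
  structure(list(curve = out, seed = seed,
                 pixel_pitch_um = pixel_pitch_um),
            class = "variance_curve")
}

#' @export
print.variance_curve <- function(x, ...) {
  cat("<variance_curve>\n")
  print(x$curve)
  invisible(x)
}

#' Export a variance curve as CSV
#'
#' Columns `edge_um`, `std_D`, `n`.
#'
#' @param vc A [spatial_variance_curve()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_variance_curve <- function(vc, path) {
  utils::write.csv(vc$curve, path, row.names = FALSE)
  invisible(path)
}
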