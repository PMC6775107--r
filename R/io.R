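# Output writers: canonical lossless container (serialized R object) plus
# interchange formats (32-bit float TIFF maps, CSV tables). Every written
# run directory carries provenance: the resolved configuration, seed and
# package version.

# The TIFF writer stores samples in [0, 1]; physical maps are therefore
# max-scaled before writing and the scale recorded in a sidecar text file
# (`<path>.scale.txt`), so `value = pixel * scale`. Invalid pixels are
# stored as 0; the validity mask travels in the CSV/serialized container.
write_float_tiff <- function(mat, path) {
  m <- t(mat)  # image rows = y
  s <- suppressWarnings(max(abs(m[is.finite(m)])))
  if (!is.finite(s) || s == 0) s <- 1
  m01 <- pmin(pmax(m / s, 0), 1)
  m01[!is.finite(m01)] <- 0
  tiff::writeTIFF(m01, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(sprintf("scale: %.17g", s), paste0(path, ".scale.txt"))
  invisible(path)
}

#' Read a map written by the package's TIFF exporter
#'
#' Applies the sidecar scale and restores the (x, y) orientation.
#'
#' @param path TIFF path written by the package.
#' @return A numeric matrix in physical units.
#' @export
read_float_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  sc <- 1
  sidecar <- paste0(path, ".scale.txt")
  if (file.exists(sidecar))
    sc <- as.numeric(sub("^scale: *", "", readLines(sidecar)[1]))
  if (is.list(m)) return(lapply(m, function(x) t(x) * sc))
  t(m) * sc
}

#' Write property maps to a run directory
#'
#' Writes the lossless canonical container (`property_maps.rds`), 32-bit
#' float TIFF en-face maps of each scalar quantity (`D`, `g`,
#' `chl_areal_ug_cm2`, `mu_s_ref`, `mu_a_peak`, `albedo`), one TIFF page
#' per band for `mu_t`, a long-format CSV `mu_t.csv`
#' (x, y, band_nm, mu_t, r2), and `summary.csv` of per-map medians.
#'
#' @param maps A [build_property_maps()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_property_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(maps, file.path(dir, "property_maps.rds"))
  scalars <- c("D", "g", "albedo", "mu_s_ref", "mu_a_peak",
               if (!maps$skeleton_mode) "chl_areal_ug_cm2")
  for (q in scalars) {
    m <- maps[[q]]
    if (is.null(m)) next
    m[!maps$valid] <- NA_real_
    write_float_tiff(m, file.path(dir, paste0(q, ".tif")))
  }
  sc <- suppressWarnings(max(maps$mu_t[is.finite(maps$mu_t)], 0))
  if (!is.finite(sc) || sc == 0) sc <- 1
  pages <- lapply(seq_along(maps$band_centers), function(b) {
    m <- t(maps$mu_t[b, , ]) / sc
    m[!is.finite(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, file.path(dir, "mu_t.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  writeLines(sprintf("scale: %.17g", sc),
             file.path(dir, "mu_t.tif.scale.txt"))
  nb <- length(maps$band_centers)
  nx <- nrow(maps$D); ny <- ncol(maps$D)
  df <- data.frame(x = rep(rep(seq_len(nx), ny), each = nb),
                   y = rep(rep(seq_len(ny), each = nx), each = nb),
                   band_nm = rep(maps$band_centers, nx * ny),
                   mu_t = as.vector(maps$mu_t),
                   r2 = as.vector(maps$mu_t_r2))
  utils::write.csv(df, file.path(dir, "mu_t.csv"), row.names = FALSE)
  med <- function(m) stats::median(m[maps$valid], na.rm = TRUE)
  sm <- data.frame(
    quantity = c("D", "g", "albedo", "mu_s_ref_cm1", "mu_a_peak_cm1",
                 "mu_t_ref_cm1",
                 if (!maps$skeleton_mode) "chl_areal_ug_cm2"),
    median = c(med(maps$D), med(maps$g), med(maps$albedo),
               med(maps$mu_s_ref), med(maps$mu_a_peak),
               med(matrix(maps$mu_t[which.min(abs(maps$band_centers -
                                                    maps$lambda_ref)), , ],
                          nx, ny)),
               if (!maps$skeleton_mode) med(maps$chl_areal_ug_cm2)),
    unit = c("dimensionless", "dimensionless", "dimensionless", "1/cm",
             "1/cm", "1/cm",
             if (!maps$skeleton_mode) "ug/cm^2"))
  utils::write.csv(sm, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_property_maps
#' @param dir Run directory containing `property_maps.rds`.
#' @export
read_property_maps <- function(dir) {
  x <- readRDS(file.path(dir, "property_maps.rds"))
  stopifnot(inherits(x, "property_maps"))
  x
}

write_provenance <- function(dir, config, extra = list()) {
  prov <- c(list(package = "isoct",
                 version = as.character(utils::packageVersion("isoct")),
                 config = config), extra)
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(prov)
}
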