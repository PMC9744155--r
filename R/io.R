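#' Occurrence CSV I/O
#'
#' Plain CSV with columns `lon`, `lat`, `year`, `source` (extra columns are
#' preserved).
#'
#' @param occ occurrence data.frame.
#' @param path file path.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write rivers, forests or protected areas as GeoJSON
#'
#' Rivers become LineString features (properties `strahler_order`, `CSI`,
#' `URB`), protected areas Polygon features (property `kind`), forest points
#' Point features (properties `area_ha`, `category`). Requires the
#' `jsonlite` package.
#'
#' @param x the object produced by [generate_rivers_forests_protected()]
#'   components: a list of river segments, a list of protected polygons, or a
#'   forest data.frame.
#' @param path file path.
#' @param type one of `"rivers"`, `"protected"`, `"forests"`.
#' @export
write_geojson <- function(x, path, type = c("rivers", "protected", "forests")) {
  type <- match.arg(type)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for GeoJSON output")
  feature <- function(geom_type, coords, props) {
    list(type = "Feature",
         geometry = list(type = geom_type, coordinates = coords),
         properties = props)
  }
  feats <- switch(type,
    rivers = lapply(x, function(r)
      feature("LineString", unname(apply(r$coords, 1, c, simplify = FALSE)),
              r[c("strahler_order", "CSI", "URB")])),
    protected = lapply(x, function(p)
      feature("Polygon",
              list(unname(apply(close_ring(p$coords), 1, c, simplify = FALSE))),
              list(kind = p$kind))),
    forests = lapply(seq_len(nrow(x)), function(i)
      feature("Point", c(x$lon[i], x$lat[i]),
              list(area_ha = x$area_ha[i], category = x$category[i]))))
  doc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
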