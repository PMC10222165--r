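#' Build a station set
#'
#' A station set is a plain data.frame of point samples: monitoring stations
#' (laboratory-measured concentrations) and/or virtual sensors (retrieved
#' values). Required columns are `id`, `x`, `y`, `value`; `source` defaults to
#' `"monitoring"`. Any further numeric columns are treated as covariates
#' (turbidity, pH, water temperature, dissolved oxygen, precipitation, wind,
#' ...). Coordinates must be planar metres; geographic lon/lat input is
#' rejected because the local Taylor expansion at the core of the package
#' assumes Euclidean offsets.
#'
#' @param df data.frame with at least `id`, `x`, `y`, `value`.
#' @return validated data.frame with class `c("station_set", "data.frame")`.
#' @export
station_set <- function(df) {
  need <- c("id", "x", "y", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing station columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("station coordinates must be numeric")
  if (nrow(df) > 0 && !all(is.finite(df$x) & is.finite(df$y)))
    stop("station coordinates must be finite")
  if (anyDuplicated(df$id))
    stop("duplicate station ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (is.null(df$source)) df$source <- rep("monitoring", nrow(df))
  df$source[is.na(df$source) | !nzchar(df$source)] <- "monitoring"
  if (!all(df$source %in% c("monitoring", "virtual")))
    stop("source must be 'monitoring' or 'virtual'")
  df$value <- as.numeric(df$value)
  if (any(is.infinite(df$value), na.rm = TRUE)) stop("station values must be finite or NA")
  class(df) <- unique(c("station_set", class(df)))
  df
}

#' Covariate column names of a station set
#' @param stations a [station_set].
#' @return character vector (possibly empty).
#' @export
covariate_names <- function(stations) {
  setdiff(names(stations)[vapply(stations, is.numeric, logical(1))],
          c("x", "y", "value"))
}

#' Read / write stations as CSV or GeoJSON
#'
#' CSV columns: `id,x,y,value[,source,<covariates...>]`. GeoJSON: a
#' FeatureCollection of Point features whose properties carry `id`, `value`,
#' `source` and covariates. Records with a blank `value` are kept with
#' `value = NA` so that candidate locations can travel through the same
#' format; they are excluded from model fitting downstream.
#'
#' @param path file path; format chosen by extension (`.geojson`/`.json`
#'   versus anything else = CSV).
#' @return `read_stations` returns a [station_set]; writers invisibly return
#'   `path`.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (length(feats) == 0L)
      return(station_set(data.frame(id = character(), x = numeric(),
                                    y = numeric(), value = numeric())))
    rows <- lapply(feats, function(f) {
      props <- f$properties
      props$value <- if (is.null(props$value)) NA_real_ else as.numeric(props$value)
      c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
        props)
    })
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    return(station_set(df))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    for (cl in intersect(c("x", "y", "value"), names(df)))
      df[[cl]] <- as.numeric(df[[cl]])
  station_set(df)
}

#' @rdname read_stations
#' @param stations a [station_set] to write.
#' @export
write_stations <- function(stations, path) {
  stations <- station_set(as.data.frame(stations))
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    props <- setdiff(names(stations), c("x", "y"))
    feats <- lapply(seq_len(nrow(stations)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(stations$x[i], stations$y[i])),
           properties = as.list(stations[i, props, drop = FALSE]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(stations), path, row.names = FALSE)
  }
  invisible(path)
}
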