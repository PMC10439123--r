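# Readers and writers: CSV tables, GeoJSON geometry, the deposit bundle
# and its validator.  CSV is the canonical interchange format (stable
# diffs); GeoJSON in WGS 84 (EPSG 4326) carries geometry.

read_csv_checked <- function(path, required, what) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d
}

#' Read a taxonomic checklist CSV
#'
#' Required columns: `raw_name`, `accepted_name`, `rank`, `genus`,
#' `family`, `flags`; `parent1`/`parent2` (hybrid parents) are optional.
#' @param path file path.
#' @return checklist data.frame.
#' @export
read_checklist <- function(path) {
  d <- read_csv_checked(path, c("raw_name", "accepted_name", "rank", "genus",
                                "family", "flags"), "checklist")
  check_checklist(d)
  d
}

#' Read an OTU definition CSV (`otu_id`, `label`, `kind`, `member`)
#' @param path file path.
#' @return otu_defs data.frame.
#' @export
read_otu_defs <- function(path) {
  d <- read_csv_checked(path, c("otu_id", "label", "kind", "member"), "OTU definition")
  check_otu_defs(d)
  d
}

#' Read a member status CSV (`accepted_name`, `status`, `red_list`, `apophyte`)
#' @param path file path.
#' @return status table with logical flag columns.
#' @export
read_status_table <- function(path) {
  d <- read_csv_checked(path, c("accepted_name", "status", "red_list", "apophyte"),
                        "status")
  d$red_list <- as.logical(as.integer(d$red_list))
  d$apophyte <- as.logical(as.integer(d$apophyte))
  d
}

#' Read atlas occurrences (`square_id`, `taxon`)
#' @param path file path.
#' @return data.frame.
#' @export
read_atlas_occ <- function(path) {
  read_csv_checked(path, c("square_id", "taxon"), "atlas occurrence")
}

#' Read vegetation-plot occurrences (`plot_id`, `lon`, `lat`, `year`, `taxon`)
#' @param path file path.
#' @return data.frame.
#' @export
read_plot_occ <- function(path) {
  read_csv_checked(path, c("plot_id", "lon", "lat", "year", "taxon"),
                   "plot occurrence")
}

#' Write the per-square statistics CSV in the deposit schema
#'
#' Columns use the deposit's abbreviations and order (`Square_Id`, `JSR`,
#' `NaS`, `NaS_%`, ..., `NG`, `NF`, `SB`, `CBS`); percentage columns are
#' rounded to one decimal on output only.
#'
#' @param stats a [compute_square_stats()] result.
#' @param path output path.
#' @export
write_species_richness <- function(stats, path) {
  out <- stats[, RICHNESS_COLUMNS]
  pct_cols <- grep("_pct$", RICHNESS_COLUMNS, value = TRUE)
  for (cn in pct_cols) out[[cn]] <- round(out[[cn]], 1)
  names(out) <- RICHNESS_HEADERS
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-square statistics CSV (deposit schema)
#'
#' Validates the schema: all required columns present (errors name the
#' missing ones), unique `Square_Id`, binary `SB`/`CBS`.
#'
#' @param path file path.
#' @return data.frame of class `square_stats` with internal column names.
#' @export
read_species_richness <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(RICHNESS_HEADERS, names(d))
  if (length(miss)) {
    stop("Species_richness file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- d[, RICHNESS_HEADERS]
  names(d) <- RICHNESS_COLUMNS
  if (anyDuplicated(d$Square_Id)) {
    stop("duplicate Square_Id in Species_richness file", call. = FALSE)
  }
  for (cn in c("SB", "CBS")) {
    if (!all(d[[cn]] %in% c(0L, 1L))) {
      stop(cn, " column must be binary 0/1", call. = FALSE)
    }
  }
  class(d) <- c("square_stats", "data.frame")
  d
}

#' Write the per-OTU status table (Taxa_status role)
#' @param assignments a [classify_otus()] result.
#' @param path output path.
#' @export
write_taxa_status <- function(assignments, path) {
  out <- assignments
  out$red_list <- as.integer(out$red_list)
  out$apophyte <- as.integer(out$apophyte)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- GeoJSON ---------------------------------------------------------------

#' Read the first (Multi)Polygon from a GeoJSON file
#'
#' Supports Polygon and MultiPolygon geometries (outer rings only; holes
#' are not supported) in a Feature, FeatureCollection or bare geometry.
#'
#' @param path GeoJSON file path.
#' @return list of ring matrices in the file's coordinates (lon, lat).
#' @export
read_geojson_polygon <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- switch(g$type,
    FeatureCollection = g$features[[1L]]$geometry,
    Feature = g$geometry,
    g)
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
  }
  if (geom$type == "Polygon") {
    list(ring_mat(geom$coordinates[[1L]]))
  } else if (geom$type == "MultiPolygon") {
    lapply(geom$coordinates, function(poly) ring_mat(poly[[1L]]))
  } else {
    stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE)
  }
}

#' Write a polygon as GeoJSON (WGS 84)
#'
#' @param ring ring matrix (or list of rings) of planar coordinates.
#' @param crs the [local_crs()] used to convert to longitude/latitude.
#' @param path output path.
#' @export
write_geojson_polygon <- function(ring, crs, path) {
  rings <- if (is.list(ring)) ring else list(ring)
  to_coords <- function(r) {
    if (r[1L, 1L] != r[nrow(r), 1L] || r[1L, 2L] != r[nrow(r), 2L]) {
      r <- rbind(r, r[1L, , drop = FALSE])
    }
    ll <- planar_to_lonlat(r[, 1L], r[, 2L], crs)
    lapply(seq_len(nrow(ll)), function(i) c(ll$lon[i], ll$lat[i]))
  }
  geom <- if (length(rings) == 1L) {
    list(type = "Polygon", coordinates = list(to_coords(rings[[1L]])))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(rings, function(r) list(to_coords(r))))
  }
  obj <- list(type = "Feature", properties = stats::setNames(list(), character(0)),
              geometry = geom)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Export the grid with joined attributes as GeoJSON (WGS 84)
#'
#' One Feature per square (polygon in EPSG 4326 via the grid's local
#' projection), with the per-square statistics joined as properties.
#'
#' @param grid a [build_grid()] result.
#' @param stats optional [compute_square_stats()] result to join.
#' @param path output path.
#' @export
write_grid_geojson <- function(grid, stats = NULL, path) {
  crs <- attr(grid, "spec")$crs
  pct_cols <- grep("_pct$", RICHNESS_COLUMNS, value = TRUE)
  features <- lapply(seq_len(nrow(grid)), function(i) {
    sq <- grid[i, ]
    ring <- square_ring(sq)
    ll <- planar_to_lonlat(ring[, 1L], ring[, 2L], crs)
    props <- list(square_id = sq$square_id)
    if (!is.null(stats)) {
      row <- stats[stats$Square_Id == sq$square_id, , drop = FALSE]
      if (nrow(row) == 1L) {
        vals <- as.list(row[, setdiff(RICHNESS_COLUMNS, "Square_Id")])
        for (cn in pct_cols) vals[[cn]] <- round(vals[[cn]], 1)
        props <- c(props, vals)
      }
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ll)), function(j) {
                           c(ll$lon[j], ll$lat[j])
                         }))))
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10, na = "null")
  invisible(path)
}

# ---- deposit bundle --------------------------------------------------------

#' Read a deposit bundle directory
#'
#' Expects `Taxa_list.csv`, `Taxa_status.csv` and `Species_richness.csv`
#' (deposit schema); `Map_data.geojson` is attached when present.
#'
#' @param dir directory path.
#' @return list of class `deposit_bundle`.
#' @export
read_deposit <- function(dir) {
  need <- file.path(dir, c("Taxa_list.csv", "Taxa_status.csv",
                           "Species_richness.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("deposit is missing file(s): ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  bundle <- list(
    taxa_list = utils::read.csv(need[1L], stringsAsFactors = FALSE),
    taxa_status = utils::read.csv(need[2L], stringsAsFactors = FALSE),
    species_richness = read_species_richness(need[3L])
  )
  map_path <- file.path(dir, "Map_data.geojson")
  if (file.exists(map_path)) {
    bundle$map_data <- jsonlite::read_json(map_path, simplifyVector = FALSE)
  }
  class(bundle) <- "deposit_bundle"
  bundle
}

#' Write a deposit bundle directory from pipeline results
#'
#' @param pipeline a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @export
write_deposit <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxa_list <- pipeline$assignments[, c("otu_id", "label", "genus", "family")]
  utils::write.csv(taxa_list, file.path(dir, "Taxa_list.csv"), row.names = FALSE)
  write_taxa_status(pipeline$assignments, file.path(dir, "Taxa_status.csv"))
  write_species_richness(pipeline$stats, file.path(dir, "Species_richness.csv"))
  write_grid_geojson(pipeline$grid, pipeline$stats,
                     file.path(dir, "Map_data.geojson"))
  invisible(dir)
}

#' Validate a deposit bundle
#'
#' Recomputes, from the bundle alone: square counts overall and under the
#' CBS/SB filters, mean (raw and rounded) / min / max JSR per subset,
#' counts of flagged squares, the distinct-taxa count of the taxa list,
#' and the internal-consistency identities of the schema (status and
#' frequency partitions of JSR, Ar+Na sum, percentage columns against
#' count columns within `pct_tol`, `NF <= NG <= JSR`).  When `expected`
#' values are supplied the recomputed quantities are compared against
#' them.
#'
#' @param bundle a [read_deposit()] result.
#' @param expected optional named list (or JSON file path) of expected
#'   values; recognised names are the `quantity` values of the returned
#'   report, e.g. `n_squares`, `n_clean`, `mean_jsr_clean_rounded`,
#'   `min_jsr_clean`, `max_jsr_all`, `mean_jsr_all_rounded`, `n_sb0`,
#'   `n_cbs0`, `n_taxa`.
#' @param pct_tol tolerance for stored percentage columns, default 0.05.
#' @return data.frame of class `deposit_validation` with columns `check`,
#'   `value`, `expected`, `pass`; attribute `ok` is the conjunction.
#' @export
validate_deposit <- function(bundle, expected = NULL, pct_tol = 0.05) {
  sr <- bundle$species_richness
  if (is.character(expected)) expected <- jsonlite::read_json(expected,
                                                              simplifyVector = TRUE)
  checks <- list()
  add <- function(name, value, pass = NA, expected_val = NA) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = as.numeric(value), expected = as.numeric(expected_val),
      pass = pass, stringsAsFactors = FALSE)
  }

  # internal consistency
  add("status_partition", sum(sr$NaS + sr$ArS + sr$NeS != sr$JSR),
      pass = all(sr$NaS + sr$ArS + sr$NeS == sr$JSR))
  add("freq_partition", sum(sr$RS + sr$MS + sr$CS != sr$JSR),
      pass = all(sr$RS + sr$MS + sr$CS == sr$JSR))
  add("arna_sum", sum(sr$ArNaS != sr$ArS + sr$NaS),
      pass = all(sr$ArNaS == sr$ArS + sr$NaS))
  add("genus_family_order", sum(!(sr$NF <= sr$NG & sr$NG <= sr$JSR)),
      pass = all(sr$NF <= sr$NG & sr$NG <= sr$JSR))
  n_pct_bad <- 0L
  for (cnt in c("NaS", "ReLS", "NeS", "ArS", "ArNaS", "ApS", "RS", "MS", "CS")) {
    pcol <- paste0(cnt, "_pct")
    expect <- ifelse(sr$JSR > 0, 100 * sr[[cnt]] / sr$JSR, NA_real_)
    stored <- sr[[pcol]]
    # epsilon absorbs float representation at exact half-rounding boundaries
    bad <- sum(abs(stored - expect) > pct_tol + 1e-9, na.rm = TRUE) +
      sum(is.na(stored) != is.na(expect))
    n_pct_bad <- n_pct_bad + bad
  }
  add("percentage_columns", n_pct_bad, pass = n_pct_bad == 0L)

  # recomputed overview quantities (compared to `expected` when given)
  subsets <- list(all = rep(TRUE, nrow(sr)),
                  no_cbs = sr$CBS == 1L,
                  clean = sr$CBS == 1L & sr$SB == 1L)
  quantities <- list(n_squares = nrow(sr),
                     n_sb0 = sum(sr$SB == 0L),
                     n_cbs0 = sum(sr$CBS == 0L),
                     n_taxa = length(unique(bundle$taxa_list[[1L]])))
  for (nm in names(subsets)) {
    keep <- subsets[[nm]]
    jsr <- sr$JSR[keep]
    quantities[[paste0("n_", if (nm == "all") "all" else nm)]] <- sum(keep)
    quantities[[paste0("mean_jsr_", nm, "_rounded")]] <- floor(mean(jsr) + 0.5)
    quantities[[paste0("min_jsr_", nm)]] <- min(jsr)
    quantities[[paste0("max_jsr_", nm)]] <- max(jsr)
  }
  for (nm in names(quantities)) {
    exp_v <- if (!is.null(expected) && nm %in% names(expected)) expected[[nm]] else NA
    add(nm, quantities[[nm]],
        pass = if (is.na(exp_v)) NA else quantities[[nm]] == exp_v,
        expected_val = exp_v)
  }
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass[!is.na(out$pass)])
  class(out) <- c("deposit_validation", "data.frame")
  out
}
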