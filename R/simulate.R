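# Synthetic atlas + vegetation-plot data with known ground truth.
#
# The generator emulates the statistical structure of a national floristic
# data set: a species pool with a log-series occupancy distribution,
# spatially coherent ranges (Gaussian kernel around a range centre),
# microspecies genera, aggregates, hybrids, nomenclatural synonyms, an
# exhaustive atlas source and a plot source with imperfect detection, plus
# injected low-effort squares.  Everything is reproducible from
# (seed, config) alone; each stage draws from its own deterministically
# derived sub-stream so partial re-runs stay stable.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the desk-scale study condition: a 20 x 20 grid of
#' 10 km squares, a pool of 300 base species, two microspecies genera
#' collapsed at genus level, a log-series occupancy distribution, near-
#' exhaustive atlas coverage, a plot source with partial detection, and
#' 20 squares with strongly reduced recording effort.
#'
#' @param seed integer master seed.
#' @param grid_rows,grid_cols grid dimensions.
#' @param cell_size cell side (m).
#' @param n_species number of base species (excluding derived subspecies,
#'   synonyms and hybrids).
#' @param sad_shape Fisher log-series parameter x in (0, 1) for species
#'   abundances; target occupancy follows a saturating abundance-occupancy
#'   relation, so larger x means more near-ubiquitous species.
#' @param status_mix named proportions over native/archeophyte/neophyte
#'   (must sum to 1).
#' @param p_red_list,p_apophyte,p_cultivar,p_ephemerophyte,p_extinct
#'   per-species flag probabilities.
#' @param p_subspecies probability that a base species spawns one accepted
#'   subspecies.
#' @param n_microspecies_genera,microspecies_per_genus microspecies genera
#'   collapsed wholesale (the Taraxacum/Hieracium situation).
#' @param n_aggregates number of aggregate / sensu-lato OTU definitions.
#' @param n_hybrids hybrid checklist rows (half resolvable into an
#'   aggregate, half not).
#' @param synonym_rate probability that a species has a synonym, and that
#'   a reported record uses it.
#' @param p_max occupancy-kernel ceiling: detection-free probability of
#'   presence at the range centre.  Default 1: at the 10-km scale a
#'   species is treated as present wherever its range overlaps; rarity
#'   comes from range size, noise from the observation layers.
#' @param plots_per_square_mean Poisson mean of vegetation plots per square.
#' @param detection_per_plot probability that a plot records a locally
#'   present species.
#' @param undersampled_squares number of injected low-effort squares.
#' @param undersampling_retention fraction of records retained in injected
#'   squares (applied to both sources).
#' @param years inclusive range plot years are drawn from.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       grid_rows = 20L, grid_cols = 20L, cell_size = 10000,
                       n_species = 300L,
                       sad_shape = 0.999,
                       status_mix = c(native = 0.70, archeophyte = 0.15,
                                      neophyte = 0.15),
                       p_red_list = 0.15, p_apophyte = 0.30,
                       p_cultivar = 0.03, p_ephemerophyte = 0.03,
                       p_extinct = 0.02, p_subspecies = 0.05,
                       n_microspecies_genera = 2L, microspecies_per_genus = 25L,
                       n_aggregates = 10L, n_hybrids = 6L,
                       synonym_rate = 0.10,
                       p_max = 1.0,
                       plots_per_square_mean = 3,
                       detection_per_plot = 0.5,
                       undersampled_squares = 20L,
                       undersampling_retention = 0.4,
                       years = c(1925L, 2020L)) {
  cfg <- as.list(environment())
  probs <- c(p_red_list, p_apophyte, p_cultivar, p_ephemerophyte, p_extinct,
             p_subspecies, synonym_rate, detection_per_plot,
             undersampling_retention, p_max)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(status_mix) - 1) > 1e-8 || any(status_mix < 0)) {
    stop("status_mix must be non-negative and sum to 1", call. = FALSE)
  }
  if (!all(names(status_mix) == c("native", "archeophyte", "neophyte"))) {
    stop("status_mix must be named native, archeophyte, neophyte", call. = FALSE)
  }
  if (sad_shape <= 0 || sad_shape >= 1) stop("sad_shape must be in (0, 1)", call. = FALSE)
  counts <- c(grid_rows, grid_cols, n_species, n_microspecies_genera,
              microspecies_per_genus, n_aggregates, n_hybrids,
              undersampled_squares)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# sub-stream seeds derived once from the master seed (kept under 2^31)
sim_streams <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 6L),
                  c("pool", "territory", "occupancy", "undersample",
                    "atlas", "plots"))
}

# deterministic pseudo-Latin name parts
make_latin <- function(n, capital, rng_unused = NULL) {
  start <- c("car", "ver", "sil", "pol", "tri", "lam", "fes", "ran", "gal",
             "cam", "pot", "ach", "sen", "hier", "erig", "dian", "alch",
             "myo", "cir", "ast", "vic", "sax", "gen", "luz", "jun")
  mid <- c("on", "ath", "ic", "ul", "an", "ell", "id", "ob", "ar", "em",
           "ig", "os", "ut", "ev", "om")
  end <- if (capital) c("ia", "us", "um", "ella", "ago", "aria", "ium", "ula")
         else c("a", "us", "um", "ense", "oides", "icum", "ata", "osa", "ifolia")
  out <- character(0)
  k <- 0L
  while (length(out) < n) {
    k <- k + 1L
    nm <- paste0(sample(start, 1L),
                 paste0(sample(mid, sample(1:2, 1L)), collapse = ""),
                 sample(end, 1L))
    if (k > 50L * n) nm <- paste0(nm, k)  # uniqueness safety valve
    if (capital) substr(nm, 1L, 1L) <- toupper(substr(nm, 1L, 1L))
    if (!(nm %in% out)) out <- c(out, nm)
  }
  out
}

#' Generate the synthetic species pool
#'
#' Builds the checklist (with synonyms, flags and hybrid parent pointers),
#' the OTU definition table, the genus-collapse list and the member status
#' table.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_pool`: `checklist`, `otu_defs`,
#'   `genus_collapse`, `status_table`, `species` (accepted names that can
#'   carry occurrences).
#' @export
generate_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_streams(cfg$seed)[["pool"]])

  n_micro_total <- cfg$n_microspecies_genera * cfg$microspecies_per_genus
  n_regular <- cfg$n_species - n_micro_total
  if (n_regular < 10L) stop("n_species too small for the microspecies settings",
                            call. = FALSE)

  n_reg_genera <- max(3L, round(n_regular / 4))
  genera <- make_latin(n_reg_genera + cfg$n_microspecies_genera, capital = TRUE)
  micro_genera <- genera[seq_len(cfg$n_microspecies_genera)]
  reg_genera <- setdiff(genera, micro_genera)

  n_families <- max(2L, ceiling(length(genera) / 4))
  families <- paste0(make_latin(n_families, capital = TRUE), "ceae")
  fam_of_genus <- stats::setNames(sample(families, length(genera), replace = TRUE),
                                  genera)

  epithets <- make_latin(n_regular + n_micro_total + 200L, capital = FALSE)
  ep_i <- 0L
  next_epithet <- function() {
    ep_i <<- ep_i + 1L
    epithets[ep_i]
  }

  sp_genus <- sample(reg_genera, n_regular, replace = TRUE)
  regular <- vapply(sp_genus, function(g) paste(g, next_epithet()), character(1),
                    USE.NAMES = FALSE)

  micro <- character(0)
  micro_genus <- character(0)
  for (g in micro_genera) {
    micro <- c(micro, vapply(seq_len(cfg$microspecies_per_genus),
                             function(i) paste(g, next_epithet()), character(1)))
    micro_genus <- c(micro_genus, rep(g, cfg$microspecies_per_genus))
  }

  species <- c(regular, micro)
  genus <- c(sp_genus, micro_genus)
  rank <- rep("species", length(species))

  # accepted subspecies of some regular species (exercise RL propagation
  # and infraspecific folding)
  is_sub_parent <- stats::runif(n_regular) < cfg$p_subspecies
  subs <- if (any(is_sub_parent)) {
    paste(regular[is_sub_parent], "subsp.",
          vapply(seq_len(sum(is_sub_parent)), function(i) next_epithet(),
                 character(1)))
  } else character(0)
  species <- c(species, subs)
  genus <- c(genus, sp_genus[is_sub_parent])
  rank <- c(rank, rep("subspecies", length(subs)))

  # aggregate / sensu-lato definitions over regular genera with >= 2 species
  otu_defs <- data.frame(otu_id = character(0), label = character(0),
                         kind = character(0), member = character(0),
                         stringsAsFactors = FALSE)
  by_genus <- split(regular, sp_genus)
  cand <- names(by_genus)[vapply(by_genus, length, integer(1)) >= 2L]
  used <- character(0)
  n_agg <- min(cfg$n_aggregates, length(cand))
  agg_genera <- sample(cand, n_agg)
  for (j in seq_len(n_agg)) {
    pool_sp <- setdiff(by_genus[[agg_genera[j]]], used)
    if (length(pool_sp) < 2L) next
    sizes <- 2:min(4L, length(pool_sp))
    size <- sizes[sample.int(length(sizes), 1L)]
    members <- sample(pool_sp, size)
    used <- c(used, members)
    kind <- if (j %% 2L == 0L) "sensu_lato" else "aggregate"
    suffix <- if (kind == "aggregate") "agg." else "s.l."
    label <- paste(members[1L], suffix)
    otu_defs <- rbind(otu_defs, data.frame(
      otu_id = label, label = label, kind = kind, member = members,
      stringsAsFactors = FALSE))
  }

  # hybrids: odd ones resolvable (parents inside one aggregate), even not
  hyb_names <- character(0)
  hyb_parents <- matrix(character(0), ncol = 2L)
  agg_ids <- unique(otu_defs$otu_id)
  for (h in seq_len(cfg$n_hybrids)) {
    g <- sample(reg_genera, 1L)
    hyb <- paste(g, paste0("x", next_epithet()))
    if (h %% 2L == 1L && length(agg_ids) > 0L) {
      id <- sample(agg_ids, 1L)
      mem <- otu_defs$member[otu_defs$otu_id == id]
      par <- sample(mem, 2L)
    } else {
      par <- sample(regular, 2L)  # usually in different OTUs -> unresolved
    }
    hyb_names <- c(hyb_names, hyb)
    hyb_parents <- rbind(hyb_parents, par)
  }

  all_accepted <- c(species, hyb_names)
  all_genus <- c(genus, vapply(strsplit(hyb_names, " "), `[`, character(1), 1L))
  all_rank <- c(rank, rep("hybrid", length(hyb_names)))

  # flags on regular species only (microspecies/subspecies/hybrids are
  # never cultivars here)
  flag_of <- rep("", length(all_accepted))
  reg_idx <- seq_len(n_regular)
  u <- stats::runif(n_regular)
  flag_of[reg_idx][u < cfg$p_cultivar] <- "cultivar"
  flag_of[reg_idx][u >= cfg$p_cultivar &
                   u < cfg$p_cultivar + cfg$p_ephemerophyte] <- "ephemerophyte"
  flag_of[reg_idx][u >= cfg$p_cultivar + cfg$p_ephemerophyte &
                   u < cfg$p_cultivar + cfg$p_ephemerophyte + cfg$p_extinct] <- "extinct"

  parent1 <- rep(NA_character_, length(all_accepted))
  parent2 <- rep(NA_character_, length(all_accepted))
  hyb_rows <- seq_along(hyb_names) + length(species)
  if (length(hyb_names)) {
    parent1[hyb_rows] <- hyb_parents[, 1L]
    parent2[hyb_rows] <- hyb_parents[, 2L]
  }

  checklist <- data.frame(
    raw_name = all_accepted, accepted_name = all_accepted,
    rank = all_rank, genus = all_genus,
    family = unname(fam_of_genus[all_genus]),
    flags = flag_of, parent1 = parent1, parent2 = parent2,
    stringsAsFactors = FALSE
  )

  # synonym rows: alternative raw names mapping to the accepted name
  has_syn <- stats::runif(length(species)) < cfg$synonym_rate
  if (any(has_syn)) {
    syn_raw <- paste0(species[has_syn], "ii")
    checklist <- rbind(checklist, data.frame(
      raw_name = syn_raw, accepted_name = species[has_syn],
      rank = rank[has_syn], genus = genus[has_syn],
      family = unname(fam_of_genus[genus[has_syn]]),
      flags = "", parent1 = NA_character_, parent2 = NA_character_,
      stringsAsFactors = FALSE))
  }

  status <- sample(names(cfg$status_mix), length(all_accepted), replace = TRUE,
                   prob = cfg$status_mix)
  red_list <- stats::runif(length(all_accepted)) < cfg$p_red_list
  apophyte <- status != "neophyte" &
    stats::runif(length(all_accepted)) < cfg$p_apophyte
  # subspecies inherit their parent's status (they are the same biological
  # entity for the alien/native axis)
  sub_rows <- which(all_rank == "subspecies")
  if (length(sub_rows)) {
    par <- binomial_of(all_accepted[sub_rows])
    status[sub_rows] <- status[match(par, all_accepted)]
  }
  status_table <- data.frame(accepted_name = all_accepted, status = status,
                             red_list = red_list, apophyte = apophyte,
                             stringsAsFactors = FALSE)

  structure(list(checklist = checklist, otu_defs = otu_defs,
                 genus_collapse = micro_genera, status_table = status_table,
                 species = all_accepted),
            class = "sim_pool")
}

# Fisher log-series abundance sampler, P(n) proportional to x^n / n
rlogseries <- function(n, x, kmax = 20000L) {
  k <- seq_len(kmax)
  p <- exp(k * log(x) - log(k))
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

# Saturating abundance-occupancy link: a species of log-series abundance n
# occupies an expected t = N * (1 - exp(-n / (occ_halfsat * N))) squares.
# Occupancy saturates with abundance, so the handful of most abundant
# species are (near-)ubiquitous -- the empirical premise of the
# benchmark-species detector -- while the log-series tail stays rare.
occupancy_targets <- function(abund, n_squares, occ_halfsat = 0.15) {
  t <- n_squares * (1 - exp(-abund / (occ_halfsat * n_squares)))
  pmin(n_squares, pmax(1L, round(t)))
}

#' Generate the true occupancy map
#'
#' Each species gets a range centre (uniform over the grid extent) and a
#' Gaussian range kernel whose radius is solved so that its expected
#' occupied-square count matches a log-series draw; presence is then
#' sampled independently per square with probability
#' `p_max * exp(-d^2 / (2 r^2))`.
#'
#' @param cfg a [sim_config()].
#' @param pool a [generate_pool()] result.
#' @param grid a [build_grid()] result.
#' @return list of class `sim_truth`: `occupancy` (data.frame `square_id`,
#'   `accepted_name`), `targets` (named target counts),
#'   `injected_undersampled` (character vector of square ids).
#' @export
generate_occupancy <- function(cfg, pool, grid) {
  streams <- sim_streams(cfg$seed)
  set.seed(streams[["occupancy"]])
  spp <- pool$species
  n_sq <- nrow(grid)
  cx <- (grid$x0 + grid$x1) / 2
  cy <- (grid$y0 + grid$y1) / 2
  extent <- c(min(grid$x0), min(grid$y0), max(grid$x1), max(grid$y1))

  abund <- rlogseries(length(spp), cfg$sad_shape)
  targets <- occupancy_targets(abund, n_sq)
  names(targets) <- spp
  names(abund) <- spp

  occ_rows <- vector("list", length(spp))
  cell <- attr(grid, "spec")$cell_size
  for (i in seq_along(spp)) {
    ctr <- c(stats::runif(1, extent[1], extent[3]),
             stats::runif(1, extent[2], extent[4]))
    d2 <- (cx - ctr[1])^2 + (cy - ctr[2])^2
    t_i <- targets[i]
    expect_occ <- function(logr) {
      r2 <- exp(2 * logr)
      sum(cfg$p_max * exp(-d2 / (2 * r2)))
    }
    lo <- log(cell / 100); hi <- log(100 * (extent[3] - extent[1] + cell))
    if (t_i >= expect_occ(hi)) {
      p <- rep(cfg$p_max, n_sq)
    } else if (t_i <= expect_occ(lo)) {
      p <- cfg$p_max * exp(-d2 / (2 * exp(2 * lo)))
    } else {
      r <- stats::uniroot(function(lr) expect_occ(lr) - t_i, c(lo, hi),
                          tol = 1e-6)$root
      p <- cfg$p_max * exp(-d2 / (2 * exp(2 * r)))
    }
    hit <- stats::runif(n_sq) < p
    if (any(hit)) {
      occ_rows[[i]] <- data.frame(square_id = grid$square_id[hit],
                                  accepted_name = spp[i],
                                  stringsAsFactors = FALSE)
    }
  }
  occupancy <- do.call(rbind, occ_rows)
  rownames(occupancy) <- NULL

  set.seed(streams[["undersample"]])
  injected <- sample(grid$square_id,
                     min(cfg$undersampled_squares, n_sq))
  # Low effort deletes records at the (square, species) level, shared by
  # both sources: a species never recorded in a poorly surveyed square is
  # missing from the atlas and from any plot-derived data alike.
  keep <- retained(occupancy$square_id, injected, cfg$undersampling_retention)
  observed <- occupancy[keep, , drop = FALSE]
  rownames(observed) <- NULL

  structure(list(occupancy = occupancy, observed = observed,
                 abundance = abund, targets = targets,
                 injected_undersampled = injected),
            class = "sim_truth")
}

#' Synthetic territory polygon
#'
#' An irregular polygon covering the grid interior whose boundary wanders
#' through the outer ring of cells, so that edge squares get inside-area
#' fractions on both sides of the 80% threshold.
#'
#' @param cfg a [sim_config()].
#' @param grid a [build_grid()] result.
#' @return a closed ring matrix (planar metres).
#' @export
simulate_territory <- function(cfg, grid) {
  set.seed(sim_streams(cfg$seed)[["territory"]])
  cell <- attr(grid, "spec")$cell_size
  x0 <- min(grid$x0); y0 <- min(grid$y0)
  x1 <- max(grid$x1); y1 <- max(grid$y1)
  inset <- 0.05 * cell
  step <- cell
  wiggle <- function(n) stats::runif(n, 0, 0.9 * cell)
  xs <- seq(x0 + inset, x1 - inset, by = step)
  ys <- seq(y0 + inset, y1 - inset, by = step)
  bottom <- cbind(xs, y0 + inset + wiggle(length(xs)))
  right <- cbind(x1 - inset - wiggle(length(ys)), ys)
  top <- cbind(rev(xs), y1 - inset - wiggle(length(xs)))
  left <- cbind(x0 + inset + wiggle(length(ys)), rev(ys))
  ring <- rbind(bottom, right, top, left)
  rbind(ring, ring[1L, , drop = FALSE])
}

# in injected squares only `retention` of the recording effort survives
retained <- function(square_id, injected, retention) {
  p <- ifelse(square_id %in% injected, retention, 1)
  stats::runif(length(square_id)) < p
}

# replace accepted names by a synonym raw name with prob synonym_rate
synonymize <- function(names, pool, rate) {
  syn <- pool$checklist[pool$checklist$raw_name != pool$checklist$accepted_name, ]
  if (nrow(syn) == 0L || rate <= 0) return(names)
  alt <- syn$raw_name[match(names, syn$accepted_name)]
  swap <- !is.na(alt) & stats::runif(length(names)) < rate
  names[swap] <- alt[swap]
  names
}

#' Sample the atlas source from the ground truth
#'
#' One confirmed locality suffices to fill an atlas square, so every
#' recorded (square, species) pair is reported: detection is 1 in
#' normally surveyed squares and `undersampling_retention` in the
#' injected low-effort squares (the record-level deletion happens once,
#' in the shared observed pool).  Reported names use a synonym with
#' probability `synonym_rate`.
#'
#' @param truth a [generate_occupancy()] result.
#' @param cfg a [sim_config()].
#' @param pool a [generate_pool()] result.
#' @return data.frame `square_id`, `taxon`.
#' @export
sample_atlas <- function(truth, cfg, pool) {
  set.seed(sim_streams(cfg$seed)[["atlas"]])
  out <- truth$observed
  data.frame(square_id = out$square_id,
             taxon = synonymize(out$accepted_name, pool, cfg$synonym_rate),
             stringsAsFactors = FALSE)
}

#' Sample the vegetation-plot source from the ground truth
#'
#' Poisson-many plots per square at uniform positions; each plot records
#' each locally recorded species (the shared observed pool, which already
#' carries the low-effort deletion in injected squares) with probability
#' `detection_per_plot`; years uniform on the configured interval;
#' coordinates output in WGS 84 longitude/latitude.
#'
#' @inheritParams sample_atlas
#' @param grid a [build_grid()] result.
#' @return data.frame `plot_id`, `lon`, `lat`, `year`, `taxon` (long
#'   format).
#' @export
sample_plots <- function(truth, cfg, pool, grid) {
  set.seed(sim_streams(cfg$seed)[["plots"]])
  spec <- attr(grid, "spec")
  occ_by_sq <- split(truth$observed$accepted_name, truth$observed$square_id)
  n_plots <- stats::rpois(nrow(grid), cfg$plots_per_square_mean)
  rows <- vector("list", nrow(grid))
  plot_no <- 0L
  for (i in seq_len(nrow(grid))) {
    if (n_plots[i] == 0L) next
    sq <- grid$square_id[i]
    local <- occ_by_sq[[sq]]
    det <- cfg$detection_per_plot
    sq_rows <- vector("list", n_plots[i])
    for (p in seq_len(n_plots[i])) {
      plot_no <- plot_no + 1L
      px <- stats::runif(1, grid$x0[i], grid$x1[i])
      py <- stats::runif(1, grid$y0[i], grid$y1[i])
      yr <- sample(cfg$years[1L]:cfg$years[2L], 1L)
      found <- if (length(local)) local[stats::runif(length(local)) < det]
               else character(0)
      if (length(found) == 0L) {
        # empty relevés are not stored; plot id still advances
        next
      }
      ll <- planar_to_lonlat(px, py, spec$crs)
      sq_rows[[p]] <- data.frame(
        plot_id = sprintf("plot_%06d", plot_no),
        lon = ll$lon, lat = ll$lat, year = yr,
        taxon = synonymize(found, pool, cfg$synonym_rate),
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, sq_rows)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(plot_id = character(0), lon = numeric(0), lat = numeric(0),
                      year = integer(0), taxon = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Run the whole generator
#'
#' @param cfg a [sim_config()].
#' @return list of class `simulation`: `cfg`, `spec`, `grid`, `territory`,
#'   `pool`, `truth`, `atlas`, `plots`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  spec <- grid_spec(n_rows = cfg$grid_rows, n_cols = cfg$grid_cols,
                    cell_size = cfg$cell_size)
  grid <- build_grid(spec)
  pool <- generate_pool(cfg)
  territory <- simulate_territory(cfg, grid)
  truth <- generate_occupancy(cfg, pool, grid)
  atlas <- sample_atlas(truth, cfg, pool)
  plots <- sample_plots(truth, cfg, pool, grid)
  structure(list(cfg = cfg, spec = spec, grid = grid, territory = territory,
                 pool = pool, truth = truth, atlas = atlas, plots = plots),
            class = "simulation")
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf(
    "synthetic data set: %d x %d grid, %d accepted taxa, %d atlas records, %d plot records\n",
    x$cfg$grid_rows, x$cfg$grid_cols, length(x$pool$species),
    nrow(x$atlas), nrow(x$plots)))
  invisible(x)
}

#' Write a synthetic data set to a fixture directory
#'
#' Writes `atlas.csv`, `plots.csv`, `checklist.csv`, `otu_defs.csv`,
#' `status.csv`, `territory.geojson` (WGS 84) and the ground-truth
#' sidecar `truth.json` (true occupancy pairs, injected square ids,
#' genus-collapse list).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$atlas, file.path(dir, "atlas.csv"), row.names = FALSE)
  utils::write.csv(sim$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(sim$pool$checklist, file.path(dir, "checklist.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$pool$otu_defs, file.path(dir, "otu_defs.csv"),
                   row.names = FALSE)
  st <- sim$pool$status_table
  st$red_list <- as.integer(st$red_list)
  st$apophyte <- as.integer(st$apophyte)
  utils::write.csv(st, file.path(dir, "status.csv"), row.names = FALSE)
  write_geojson_polygon(sim$territory, sim$spec$crs,
                        file.path(dir, "territory.geojson"))
  cfg <- sim$cfg
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = 10)
  jsonlite::write_json(
    list(occupancy = sim$truth$occupancy,
         injected_undersampled = sim$truth$injected_undersampled,
         genus_collapse = sim$pool$genus_collapse,
         seed = sim$cfg$seed),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = 10)
  invisible(dir)
}

#' Ground-truth OTU richness per square
#'
#' Collapses the true occupancy through the same OTU mapping the pipeline
#' uses (minus excluded taxa), yielding the per-square richness an
#' error-free pipeline must reproduce.
#'
#' @param sim a [simulate_dataset()] result.
#' @param exclude_otus otu_ids to drop (e.g. units the status-conflict
#'   rule removes from the analyzable set).
#' @return data.frame `square_id`, `true_jsr` for every grid square.
#' @export
true_richness <- function(sim, exclude_otus = character(0)) {
  excl <- apply_exclusions(sim$pool$checklist)
  occ <- sim$truth$occupancy
  occ <- occ[!(occ$accepted_name %in% excl$log$accepted_name), , drop = FALSE]
  hyb <- sim$pool$checklist[sim$pool$checklist$rank == "hybrid", , drop = FALSE]
  res <- vapply(seq_len(nrow(hyb)), function(i) {
    resolve_hybrid(c(hyb$parent1[i], hyb$parent2[i]), sim$pool$otu_defs)
  }, character(1))
  bad_hyb <- hyb$accepted_name[is.na(res)]
  ok_hyb <- stats::setNames(res[!is.na(res)], hyb$accepted_name[!is.na(res)])
  occ <- occ[!(occ$accepted_name %in% bad_hyb), , drop = FALSE]
  otu <- ifelse(occ$accepted_name %in% names(ok_hyb),
                ok_hyb[occ$accepted_name],
                collapse_to_otu(occ$accepted_name, sim$pool$otu_defs,
                                sim$pool$genus_collapse, sim$pool$checklist))
  pairs <- unique(data.frame(square_id = occ$square_id, otu_id = otu,
                             stringsAsFactors = FALSE))
  pairs <- pairs[!(pairs$otu_id %in% exclude_otus), , drop = FALSE]
  n <- tapply(pairs$otu_id, factor(pairs$square_id, levels = sim$grid$square_id),
              length, default = 0L)
  data.frame(square_id = sim$grid$square_id, true_jsr = as.integer(n),
             stringsAsFactors = FALSE)
}
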