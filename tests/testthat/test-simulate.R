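# Synthetic-data generator: determinism, distributional targets, limit
# cases.

test_that("generation is reproducible from (seed, config) alone", {
  cfg <- sim_config(seed = 17, grid_rows = 6L, grid_cols = 6L, n_species = 70L,
                    n_microspecies_genera = 1L, microspecies_per_genus = 8L,
                    n_aggregates = 3L, n_hybrids = 2L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pool$checklist, s2$pool$checklist)
  expect_identical(s1$truth$occupancy, s2$truth$occupancy)
  expect_identical(s1$atlas, s2$atlas)
  expect_identical(s1$plots, s2$plots)
  expect_identical(s1$territory, s2$territory)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(p_cultivar = 1.5), "probabilities")
  expect_error(sim_config(status_mix = c(native = 0.5, archeophyte = 0.2,
                                         neophyte = 0.2)), "sum to 1")
  expect_error(sim_config(sad_shape = 1), "sad_shape")
  expect_error(sim_config(n_hybrids = -1), "counts")
})

test_that("pool respects structural settings", {
  cfg <- sim_config(seed = 2, n_hybrids = 0L, n_species = 120L,
                    n_microspecies_genera = 2L, microspecies_per_genus = 10L)
  pool <- generate_pool(cfg)
  expect_false(any(pool$checklist$rank == "hybrid"))
  expect_length(pool$genus_collapse, 2L)
  for (g in pool$genus_collapse) {
    expect_equal(sum(pool$checklist$genus == g &
                       pool$checklist$rank == "species" &
                       pool$checklist$raw_name == pool$checklist$accepted_name),
                 10L)
  }
  # every accepted name is unique; every OTU member is an accepted name
  acc <- pool$checklist$accepted_name[pool$checklist$raw_name ==
                                        pool$checklist$accepted_name]
  expect_equal(anyDuplicated(acc), 0L)
  expect_true(all(pool$otu_defs$member %in% acc))
  # status table covers the whole pool
  expect_setequal(pool$status_table$accepted_name, acc)
})

test_that("cultivar counts follow the configured binomial rate", {
  n <- 300L
  p <- 0.05
  counts <- vapply(1:60, function(s) {
    pool <- generate_pool(sim_config(seed = 1000L + s, n_species = n,
                                     p_cultivar = p))
    sum(has_flag <- grepl("cultivar", pool$checklist$flags))
  }, numeric(1))
  # flags are drawn only for the regular (non-microspecies) species
  n_reg <- n - 2L * 25L
  exp_mean <- n_reg * p
  sd3 <- 3 * sqrt(n_reg * p * (1 - p)) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - exp_mean), sd3)
})

test_that("occupancy kernel limit cases behave as forced", {
  cfg <- sim_config(seed = 4, grid_rows = 5L, grid_cols = 5L, n_species = 40L,
                    n_microspecies_genera = 0L, microspecies_per_genus = 0L,
                    n_aggregates = 0L, n_hybrids = 0L)
  pool <- generate_pool(cfg)
  grid <- build_grid(grid_spec(n_rows = 5, n_cols = 5))
  truth <- generate_occupancy(cfg, pool, grid)
  # a species whose target equals the grid size occupies every square
  # (p_max = 1 and the radius solver saturates)
  full <- names(truth$targets)[truth$targets == 25]
  if (length(full)) {
    occ_n <- table(truth$occupancy$accepted_name)[full]
    expect_true(all(occ_n == 25))
  }
  # every species occupies at least its target's support within the grid
  expect_true(all(truth$occupancy$square_id %in% grid$square_id))
})

test_that("realized occupancy tracks the abundance-driven targets", {
  rho <- vapply(1:5, function(s) {
    sim <- small_sim(seed = 200 + s)
    occ <- table(factor(sim$truth$occupancy$accepted_name,
                        levels = names(sim$truth$targets)))
    suppressWarnings(cor(as.integer(occ), sim$truth$targets,
                         method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rho), 0.9)
})

test_that("plot detection saturates to true occupancy", {
  # detection 1 with at least one plot per square recovers local truth
  cfg <- sim_config(seed = 6, grid_rows = 4L, grid_cols = 4L, n_species = 50L,
                    n_microspecies_genera = 0L, microspecies_per_genus = 0L,
                    n_aggregates = 0L, n_hybrids = 0L, synonym_rate = 0,
                    detection_per_plot = 1, plots_per_square_mean = 6,
                    undersampled_squares = 0L)
  sim <- simulate_dataset(cfg)
  xy <- lonlat_to_planar(sim$plots$lon, sim$plots$lat, sim$spec$crs)
  plot_sq <- assign_point(xy$x, xy$y, sim$spec)
  plot_pairs <- unique(data.frame(square_id = plot_sq, name = sim$plots$taxon))
  truth_pairs <- unique(sim$truth$occupancy)
  # restrict truth to squares that received at least one plot
  covered <- unique(plot_pairs$square_id)
  tp <- truth_pairs[truth_pairs$square_id %in% covered, ]
  expect_equal(nrow(plot_pairs), nrow(tp))
  # zero plot intensity -> empty table
  cfg0 <- sim_config(seed = 6, plots_per_square_mean = 0)
  pool0 <- generate_pool(cfg0)
  g0 <- build_grid(grid_spec(n_rows = cfg0$grid_rows, n_cols = cfg0$grid_cols))
  truth0 <- generate_occupancy(cfg0, pool0, g0)
  expect_equal(nrow(sample_plots(truth0, cfg0, pool0, g0)), 0L)
})

test_that("noise-free atlas equals true occupancy", {
  cfg <- sim_config(seed = 8, grid_rows = 5L, grid_cols = 5L, n_species = 40L,
                    n_microspecies_genera = 0L, microspecies_per_genus = 0L,
                    n_aggregates = 0L, n_hybrids = 0L,
                    synonym_rate = 0, undersampling_retention = 1)
  pool <- generate_pool(cfg)
  grid <- build_grid(grid_spec(n_rows = 5, n_cols = 5))
  truth <- generate_occupancy(cfg, pool, grid)
  atlas <- sample_atlas(truth, cfg, pool)
  expect_equal(nrow(atlas), nrow(truth$occupancy))
  expect_setequal(paste(atlas$square_id, atlas$taxon),
                  paste(truth$occupancy$square_id, truth$occupancy$accepted_name))
})

test_that("injected squares lose records at the configured retention", {
  cfg <- sim_config(seed = 12, undersampling_retention = 0.4)
  sim <- simulate_dataset(cfg)
  inj <- sim$truth$injected_undersampled
  t_in <- sum(sim$truth$occupancy$square_id %in% inj)
  o_in <- sum(sim$truth$observed$square_id %in% inj)
  # binomial check within 3 SD
  expect_lt(abs(o_in - 0.4 * t_in), 3 * sqrt(t_in * 0.4 * 0.6))
  # untouched squares keep everything
  t_out <- sim$truth$occupancy[!(sim$truth$occupancy$square_id %in% inj), ]
  o_out <- sim$truth$observed[!(sim$truth$observed$square_id %in% inj), ]
  expect_equal(nrow(o_out), nrow(t_out))
})

test_that("the synthetic territory produces both kept and excluded edge squares", {
  sim <- small_sim(seed = 21)
  cbs <- grid_cbs(sim$grid, sim$territory)
  expect_true(any(cbs$CBS == 0L))
  expect_true(any(cbs$CBS == 1L))
  interior <- sim$grid$row > 0 & sim$grid$row < 7 & sim$grid$col > 0 & sim$grid$col < 7
  expect_true(all(cbs$CBS[interior] == 1L))
  expect_true(all(cbs$inside_fraction >= 0 & cbs$inside_fraction <= 1))
})
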