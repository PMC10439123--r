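# Name standardization, exclusions, OTU collapse, hybrids, source merge.

test_that("standardize_name does exact normalized lookup", {
  cl <- fixture_checklist()
  expect_equal(standardize_name("Aus bus", cl), "Aus bus")
  expect_equal(standardize_name("Aus  bus   var.  cus", cl), "Aus bus")  # synonym row
  expect_true(is.na(standardize_name("Nonexistens plantae", cl)))
  # conflicting duplicate raw names are a checklist error
  bad <- rbind(cl, within(cl[1, ], accepted_name <- "Aus cus"))
  expect_error(standardize_name("Aus bus", bad), "conflicting")
})

test_that("apply_exclusions removes flagged taxa with logged reasons", {
  ex <- apply_exclusions(fixture_checklist())
  expect_setequal(ex$log$accepted_name, c("Aus dus", "Aus eus", "Aus fus"))
  expect_equal(ex$log$reason[ex$log$accepted_name == "Aus dus"], "cultivar")
  expect_equal(ex$log$reason[ex$log$accepted_name == "Aus fus"], "extinct")
  expect_false(any(c("Aus dus", "Aus eus", "Aus fus") %in%
                     ex$retained$accepted_name))
  expect_true("Aus bus" %in% ex$retained$accepted_name)
})

test_that("collapse_to_otu applies genus-collapse > aggregate > singleton precedence", {
  cl <- fixture_checklist()
  defs <- fixture_otu_defs()
  gc <- "Taraxacum"
  # all microspecies of a collapse genus land in one OTU
  got <- collapse_to_otu(c("Taraxacum unum", "Taraxacum duo", "Taraxacum tria"),
                         defs, gc, cl)
  expect_equal(unique(got), "Taraxacum sp.")
  # aggregate member
  expect_equal(collapse_to_otu("Bus alpha", defs, gc, cl), "Bus alpha agg.")
  # singleton labelled by the name itself
  expect_equal(collapse_to_otu("Bus gamma", defs, gc, cl), "Bus gamma")
  # subspecies folds into the parent species' OTU
  expect_equal(collapse_to_otu("Aus bus subsp. tus", defs, gc, cl), "Aus bus")
  # idempotent + deterministic
  expect_identical(got, collapse_to_otu(c("Taraxacum unum", "Taraxacum duo",
                                          "Taraxacum tria"), defs, gc, cl))
  # duplicate membership across OTUs is a definition error
  dup <- rbind(defs, data.frame(otu_id = "X agg.", label = "X agg.",
                                kind = "aggregate", member = "Bus alpha"))
  expect_error(collapse_to_otu("Bus alpha", dup, gc, cl), "more than one OTU")
})

test_that("hybrids resolve only when both parents share an aggregate", {
  defs <- fixture_otu_defs()
  expect_equal(resolve_hybrid(c("Bus alpha", "Bus beta"), defs), "Bus alpha agg.")
  expect_true(is.na(resolve_hybrid(c("Aus bus", "Bus gamma"), defs)))
  expect_true(is.na(resolve_hybrid(c(NA, NA), defs)))
  expect_true(is.na(resolve_hybrid("Bus alpha", defs)))
})

test_that("merge_sources has union semantics with provenance", {
  a <- data.frame(square_id = c("s1", "s1"), otu_id = c("o1", "o2"))
  p <- data.frame(square_id = c("s1", "s2"), otu_id = c("o1", "o3"))
  m <- merge_sources(a, p)
  expect_equal(nrow(m), 3L)
  both <- m[m$square_id == "s1" & m$otu_id == "o1", ]
  expect_true(both$atlas && both$plots)
  only_a <- m[m$otu_id == "o2", ]
  expect_true(only_a$atlas && !only_a$plots)
  # identity with an empty second source
  m0 <- merge_sources(a, a[0, ])
  expect_equal(nrow(m0), 2L)
  expect_true(all(m0$atlas) && !any(m0$plots))
  # commutative and idempotent on the presence set
  m_ab <- merge_sources(a, p)
  m_ba <- merge_sources(p, a)
  expect_equal(m_ab[, c("square_id", "otu_id")], m_ba[, c("square_id", "otu_id")])
  m_aa <- merge_sources(a, a)
  expect_equal(m_aa[, c("square_id", "otu_id")],
               m0[, c("square_id", "otu_id")])
  expect_error(merge_sources(a, p, known_squares = "s1"), "unknown square")
})

test_that("harmonize produces a consistent report and loses nothing silently", {
  cl <- fixture_checklist()
  defs <- fixture_otu_defs()
  spec <- grid_spec(n_rows = 2, n_cols = 2, cell_size = 10000)
  g <- build_grid(spec)
  atlas <- data.frame(
    square_id = c("AA00", "AA00", "AA01", "AA10", "AA00", "AA01", "AA00"),
    taxon = c("Aus bus", "Taraxacum unum", "Bus alpha", "Aus dus",
              "Bus xhybrida", "Cus xignota", "Ignota species"))
  h <- harmonize(atlas, NULL, cl, defs, "Taraxacum", spec)
  r <- h$report
  # partition identity of the overlap report
  expect_equal(r$n_in_both + r$n_atlas_only + r$n_plots_only, r$n_otus)
  expect_equal(r$n_unmatched_atlas, 1L)           # "Ignota species"
  expect_equal(r$n_excluded_by_flag$cultivar, 1L) # "Aus dus"
  expect_equal(r$n_excluded_hybrids, 1L)          # "Cus xignota"
  # resolvable hybrid folded into the aggregate
  expect_true("Bus alpha agg." %in% h$presence$otu_id)
  expect_false("Aus dus" %in% h$presence$otu_id)
  # hybrid_unresolved and flag exclusions appear in the log
  expect_setequal(unique(h$exclusion_log$reason),
                  c("cultivar", "ephemerophyte", "extinct", "hybrid_unresolved"))
  # harmonizing twice gives identical presence (idempotence)
  h2 <- harmonize(atlas, NULL, cl, defs, "Taraxacum", spec)
  expect_identical(h$presence, h2$presence)
})

test_that("plot records are assigned to squares through the projection", {
  cl <- fixture_checklist()
  spec <- grid_spec(n_rows = 2, n_cols = 2, cell_size = 10000)
  # a point in the middle of cell (row 1, col 0) = AA10
  ll <- planar_to_lonlat(5000, 15000, spec$crs)
  plots <- data.frame(plot_id = "p1", lon = ll$lon, lat = ll$lat,
                      year = 1999, taxon = "Aus bus")
  h <- harmonize(data.frame(square_id = character(0), taxon = character(0)),
                 plots, cl, fixture_otu_defs(), "Taraxacum", spec)
  expect_equal(h$presence$square_id, "AA10")
  expect_equal(h$presence$otu_id, "Aus bus")
  expect_true(h$presence$plots && !h$presence$atlas)
})

test_that("disjoint and identical sources give the expected overlap counts", {
  cl <- fixture_checklist()
  defs <- fixture_otu_defs()
  spec <- grid_spec(n_rows = 1, n_cols = 1)
  a <- data.frame(square_id = "AA00", taxon = "Aus bus")
  b_plot <- data.frame(plot_id = "p", lon = planar_to_lonlat(5e3, 5e3, spec$crs)$lon,
                       lat = planar_to_lonlat(5e3, 5e3, spec$crs)$lat,
                       year = 2000, taxon = "Bus gamma")
  h <- harmonize(a, b_plot, cl, defs, "Taraxacum", spec)
  expect_equal(h$report$n_in_both, 0L)
  same_plot <- within(b_plot, taxon <- "Aus bus")
  h2 <- harmonize(a, same_plot, cl, defs, "Taraxacum", spec)
  expect_equal(h2$report$n_atlas_only, 0L)
  expect_equal(h2$report$n_plots_only, 0L)
  expect_equal(h2$report$n_in_both, 1L)
})
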