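# Status propagation rules, conflict exclusion, frequency classes.

test_that("Red-List status propagates from species to subspecies", {
  st <- data.frame(
    accepted_name = c("Aus bus", "Aus bus subsp. unus", "Aus bus subsp. duo",
                      "Aus cus", "Aus cus subsp. tres"),
    status = "native",
    red_list = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    apophyte = FALSE)
  out <- propagate_red_list(st)
  expect_true(all(out$red_list[2:3]))
  expect_false(out$red_list[5])   # parent not Red List -> unchanged
  # no subspecies present -> identity
  st2 <- st[c(1, 4), ]
  expect_equal(propagate_red_list(st2)$red_list, st2$red_list)
})

test_that("a tiny non-Red-List minority is ignored (dominant Red List wins)", {
  # two-member aggregate: the Red-List member occupies ~99% of the squares
  sq_dom <- sprintf("s%03d", 1:99)
  res <- classify_otu(status = c("native", "native"),
                      red_list = c(TRUE, FALSE), apophyte = c(FALSE, FALSE),
                      squares = list(sq_dom, "s100"))
  expect_true(res$red_list)
  expect_equal(res$verdict, "KEPT")
})

test_that("a very rare Red-List member does not make the group Red List", {
  sq_dom <- sprintf("s%03d", 1:99)
  res <- classify_otu(status = c("native", "native"),
                      red_list = c(FALSE, TRUE), apophyte = c(FALSE, FALSE),
                      squares = list(sq_dom, "s100"))
  expect_false(res$red_list)
  expect_equal(res$verdict, "KEPT")
})

test_that("a substantial native/neophyte split excludes the OTU", {
  res <- classify_otu(status = c("native", "neophyte"),
                      red_list = c(FALSE, FALSE), apophyte = c(FALSE, FALSE),
                      squares = list(sprintf("a%02d", 1:60), sprintf("b%02d", 1:40)))
  expect_equal(res$verdict, "EXCLUDED_CONFLICT")
  expect_true(is.na(res$status))
})

test_that("the member-count criterion alone can excuse a minority", {
  # 21 members: 1 neophyte among 20 natives (4.8% <= 5% by count), but the
  # neophyte occupies many squares (fails the square criterion)
  squares <- c(lapply(1:20, function(i) sprintf("n%02d_%d", 1:3, i)),
               list(sprintf("x%02d", 1:30)))
  res <- classify_otu(status = c(rep("native", 20), "neophyte"),
                      red_list = rep(FALSE, 21), apophyte = rep(FALSE, 21),
                      squares = squares)
  expect_equal(res$verdict, "KEPT")
  expect_equal(res$status, "native")
})

test_that("tol = 0 reduces to strict unanimity", {
  # any mixed native/alien OTU is excluded
  res <- classify_otu(c("native", "neophyte"), c(FALSE, FALSE), c(FALSE, FALSE),
                      list(sprintf("a%02d", 1:99), "b1"), tol = 0)
  expect_equal(res$verdict, "EXCLUDED_CONFLICT")
  # any non-unanimous Red-List set resolves to FALSE
  res2 <- classify_otu(c("native", "native"), c(TRUE, FALSE), c(FALSE, FALSE),
                       list(sprintf("a%02d", 1:99), "b1"), tol = 0)
  expect_false(res2$red_list)
})

test_that("exact 50/50 dominance ties are conservative", {
  res <- classify_otu(c("native", "neophyte"), c(TRUE, FALSE), c(FALSE, FALSE),
                      squares = list(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10)))
  expect_equal(res$verdict, "EXCLUDED_CONFLICT")
  expect_false(res$red_list)
})

test_that("shrinking a minority never flips the OTU away from the dominant side", {
  dom <- sprintf("d%02d", 1:50)
  for (m in c(20, 10, 5, 2, 1)) {
    res <- classify_otu(c("native", "archeophyte"), c(FALSE, FALSE),
                        c(FALSE, FALSE),
                        squares = list(dom, sprintf("m%02d", seq_len(m))))
    expect_equal(res$status, "native")
  }
})

test_that("frequency classes use inclusive moderate endpoints", {
  expect_equal(frequency_class(3283, 3283), "common")
  expect_equal(frequency_class(1, 3283), "rare")
  # exactly 25% and 75% are moderate ("between 25% and 75%")
  expect_equal(frequency_class(100, 400), "moderate")
  expect_equal(frequency_class(300, 400), "moderate")
  expect_equal(frequency_class(301, 400), "common")
  expect_equal(frequency_class(99, 400), "rare")
  expect_error(frequency_class(1, 0), "positive")
  expect_error(frequency_class(10, 5), "n_occupied")
})

test_that("classify_otu matches the enumeration oracle on all small configurations", {
  # option space per member: status x Red List x occupied-square archetype
  sqsets <- list(q1 = "q01", q2 = "q02",
                 mid = sprintf("q%02d", 1:8),
                 wide = sprintf("q%02d", 1:38))
  opts <- expand.grid(status = c("native", "archeophyte", "neophyte"),
                      rl = c(TRUE, FALSE), sq = seq_along(sqsets),
                      stringsAsFactors = FALSE)
  n_opt <- nrow(opts)  # 24
  agree <- function(idx, tol) {
    status <- opts$status[idx]
    rl <- opts$rl[idx]
    ap <- rep(FALSE, length(idx))
    squares <- unname(sqsets[opts$sq[idx]])
    got <- classify_otu(status, rl, ap, squares, tol = tol)
    want <- oracle_classify(status, rl, ap, squares, tol = tol)
    identical(got, want)
  }
  # unordered member configurations with repetition, sizes 1-3
  configs <- c(lapply(seq_len(n_opt), identity),
               unlist(lapply(seq_len(n_opt), function(i) {
                 lapply(i:n_opt, function(j) c(i, j))
               }), recursive = FALSE),
               unlist(lapply(seq_len(n_opt), function(i) {
                 unlist(lapply(i:n_opt, function(j) {
                   lapply(j:n_opt, function(k) c(i, j, k))
                 }), recursive = FALSE)
               }), recursive = FALSE))
  for (tol in c(0, 0.05, 0.2)) {
    ok <- vapply(configs, agree, logical(1), tol = tol)
    expect_true(all(ok),
                info = paste("tol", tol, "- first mismatch at config",
                             which(!ok)[1]))
  }
})

test_that("classify_otus assigns one status and one frequency class per kept OTU", {
  sim <- small_sim(seed = 9)
  h <- harmonize(sim$atlas, sim$plots, sim$pool$checklist, sim$pool$otu_defs,
                 sim$pool$genus_collapse, sim$spec)
  asg <- classify_otus(h, sim$pool$status_table, n_total_squares = 64)
  kept <- asg[asg$verdict == "KEPT", ]
  expect_true(all(kept$status %in% c("native", "archeophyte", "neophyte")))
  expect_true(all(kept$freq_class %in% c("rare", "moderate", "common")))
  excl <- asg[asg$verdict == "EXCLUDED_CONFLICT", ]
  expect_true(all(is.na(excl$status)))
  # every OTU with occurrences got a verdict
  expect_setequal(asg$otu_id, unique(h$presence$otu_id))
})
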