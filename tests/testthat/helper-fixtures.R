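# Hand-built fixtures and independent oracles shared across test files.

fixture_checklist <- function() {
  data.frame(
    raw_name = c("Aus bus", "Aus bus var. cus", "Aus cus", "Aus dus",
                 "Aus eus", "Aus fus", "Aus bus subsp. tus",
                 "Bus alpha", "Bus beta", "Bus gamma",
                 "Taraxacum unum", "Taraxacum duo", "Taraxacum tria",
                 "Bus xhybrida", "Cus xignota"),
    accepted_name = c("Aus bus", "Aus bus", "Aus cus", "Aus dus",
                      "Aus eus", "Aus fus", "Aus bus subsp. tus",
                      "Bus alpha", "Bus beta", "Bus gamma",
                      "Taraxacum unum", "Taraxacum duo", "Taraxacum tria",
                      "Bus xhybrida", "Cus xignota"),
    rank = c("species", "species", "species", "species",
             "species", "species", "subspecies",
             "species", "species", "species",
             "species", "species", "species",
             "hybrid", "hybrid"),
    genus = c(rep("Aus", 7), rep("Bus", 3), rep("Taraxacum", 3), "Bus", "Cus"),
    family = c(rep("Aceae", 7), rep("Bceae", 3), rep("Asteraceae", 3),
               "Bceae", "Cceae"),
    flags = c("", "", "", "cultivar", "ephemerophyte", "extinct", "",
              "", "", "", "", "", "", "", ""),
    parent1 = c(rep(NA, 13), "Bus alpha", "Aus bus"),
    parent2 = c(rep(NA, 13), "Bus beta", "Bus gamma"),
    stringsAsFactors = FALSE
  )
}

fixture_otu_defs <- function() {
  data.frame(
    otu_id = c("Bus alpha agg.", "Bus alpha agg."),
    label = c("Bus alpha agg.", "Bus alpha agg."),
    kind = c("aggregate", "aggregate"),
    member = c("Bus alpha", "Bus beta"),
    stringsAsFactors = FALSE
  )
}

fixture_status <- function() {
  cl <- fixture_checklist()
  nm <- unique(cl$accepted_name)
  data.frame(
    accepted_name = nm,
    status = ifelse(grepl("^Taraxacum", nm), "native",
                    ifelse(nm %in% c("Aus cus"), "neophyte",
                           ifelse(nm %in% c("Aus dus"), "archeophyte", "native"))),
    red_list = nm %in% c("Bus alpha"),
    apophyte = nm %in% c("Aus bus"),
    stringsAsFactors = FALSE
  )
}

# independent re-implementation of the minority-propagation rules, written
# as plain candidate checking: for every category, test whether it can be
# "the" category (all other members ignorable under either criterion)
oracle_classify <- function(status, red_list, apophyte, squares, tol) {
  usq <- function(idx) unique(unlist(squares[idx]))
  total <- length(usq(seq_along(status)))
  decide <- function(vals) {
    cats <- sort(unique(vals))
    if (length(cats) == 1L) return(list(value = cats, conflict = FALSE))
    size <- sapply(cats, function(cc) length(usq(which(vals == cc))))
    cnt <- sapply(cats, function(cc) sum(vals == cc))
    best <- which(size == max(size))
    if (length(best) > 1L) best <- best[cnt[best] == max(cnt[best])]
    if (length(best) > 1L) return(list(value = NA_character_, conflict = TRUE))
    dom <- cats[best]
    minority <- which(vals != dom)
    ok_count <- length(minority) <= tol * length(vals)
    ok_sq <- length(usq(minority)) < tol * total
    list(value = dom, conflict = !(ok_count || ok_sq))
  }
  st <- decide(status)
  verdict <- "KEPT"
  if (st$conflict) {
    both_axes <- any(status %in% c("native", "archeophyte")) &&
      any(status == "neophyte")
    if (is.na(st$value) || both_axes) verdict <- "EXCLUDED_CONFLICT"
  }
  boolean <- function(v) {
    d <- decide(ifelse(v, "T", "F"))
    if (d$conflict || is.na(d$value)) FALSE else d$value == "T"
  }
  list(status = if (verdict == "KEPT") st$value else NA_character_,
       red_list = boolean(red_list), apophyte = boolean(apophyte),
       verdict = verdict)
}

# full-sort oracle for the wish list
oracle_wish <- function(presence, k) {
  pr <- unique(presence[, c("square_id", "otu_id")])
  cnt <- sapply(split(pr$square_id, pr$otu_id), function(s) length(unique(s)))
  ids <- names(cnt)[order(-cnt, names(cnt), method = "radix")]
  data.frame(otu_id = ids[seq_len(min(k, length(ids)))],
             n_squares = unname(cnt[ids[seq_len(min(k, length(ids)))]]),
             stringsAsFactors = FALSE)
}

# random presence table over synthetic ids
random_presence <- function(n_squares = 30, n_otus = 40, density = 0.2) {
  sq <- sprintf("sq%02d", seq_len(n_squares))
  ot <- sprintf("otu%02d", seq_len(n_otus))
  g <- expand.grid(square_id = sq, otu_id = ot, stringsAsFactors = FALSE)
  g[stats::runif(nrow(g)) < density, , drop = FALSE]
}

small_sim <- function(seed = 3, ...) {
  simulate_dataset(sim_config(seed = seed, grid_rows = 8L, grid_cols = 8L,
                              n_species = 80L, n_microspecies_genera = 1L,
                              microspecies_per_genus = 10L, n_aggregates = 4L,
                              n_hybrids = 2L, undersampled_squares = 4L,
                              plots_per_square_mean = 2, ...))
}
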