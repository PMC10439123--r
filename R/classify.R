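# Status classification of OTUs: native/archeophyte/neophyte status,
# Red-List and apophyte flags under minority-propagation rules, conflict
# exclusion, and frequency classes.
#
# The rules, applied per OTU over its member taxa:
#   1. A Red-List species confers Red-List status on all its subspecies
#      (propagate_red_list, run on the member status table first).
#   2. If all members agree (status, Red List), the OTU takes that value.
#   3. A minority is *ignored* when it is small by either criterion:
#      no more than `tol` of the members by count, OR occupying strictly
#      less than `tol` of all squares where the OTU was found.  The OTU is
#      then classified by the dominant category (largest occupied-square
#      union).
#   4. If native-side (native or archeophyte) and alien (neophyte) members
#      conflict and the minority exceeds `tol` on BOTH criteria, the OTU
#      cannot be categorized and is excluded (verdict EXCLUDED_CONFLICT).
#      Non-ignorable conflicts *within* the native side (native vs
#      archeophyte) resolve to the dominant category: both sides count as
#      native in downstream statistics, so categorization is not blocked.
#   5. Non-ignorable mixed Red-List or apophyte sets resolve to FALSE
#      (conservative: a unit is only flagged when the rule clearly says
#      so).  Exact dominance ties: EXCLUDED_CONFLICT for status, FALSE
#      for the boolean flags.

STATUS_LEVELS <- c("native", "archeophyte", "neophyte")

#' Propagate Red-List status from species to their subspecies
#'
#' Members are matched by name structure: an infraspecific taxon (rank
#' `subspecies` or `varietas`, or any name whose first two words form the
#' parent binomial) of a Red-List species becomes Red-List itself.
#'
#' @param status_table data.frame `accepted_name`, `status`, `red_list`
#'   (logical or 0/1), `apophyte`, optionally `rank`.
#' @return the table with `red_list` updated.
#' @export
propagate_red_list <- function(status_table) {
  st <- status_table
  st$red_list <- as.logical(st$red_list)
  nm <- normalize_name(st$accepted_name)
  parent <- binomial_of(nm)
  is_infra <- parent != nm & !grepl("agg\\.|s\\.l\\.", nm)
  rl_parents <- nm[st$red_list]
  st$red_list[is_infra & parent %in% rl_parents] <- TRUE
  st
}

# smallest occupied-square union among categories = the minority side.
# members: list of per-member square-id character vectors, grouped outside.
union_size <- function(squares) length(unique(unlist(squares, use.names = FALSE)))

# Decide a categorical attribute for one OTU.
# values: character vector (one per member); squares: list of square-id
# vectors. Returns list(value, conflict) where conflict=TRUE means no single
# category can be assigned.
dominant_category <- function(values, squares, tol) {
  cats <- unique(values)
  if (length(cats) == 1L) return(list(value = cats, conflict = FALSE))
  total_sq <- union_size(squares)
  cat_sq <- vapply(cats, function(c) union_size(squares[values == c]), integer(1))
  cat_n <- vapply(cats, function(c) sum(values == c), integer(1))
  best_sq <- max(cat_sq)
  top <- cats[cat_sq == best_sq]
  if (length(top) > 1L) {
    top_n <- cat_n[match(top, cats)]
    top <- top[top_n == max(top_n)]
  }
  if (length(top) > 1L) return(list(value = NA_character_, conflict = TRUE))
  dom <- top[1L]
  minority <- values != dom
  n_min <- sum(minority)
  min_sq <- union_size(squares[minority])
  ignorable <- (n_min <= tol * length(values)) || (min_sq < tol * total_sq)
  if (ignorable) return(list(value = dom, conflict = FALSE))
  list(value = dom, conflict = TRUE)
}

#' Classify one OTU from its member statuses and occupied squares
#'
#' Applies the minority-propagation rules (see the package vignette) to
#' the floristic status, Red-List flag and apophyte flag independently.
#'
#' @param status character vector, one of `"native"`, `"archeophyte"`,
#'   `"neophyte"` per member.
#' @param red_list,apophyte logical vectors per member.
#' @param squares list of character vectors: squares occupied by each
#'   member (within this OTU's records).
#' @param tol minority tolerance, default 0.05: a minority of no more than
#'   `tol` of members, or occupying under `tol` of the OTU's squares, is
#'   ignored.
#' @return list: `status`, `red_list`, `apophyte`, `verdict` (`"KEPT"` or
#'   `"EXCLUDED_CONFLICT"`).
#' @export
classify_otu <- function(status, red_list, apophyte, squares, tol = 0.05) {
  n <- length(status)
  if (n == 0L) stop("empty member set", call. = FALSE)
  stopifnot(length(red_list) == n, length(apophyte) == n, length(squares) == n)
  if (!all(status %in% STATUS_LEVELS)) {
    stop("status values must be one of: ", paste(STATUS_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  red_list <- as.logical(red_list)
  apophyte <- as.logical(apophyte)

  st <- dominant_category(status, squares, tol)
  verdict <- "KEPT"
  if (st$conflict) {
    present <- unique(status)
    native_side <- any(present %in% c("native", "archeophyte"))
    alien_side <- "neophyte" %in% present
    if (is.na(st$value) || (native_side && alien_side)) {
      # alien/native split too large to ignore, or an unresolvable tie
      verdict <- "EXCLUDED_CONFLICT"
    }
    # else: native vs archeophyte only -> dominant stands
  }

  bool_value <- function(v) {
    d <- dominant_category(ifelse(v, "yes", "no"), squares, tol)
    if (d$conflict || is.na(d$value)) FALSE else d$value == "yes"
  }

  list(status = if (verdict == "KEPT") st$value else NA_character_,
       red_list = bool_value(red_list),
       apophyte = bool_value(apophyte),
       verdict = verdict)
}

#' Frequency class of an OTU from its occupied-square count
#'
#' Relative frequency `f = n_occupied / n_total_squares`; common when
#' `f > 0.75`, rare when `f < 0.25`, moderate otherwise (both endpoints
#' inclusive to moderate).  The denominator is the full grid, not any
#' cleaned subset.
#'
#' @param n_occupied integer vector of occupied-square counts.
#' @param n_total_squares total squares in the grid (the full-scale
#'   reference uses 3283).
#' @return character vector in `c("rare", "moderate", "common")`.
#' @export
frequency_class <- function(n_occupied, n_total_squares = 3283) {
  if (n_total_squares <= 0) stop("n_total_squares must be positive", call. = FALSE)
  if (any(n_occupied < 0 | n_occupied > n_total_squares)) {
    stop("n_occupied must lie in [0, n_total_squares]", call. = FALSE)
  }
  f <- n_occupied / n_total_squares
  ifelse(f > 0.75, "common", ifelse(f < 0.25, "rare", "moderate"))
}

#' Classify every OTU of a harmonized data set
#'
#' Runs [propagate_red_list()] on the member status table, then
#' [classify_otu()] per OTU using member-level occupied squares from the
#' pre-collapse occurrence records, and assigns frequency classes from the
#' OTU-level occupied-square counts.
#'
#' @param harm a [harmonize()] result (or a list with `member_occ`,
#'   `otu_map`, `otu_table`, `presence`).
#' @param status_table data.frame `accepted_name`, `status`, `red_list`,
#'   `apophyte`.
#' @param tol minority tolerance (default 0.05).
#' @param n_total_squares frequency-class denominator: total grid squares.
#' @param force_exclude optional character vector of otu_ids to exclude
#'   regardless of the rules (expert override).
#' @return data.frame of class `status_assignment`: `otu_id`, `label`,
#'   `family`, `genus`, `status`, `red_list`, `apophyte`, `freq_class`,
#'   `verdict`.
#' @export
classify_otus <- function(harm, status_table, tol = 0.05,
                          n_total_squares, force_exclude = character(0)) {
  st <- propagate_red_list(status_table)
  st_key <- normalize_name(st$accepted_name)

  occ <- harm$member_occ
  occ$otu_id <- harm$otu_map$otu_id[match(normalize_name(occ$accepted_name),
                                          harm$otu_map$accepted_name)]
  # squares per member, grouped by OTU
  occ_split <- split(occ, occ$otu_id)

  otu_sq <- tapply(harm$presence$square_id, harm$presence$otu_id,
                   function(s) length(unique(s)))

  rows <- lapply(seq_len(nrow(harm$otu_table)), function(i) {
    id <- harm$otu_table$otu_id[i]
    memb <- occ_split[[id]]
    if (is.null(memb)) {
      return(NULL)  # OTU with no occurrence records: nothing to classify
    }
    members <- unique(memb$accepted_name)
    idx <- match(normalize_name(members), st_key)
    if (anyNA(idx)) {
      stop("no status entry for member(s): ",
           paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    squares <- lapply(members, function(m) memb$square_id[memb$accepted_name == m])
    cls <- classify_otu(st$status[idx], st$red_list[idx], st$apophyte[idx],
                        squares, tol = tol)
    if (id %in% force_exclude) cls$verdict <- "EXCLUDED_CONFLICT"
    n_occ <- as.integer(otu_sq[[id]])
    data.frame(
      otu_id = id,
      label = harm$otu_table$label[i],
      family = harm$otu_table$family[i],
      genus = harm$otu_table$genus[i],
      status = if (cls$verdict == "KEPT") cls$status else NA_character_,
      red_list = cls$red_list,
      apophyte = cls$apophyte,
      freq_class = if (cls$verdict == "KEPT") {
        frequency_class(n_occ, n_total_squares)
      } else NA_character_,
      verdict = cls$verdict,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("status_assignment", "data.frame")
  out
}
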