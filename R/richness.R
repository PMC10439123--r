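# Per-square richness statistics (the Species_richness schema) and
# subset summaries under the cross-boundary / sampling-bias filters.

# canonical output column order; internal names use _pct, serialization
# renames to the deposit's "_%" headers
RICHNESS_COLUMNS <- c(
  "Square_Id", "JSR",
  "NaS", "NaS_pct", "ReLS", "ReLS_pct", "NeS", "NeS_pct", "ArS", "ArS_pct",
  "ArNaS", "ArNaS_pct", "ApS", "ApS_pct",
  "RS", "RS_pct", "MS", "MS_pct", "CS", "CS_pct",
  "NG", "NF", "SB", "CBS"
)

RICHNESS_HEADERS <- c(
  "Square_Id", "JSR",
  "NaS", "NaS_%", "ReLS", "ReLS_%", "NeS", "NeS_%", "ArS", "ArS_%",
  "Ar+Na_S", "Ar+Na_S_%", "ApS", "ApS_%",
  "RS", "RS_%", "MS", "MS_%", "CS", "CS_%",
  "NG", "NF", "SB", "CBS"
)

#' Per-square richness statistics
#'
#' Computes, for every square of the grid (including empty ones), the
#' joined species richness JSR and its decomposition by floristic status
#' (NaS native, ArS archeophyte, NeS neophyte, ArNaS = ArS + NaS),
#' conservation (ReLS Red List), apophytes (ApS), frequency class (RS
#' rare, MS moderate, CS common), the number of genera (NG) and families
#' (NF), and the per-square flags SB (1 = adequately sampled) and CBS
#' (1 = more than 80% of area inside the territory).  Percentages are
#' `100 * count / JSR`, `NA` where `JSR = 0`, and are kept at full
#' precision (rounding happens only on serialization).
#'
#' OTUs excluded by the conflict rule must be removed beforehand: any OTU
#' in `presence` without a KEPT assignment raises an error.
#'
#' @param presence a [merge_sources()] presence table.
#' @param assignments a [classify_otus()] result.
#' @param square_ids character vector of all square ids in the grid.
#' @param sb,cbs named integer 0/1 vectors (names = square ids) or
#'   data.frames with `square_id` and `SB`/`CBS` columns; missing squares
#'   default to 1.
#' @return data.frame of class `square_stats` with the columns of the
#'   Species_richness schema, one row per square.
#' @export
compute_square_stats <- function(presence, assignments, square_ids,
                                 sb = NULL, cbs = NULL) {
  kept <- assignments[assignments$verdict == "KEPT", , drop = FALSE]
  pres <- presence[presence$otu_id %in% kept$otu_id, , drop = FALSE]
  missing <- setdiff(unique(presence$otu_id), assignments$otu_id)
  if (length(missing)) {
    stop("presence table contains OTU(s) without a status assignment: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }

  idx <- match(pres$otu_id, kept$otu_id)
  pres$status <- kept$status[idx]
  pres$red_list <- kept$red_list[idx]
  pres$apophyte <- kept$apophyte[idx]
  pres$freq_class <- kept$freq_class[idx]
  pres$genus <- kept$genus[idx]
  pres$family <- kept$family[idx]

  flag_vec <- function(f, default = 1L) {
    v <- stats::setNames(rep(default, length(square_ids)), square_ids)
    if (is.null(f)) return(v)
    if (is.data.frame(f)) {
      col <- intersect(c("SB", "CBS", "flag"), names(f))[1L]
      v[as.character(f$square_id)] <- as.integer(f[[col]])
    } else {
      v[names(f)] <- as.integer(f)
    }
    v
  }
  sb_v <- flag_vec(sb)
  cbs_v <- flag_vec(cbs)

  count_by <- function(cond) {
    t <- table(factor(pres$square_id[cond], levels = square_ids))
    as.integer(t)
  }
  jsr <- count_by(rep(TRUE, nrow(pres)))
  nas <- count_by(pres$status == "native")
  ars <- count_by(pres$status == "archeophyte")
  nes <- count_by(pres$status == "neophyte")
  rels <- count_by(pres$red_list)
  aps <- count_by(pres$apophyte)
  rs <- count_by(pres$freq_class == "rare")
  ms <- count_by(pres$freq_class == "moderate")
  cs <- count_by(pres$freq_class == "common")
  ng <- as.integer(tapply(pres$genus, factor(pres$square_id, levels = square_ids),
                          function(g) length(unique(g)), default = 0L))
  nf <- as.integer(tapply(pres$family, factor(pres$square_id, levels = square_ids),
                          function(g) length(unique(g)), default = 0L))

  pct <- function(count) ifelse(jsr > 0, 100 * count / jsr, NA_real_)

  out <- data.frame(
    Square_Id = square_ids,
    JSR = jsr,
    NaS = nas, NaS_pct = pct(nas),
    ReLS = rels, ReLS_pct = pct(rels),
    NeS = nes, NeS_pct = pct(nes),
    ArS = ars, ArS_pct = pct(ars),
    ArNaS = ars + nas, ArNaS_pct = pct(ars + nas),
    ApS = aps, ApS_pct = pct(aps),
    RS = rs, RS_pct = pct(rs),
    MS = ms, MS_pct = pct(ms),
    CS = cs, CS_pct = pct(cs),
    NG = ng, NF = nf,
    SB = as.integer(sb_v[square_ids]), CBS = as.integer(cbs_v[square_ids]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("square_stats", "data.frame")
  out
}

#' Summary statistics for a subset of squares
#'
#' Reproduces the three-regime overview (entire data set / without
#' cross-boundary squares / clean): square count, joined richness (distinct
#' OTUs present in at least one square of the subset), and the mean, min
#' and max of per-square JSR.  The mean is reported both raw and rounded
#' half-up to an integer, the convention used when such overview tables
#' print whole numbers.
#'
#' @param stats a [compute_square_stats()] result.
#' @param presence the presence table the stats were computed from (only
#'   KEPT OTUs contribute to joined richness).
#' @param keep logical vector over `stats` rows, or a character vector of
#'   square ids, selecting the subset.
#' @return list of class `subset_summary`: `n_squares`, `joined_richness`,
#'   `mean_jsr`, `mean_jsr_rounded`, `min_jsr`, `max_jsr`; all `NA` (with
#'   `n_squares = 0`) for an empty subset.
#' @export
summarize_subset <- function(stats, presence, keep = rep(TRUE, nrow(stats))) {
  if (is.character(keep)) keep <- stats$Square_Id %in% keep
  ids <- stats$Square_Id[keep]
  if (length(ids) == 0L) {
    out <- list(n_squares = 0L, joined_richness = NA_integer_, mean_jsr = NA_real_,
                mean_jsr_rounded = NA_integer_, min_jsr = NA_integer_,
                max_jsr = NA_integer_)
    class(out) <- "subset_summary"
    return(out)
  }
  jsr <- stats$JSR[keep]
  rich <- length(unique(presence$otu_id[presence$square_id %in% ids]))
  m <- mean(jsr)
  out <- list(
    n_squares = length(ids),
    joined_richness = rich,
    mean_jsr = m,
    mean_jsr_rounded = as.integer(floor(m + 0.5)),
    min_jsr = min(jsr),
    max_jsr = max(jsr)
  )
  class(out) <- "subset_summary"
  out
}

#' @export
print.subset_summary <- function(x, ...) {
  if (x$n_squares == 0L) {
    cat("subset summary: empty subset\n")
    return(invisible(x))
  }
  cat(sprintf("squares: %d; joined richness: %d; JSR mean %s (%.2f), range %d-%d\n",
              x$n_squares, x$joined_richness, x$mean_jsr_rounded, x$mean_jsr,
              x$min_jsr, x$max_jsr))
  invisible(x)
}
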