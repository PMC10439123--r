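# Benchmark-species ("wish list") undersampling detection.
#
# Rationale: the most frequent species of a national data set are found
# essentially everywhere, so a square from which several of them are
# missing was very probably undersurveyed rather than genuinely poor.

#' Build the wish list of benchmark species
#'
#' The `k` OTUs with the largest occupied-square counts, ordered by
#' frequency descending with ties broken lexicographically by otu_id
#' (deterministic).  An optional exclusion list stands in for the expert
#' screening of candidates whose range or niche genuinely excludes parts
#' of the territory.
#'
#' @param presence a presence table (`square_id`, `otu_id`).
#' @param k list length, default 20.
#' @param exclude otu_ids never admitted to the list.
#' @return data.frame of class `wish_list`: `otu_id`, `n_squares`, ordered
#'   by rank.
#' @export
build_wish_list <- function(presence, k = 20, exclude = character(0)) {
  if (is.null(presence) || nrow(presence) == 0L) {
    stop("presence table is empty", call. = FALSE)
  }
  pr <- unique(data.frame(square_id = presence$square_id,
                          otu_id = presence$otu_id, stringsAsFactors = FALSE))
  pr <- pr[!(pr$otu_id %in% exclude), , drop = FALSE]
  counts <- table(pr$otu_id)
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  ids <- names(counts)[ord]
  n <- as.integer(counts)[ord]
  if (length(ids) < k) {
    warning("fewer OTUs (", length(ids), ") than requested wish-list length ", k)
    k <- length(ids)
  }
  out <- data.frame(otu_id = ids[seq_len(k)], n_squares = n[seq_len(k)],
                    stringsAsFactors = FALSE)
  class(out) <- c("wish_list", "data.frame")
  out
}

#' Flag potentially undersampled squares
#'
#' A square missing `m` or more wish-list species is considered
#' undersampled (SB = 0); squares missing fewer keep SB = 1.  Flags are
#' emitted for every square of the grid, including empty ones.
#'
#' @param presence a presence table.
#' @param wish a [build_wish_list()] result (or data.frame with `otu_id`).
#' @param square_ids all square ids to flag.
#' @param m minimum number of missing wish-list species that triggers the
#'   flag; default 3.
#' @return data.frame `square_id`, `n_missing`, `SB`.
#' @export
flag_undersampled <- function(presence, wish, square_ids, m = 3) {
  wl <- unique(wish$otu_id)
  pr <- presence[presence$otu_id %in% wl, , drop = FALSE]
  have <- tapply(pr$otu_id, factor(pr$square_id, levels = square_ids),
                 function(o) length(unique(o)), default = 0L)
  n_missing <- length(wl) - as.integer(have)
  data.frame(square_id = square_ids,
             n_missing = n_missing,
             SB = as.integer(n_missing < m),
             stringsAsFactors = FALSE)
}
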