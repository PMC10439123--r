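# Taxonomic harmonization: checklist standardization, exclusion rules,
# collapse into operational taxonomic units (OTUs), hybrid resolution, and
# the merge of atlas and plot occurrences into one presence table.
#
# Contracts (all plain data.frames):
#   checklist:  raw_name, accepted_name, rank, genus, family, flags
#               (semicolon-separated subset of cultivar/ephemerophyte/
#               extinct/preliminarily_accepted); optional parent1, parent2
#               for hybrid rows.
#   otu_defs:   otu_id, label, kind (aggregate | sensu_lato), member
#               (one row per member accepted name).
#   occurrences: atlas (square_id, taxon); plots (plot_id, lon, lat, year,
#               taxon).
# No record is dropped silently: every exclusion carries a reason in the
# exclusion log, and unmatched names are counted in the report.

EXCLUSION_FLAGS <- c("cultivar", "ephemerophyte", "extinct")

#' Normalize a taxon name for checklist matching
#'
#' Matching is exact on a normalized key: trimmed, internal whitespace
#' collapsed, the hybrid sign unified.  No fuzzy matching — a lookup either
#' hits the checklist or is reported UNMATCHED; inventing near-matches
#' would invent occurrences.
#'
#' @param x character vector of raw names.
#' @return normalized names.
#' @export
normalize_name <- function(x) {
  x <- gsub("×", "x", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# split "a;b" flag strings into a list of character vectors
split_flags <- function(flags) {
  flags[is.na(flags)] <- ""
  strsplit(flags, ";", fixed = TRUE)
}

has_flag <- function(flags, flag) {
  vapply(split_flags(flags), function(f) flag %in% trimws(f), logical(1))
}

check_checklist <- function(checklist) {
  need <- c("raw_name", "accepted_name", "rank", "genus", "family", "flags")
  miss <- setdiff(need, names(checklist))
  if (length(miss)) {
    stop("checklist is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- normalize_name(checklist$raw_name)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    for (k in dup) {
      acc <- unique(checklist$accepted_name[key == k])
      if (length(acc) > 1L) {
        stop("checklist maps raw name '", k, "' to conflicting accepted names: ",
             paste(acc, collapse = " / "), call. = FALSE)
      }
    }
  }
  invisible(checklist)
}

#' Standardize raw taxon names against a checklist
#'
#' @param raw_name character vector of raw names as recorded in a source.
#' @param checklist checklist data.frame (see package overview for schema).
#' @return character vector of accepted names; `NA` for names absent from
#'   the checklist (UNMATCHED — the caller reports them, never drops them
#'   silently).
#' @export
standardize_name <- function(raw_name, checklist) {
  check_checklist(checklist)
  key <- normalize_name(checklist$raw_name)
  idx <- match(normalize_name(raw_name), key)
  # accepted names are valid keys too, even without an explicit synonym row
  acc_idx <- match(normalize_name(raw_name), normalize_name(checklist$accepted_name))
  out <- checklist$accepted_name[idx]
  out[is.na(out)] <- checklist$accepted_name[acc_idx[is.na(out)]]
  out
}

#' Remove cultivars, ephemerophytes and extinct taxa from a checklist
#'
#' Cultivated and casual taxa reflect human decisions rather than ecology,
#' and regionally extinct taxa no longer contribute to standing richness;
#' all three classes are dropped before any counting, each with a logged
#' reason.
#'
#' @param checklist checklist data.frame.
#' @return list with `retained` (checklist subset) and `log` (data.frame
#'   `accepted_name`, `reason`, one row per excluded entry).
#' @export
apply_exclusions <- function(checklist) {
  check_checklist(checklist)
  reason <- rep(NA_character_, nrow(checklist))
  for (fl in EXCLUSION_FLAGS) {
    hit <- has_flag(checklist$flags, fl) & is.na(reason)
    reason[hit] <- fl
  }
  excl <- !is.na(reason)
  list(
    retained = checklist[!excl, , drop = FALSE],
    log = data.frame(accepted_name = checklist$accepted_name[excl],
                     reason = reason[excl], stringsAsFactors = FALSE)
  )
}

check_otu_defs <- function(otu_defs) {
  need <- c("otu_id", "label", "kind", "member")
  miss <- setdiff(need, names(otu_defs))
  if (length(miss)) {
    stop("otu_defs is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- otu_defs$member[duplicated(otu_defs$member)]
  if (length(dup)) {
    stop("accepted name(s) assigned to more than one OTU definition: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(otu_defs)
}

genus_otu_id <- function(genus) paste(genus, "sp.")

binomial_of <- function(name) {
  parts <- strsplit(normalize_name(name), " ", fixed = TRUE)
  vapply(parts, function(p) paste(p[seq_len(min(2L, length(p)))], collapse = " "),
         character(1))
}

#' Collapse accepted names into operational taxonomic units
#'
#' Precedence per name: (1) its genus is on the genus-collapse list (the
#' microspecies genera treated wholesale at genus level) -> the genus OTU;
#' (2) it is a member of a defined aggregate / sensu-lato group -> that
#' OTU; (3) it is an infraspecific taxon (subspecies/varietas) whose parent
#' species resolves under (1)-(2) or to a singleton -> the parent's OTU;
#' (4) otherwise a singleton OTU labelled by the name itself.
#'
#' @param accepted_name character vector of standardized names.
#' @param otu_defs OTU definition table.
#' @param genus_collapse character vector of genera collapsed wholesale.
#' @param checklist checklist (for genus and rank lookup).
#' @return character vector of OTU ids (same length as input).
#' @export
collapse_to_otu <- function(accepted_name, otu_defs, genus_collapse, checklist) {
  check_otu_defs(otu_defs)
  acc_key <- normalize_name(checklist$accepted_name)
  name <- normalize_name(accepted_name)
  i <- match(name, acc_key)
  genus <- checklist$genus[i]
  rank <- checklist$rank[i]
  # fall back to the first word when a name is not a checklist accepted name
  genus[is.na(genus)] <- vapply(strsplit(name[is.na(genus)], " "), `[`, character(1), 1L)

  out <- rep(NA_character_, length(name))
  collapse <- genus %in% genus_collapse
  out[collapse] <- genus_otu_id(genus[collapse])

  member_idx <- match(name, normalize_name(otu_defs$member))
  in_def <- is.na(out) & !is.na(member_idx)
  out[in_def] <- otu_defs$otu_id[member_idx[in_def]]

  # infraspecific taxa not covered by any definition fold into the parent
  infra <- is.na(out) & !is.na(rank) & rank %in% c("subspecies", "varietas")
  if (any(infra)) {
    parent <- binomial_of(name[infra])
    out[infra] <- collapse_to_otu(parent, otu_defs, genus_collapse, checklist)
  }
  out[is.na(out)] <- name[is.na(out)]
  out
}

#' Resolve a hybrid to an existing aggregate, or exclude it
#'
#' Hybrids are not species-level taxa and are excluded — unless an
#' aggregate or sensu-lato group already exists that contains *both*
#' parental taxa, in which case the hybrid's records are folded into that
#' group.
#'
#' @param parents character vector of length 2 (accepted parent names), or
#'   anything shorter/NA when parents are unknown.
#' @param otu_defs OTU definition table.
#' @return the OTU id, or `NA` (excluded, reason "hybrid_unresolved").
#' @export
resolve_hybrid <- function(parents, otu_defs) {
  check_otu_defs(otu_defs)
  parents <- parents[!is.na(parents) & nzchar(parents)]
  if (length(parents) != 2L) return(NA_character_)
  grp <- otu_defs[otu_defs$kind %in% c("aggregate", "sensu_lato"), , drop = FALSE]
  o1 <- grp$otu_id[match(normalize_name(parents[1L]), normalize_name(grp$member))]
  o2 <- grp$otu_id[match(normalize_name(parents[2L]), normalize_name(grp$member))]
  if (!is.na(o1) && !is.na(o2) && o1 == o2) o1 else NA_character_
}

#' Merge atlas- and plot-derived square-level occurrences
#'
#' Union semantics: one confirmed locality in either source fills the
#' square.  Provenance is kept per (square, OTU) pair.
#'
#' @param atlas_occ,plot_occ data.frames with columns `square_id`,
#'   `otu_id` (duplicates allowed; rows beyond the first are redundant).
#' @param known_squares optional character vector; square ids outside it
#'   raise an error.
#' @return data.frame of class `presence_table`: `square_id`, `otu_id`,
#'   logical `atlas`, `plots`.
#' @export
merge_sources <- function(atlas_occ, plot_occ, known_squares = NULL) {
  take <- function(d) {
    if (is.null(d) || nrow(d) == 0L) {
      return(data.frame(square_id = character(0), otu_id = character(0)))
    }
    unique(data.frame(square_id = as.character(d$square_id),
                      otu_id = as.character(d$otu_id), stringsAsFactors = FALSE))
  }
  a <- take(atlas_occ)
  p <- take(plot_occ)
  if (!is.null(known_squares)) {
    bad <- setdiff(unique(c(a$square_id, p$square_id)), known_squares)
    if (length(bad)) {
      stop("unknown square id(s): ", paste(utils::head(bad, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  key_a <- paste(a$square_id, a$otu_id, sep = "\r")
  key_p <- paste(p$square_id, p$otu_id, sep = "\r")
  all_key <- union(key_a, key_p)
  parts <- strsplit(all_key, "\r", fixed = TRUE)
  out <- data.frame(
    square_id = vapply(parts, `[`, character(1), 1L),
    otu_id = vapply(parts, `[`, character(1), 2L),
    atlas = all_key %in% key_a,
    plots = all_key %in% key_p,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$square_id, out$otu_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("presence_table", "data.frame")
  out
}

# Map raw occurrence records to (square_id, accepted_name), with exclusion
# accounting. Returns list(records, n_raw, n_unmatched, excluded counts).
standardize_source <- function(square_id, taxon, checklist, exclusions) {
  raw <- normalize_name(taxon)
  accepted <- standardize_name(raw, checklist)
  unmatched <- is.na(accepted)
  excl_reason <- exclusions$log$reason[match(accepted, exclusions$log$accepted_name)]
  keep <- !unmatched & is.na(excl_reason)
  list(
    records = unique(data.frame(square_id = square_id[keep],
                                accepted_name = accepted[keep],
                                stringsAsFactors = FALSE)),
    n_raw = length(unique(raw)),
    n_unmatched = length(unique(raw[unmatched])),
    excluded = table(excl_reason[!unmatched & !is.na(excl_reason)])
  )
}

#' Harmonize both occurrence sources into one OTU presence table
#'
#' Runs the full harmonization chain: name standardization against the
#' checklist, exclusion of cultivars/ephemerophytes/extinct taxa, hybrid
#' resolution, OTU collapse, plot-to-square assignment, and the
#' atlas/plot merge.  Every removal is logged; the report carries the
#' source-overlap accounting.
#'
#' @param atlas_occ data.frame `square_id`, `taxon`.
#' @param plot_occ data.frame `plot_id`, `lon`, `lat`, `year`, `taxon`
#'   (long format, one row per species-in-plot); may be `NULL`.
#' @param checklist,otu_defs,genus_collapse see [collapse_to_otu()].
#' @param spec a [grid_spec()]; used to assign plot coordinates (WGS 84
#'   lon/lat, reprojected internally) to squares.
#' @return list of class `harmonization` with elements `presence`
#'   ([merge_sources()] output), `member_occ` (square x accepted-name
#'   records, pre-collapse, for status classification), `otu_table`
#'   (otu_id, label, kind, genus, family), `otu_map` (accepted_name ->
#'   otu_id), `report` (see [harmonization_report()]), `exclusion_log`.
#' @export
harmonize <- function(atlas_occ, plot_occ, checklist, otu_defs, genus_collapse,
                      spec) {
  check_checklist(checklist)
  check_otu_defs(otu_defs)
  excl <- apply_exclusions(checklist)

  atl <- standardize_source(as.character(atlas_occ$square_id), atlas_occ$taxon,
                            checklist, excl)

  if (!is.null(plot_occ) && nrow(plot_occ) > 0L) {
    pl_xy <- lonlat_to_planar(plot_occ$lon, plot_occ$lat, spec$crs)
    pl_sq <- assign_point(pl_xy$x, pl_xy$y, spec)
    ok <- !is.na(pl_sq)
    plt <- standardize_source(pl_sq[ok], plot_occ$taxon[ok], checklist, excl)
  } else {
    plt <- standardize_source(character(0), character(0), checklist, excl)
  }

  # hybrid handling: resolvable hybrids map to their aggregate, the rest are
  # excluded with a logged reason
  hyb <- checklist[checklist$rank == "hybrid", , drop = FALSE]
  hybrid_map <- character(0)
  hybrid_excluded <- character(0)
  if (nrow(hyb)) {
    p1 <- if ("parent1" %in% names(hyb)) hyb$parent1 else rep(NA_character_, nrow(hyb))
    p2 <- if ("parent2" %in% names(hyb)) hyb$parent2 else rep(NA_character_, nrow(hyb))
    res <- vapply(seq_len(nrow(hyb)), function(i) {
      resolve_hybrid(c(p1[i], p2[i]), otu_defs)
    }, character(1))
    hybrid_map <- stats::setNames(res, normalize_name(hyb$accepted_name))
    hybrid_excluded <- names(hybrid_map)[is.na(hybrid_map)]
    hybrid_map <- hybrid_map[!is.na(hybrid_map)]
  }

  map_records <- function(rec) {
    if (nrow(rec) == 0L) {
      return(list(pairs = data.frame(square_id = character(0), otu_id = character(0)),
                  records = rec))
    }
    nm <- normalize_name(rec$accepted_name)
    bad <- nm %in% hybrid_excluded
    rec <- rec[!bad, , drop = FALSE]
    nm <- nm[!bad]
    otu <- rep(NA_character_, length(nm))
    hyb_hit <- nm %in% names(hybrid_map)
    otu[hyb_hit] <- hybrid_map[nm[hyb_hit]]
    otu[!hyb_hit] <- collapse_to_otu(nm[!hyb_hit], otu_defs, genus_collapse,
                                     checklist)
    list(pairs = unique(data.frame(square_id = rec$square_id, otu_id = otu,
                                   stringsAsFactors = FALSE)),
         records = rec)
  }
  atl_m <- map_records(atl$records)
  plt_m <- map_records(plt$records)

  presence <- merge_sources(atl_m$pairs, plt_m$pairs)
  member_occ <- unique(rbind(atl_m$records, plt_m$records))
  rownames(member_occ) <- NULL

  otu_table <- build_otu_table(unique(presence$otu_id), otu_defs, genus_collapse,
                               checklist)

  exclusion_log <- rbind(
    excl$log,
    if (length(hybrid_excluded)) {
      data.frame(accepted_name = hybrid_excluded, reason = "hybrid_unresolved",
                 stringsAsFactors = FALSE)
    }
  )

  report <- harmonization_report(atl, plt, atl_m$pairs, plt_m$pairs, excl,
                                 hybrid_excluded)

  structure(list(presence = presence, member_occ = member_occ,
                 otu_table = otu_table,
                 otu_map = otu_map_table(member_occ$accepted_name, hybrid_map,
                                         otu_defs, genus_collapse, checklist),
                 report = report, exclusion_log = exclusion_log),
            class = "harmonization")
}

# accepted_name -> otu_id lookup covering hybrids
otu_map_table <- function(accepted_names, hybrid_map, otu_defs, genus_collapse,
                          checklist) {
  nm <- unique(normalize_name(accepted_names))
  otu <- character(length(nm))
  hyb <- nm %in% names(hybrid_map)
  otu[hyb] <- hybrid_map[nm[hyb]]
  otu[!hyb] <- collapse_to_otu(nm[!hyb], otu_defs, genus_collapse, checklist)
  data.frame(accepted_name = nm, otu_id = otu, stringsAsFactors = FALSE)
}

# per-OTU label/kind/genus/family; aggregates inherit the genus of their
# members, genus-collapse OTUs count as one genus
build_otu_table <- function(otu_ids, otu_defs, genus_collapse, checklist) {
  acc_key <- normalize_name(checklist$accepted_name)
  genus_of <- function(name) {
    g <- checklist$genus[match(normalize_name(name), acc_key)]
    if (is.na(g)) strsplit(normalize_name(name), " ")[[1]][1] else g
  }
  fam_map <- unique(checklist[, c("genus", "family")])
  rows <- lapply(sort(otu_ids), function(id) {
    if (id %in% otu_defs$otu_id) {
      def <- otu_defs[otu_defs$otu_id == id, , drop = FALSE]
      genus <- unique(vapply(def$member, genus_of, character(1)))
      genus <- genus[1L]
      kind <- def$kind[1L]
      label <- def$label[1L]
    } else if (id %in% genus_otu_id(genus_collapse)) {
      genus <- sub(" sp.", "", id, fixed = TRUE)
      kind <- "genus_collapse"
      label <- id
    } else {
      genus <- genus_of(id)
      kind <- "species"
      label <- id
    }
    family <- fam_map$family[match(genus, fam_map$genus)]
    data.frame(otu_id = id, label = label, kind = kind, genus = genus,
               family = ifelse(is.na(family), "Unknown", family),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Harmonization audit report
#'
#' Counts raw names per source, unmatched names, exclusions by reason, and
#' the OTU-level overlap between sources.  The overlap satisfies the
#' partition identity `n_in_both + n_atlas_only + n_plots_only = n_otus`.
#'
#' @keywords internal
harmonization_report <- function(atl, plt, atlas_pairs, plot_pairs, excl,
                                 hybrid_excluded) {
  a_otus <- unique(atlas_pairs$otu_id)
  p_otus <- unique(plot_pairs$otu_id)
  excl_counts <- vapply(EXCLUSION_FLAGS, function(fl) {
    sum(excl$log$reason == fl)
  }, integer(1))
  list(
    n_raw_atlas = atl$n_raw,
    n_raw_plots = plt$n_raw,
    n_unmatched_atlas = atl$n_unmatched,
    n_unmatched_plots = plt$n_unmatched,
    n_excluded_by_flag = as.list(excl_counts),
    n_excluded_hybrids = length(hybrid_excluded),
    n_after_checklist = length(unique(c(atl$records$accepted_name,
                                        plt$records$accepted_name))),
    n_otus = length(union(a_otus, p_otus)),
    n_in_both = length(intersect(a_otus, p_otus)),
    n_atlas_only = length(setdiff(a_otus, p_otus)),
    n_plots_only = length(setdiff(p_otus, a_otus))
  )
}

#' @export
print.harmonization <- function(x, ...) {
  r <- x$report
  cat("Harmonized occurrence data\n")
  cat(sprintf("  raw names: atlas %d, plots %d (unmatched: %d / %d)\n",
              r$n_raw_atlas, r$n_raw_plots, r$n_unmatched_atlas, r$n_unmatched_plots))
  cat(sprintf("  OTUs: %d (both sources %d, atlas only %d, plots only %d)\n",
              r$n_otus, r$n_in_both, r$n_atlas_only, r$n_plots_only))
  cat(sprintf("  presence records: %d\n", nrow(x$presence)))
  invisible(x)
}
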