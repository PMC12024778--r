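# Vegetation survey processing: Braun-Blanquet cover conversion,
# flowering phenology weighting, weekly nectariferous potential, and
# the observation-to-LUU assignment feeding the HPP engine.

#' Weeks of the monitored flowering season
#'
#' Phenology is monitored over ISO weeks 10 to 34 (March to August);
#' weeks outside this axis are treated as non-flowering.
#'
#' @return Integer vector 10:34.
#' @export
hpp_weeks <- function() 10:34

#' Convert a Braun-Blanquet class to percent cover
#'
#' Midpoint quantification of the abundance-dominance scale:
#' r = 0.1, + = 0.5, 1 = 2.5, 2 = 15, 3 = 37.5, 4 = 62.5, 5 = 87.5
#' percent.
#'
#' @param bb_class character vector of classes in
#'   `c("r", "+", "1", "2", "3", "4", "5")`.
#' @return Numeric percent cover.
#' @examples
#' cover_rate(c("r", "3", "5"))
#' @export
cover_rate <- function(bb_class) {
  map <- c(r = 0.1, `+` = 0.5, `1` = 2.5, `2` = 15, `3` = 37.5,
           `4` = 62.5, `5` = 87.5)
  out <- map[as.character(bb_class)]
  if (anyNA(out))
    stop("unknown Braun-Blanquet class: ",
         paste(unique(bb_class[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Phenology calendars as a taxon-by-week phase matrix
#'
#' Expands a long phenology table (taxon, week, phase over flowering
#' weeks) into a character matrix over the full week axis, `"none"`
#' where a taxon does not flower.
#'
#' @param phenology data frame with columns `taxon`, `week`, `phase`
#'   (`"early"`, `"full"` or `"late"`; optionally explicit `"none"`).
#' @param taxa optional taxa to include (rows); defaults to those
#'   present in `phenology`.
#' @return Character matrix, rownames taxa, colnames weeks 10-34.
#' @export
phenology_calendar <- function(phenology, taxa = NULL) {
  stopifnot(all(c("taxon", "week", "phase") %in% names(phenology)))
  bad <- setdiff(unique(phenology$phase),
                 c("none", "early", "full", "late"))
  if (length(bad)) stop("unknown phenophase: ", paste(bad, collapse = ", "))
  if (is.null(taxa)) taxa <- sort(unique(phenology$taxon))
  wk <- hpp_weeks()
  cal <- matrix("none", nrow = length(taxa), ncol = length(wk),
                dimnames = list(taxa, wk))
  keep <- phenology$taxon %in% taxa & phenology$week %in% wk
  ph <- phenology[keep, ]
  cal[cbind(match(ph$taxon, taxa), match(ph$week, wk))] <- ph$phase
  cal
}

#' Flowering duration Sf in weeks
#'
#' @param calendar a matrix from [phenology_calendar()].
#' @return Named integer vector: number of weeks with phase != none.
#' @export
flowering_duration <- function(calendar) {
  apply(calendar, 1L, function(p) sum(p != "none"))
}

#' Flowering intensity of a phenophase
#'
#' If = 0 outside flowering, 0.5 in the early and late phases, 1 at
#' full flowering.
#'
#' @param phase character vector of phenophases.
#' @return Numeric vector in `{0, 0.5, 1}`.
#' @export
flowering_intensity <- function(phase) {
  map <- c(none = 0, early = 0.5, full = 1, late = 0.5)
  out <- map[phase]
  if (anyNA(out))
    stop("unknown phenophase: ",
         paste(unique(phase[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Weekly nectariferous potential of a taxon
#'
#' pnht = (pnt / Sf) * If(week): the annual potential spread uniformly
#' over the flowering weeks and damped by the flowering intensity, so
#' the season total never exceeds the annual potential (with equality
#' only when every flowering week is at full bloom).
#'
#' @param pnt annual nectariferous potential, kg/ha.
#' @param calendar one taxon's calendar: named character vector of
#'   phases over weeks (names are week numbers), or a 1-row matrix.
#' @param week week number(s) in 10-34.
#' @return pnht in kg/ha/week.
#' @examples
#' cal <- setNames(c("early", "full", "full", "late"), 20:23)
#' weekly_nectar_potential(100, cal, 20:23)   # 12.5 25 25 12.5
#' @export
weekly_nectar_potential <- function(pnt, calendar, week) {
  if (is.matrix(calendar)) calendar <- calendar[1L, ]
  sf <- sum(calendar != "none")
  if (sf == 0L) {
    if (pnt > 0) stop("inconsistent calendar: Sf = 0 with nonzero pnt")
    return(rep(0, length(week)))
  }
  phase <- ifelse(as.character(week) %in% names(calendar),
                  calendar[as.character(week)], "none")
  pnt / sf * flowering_intensity(phase)
}

#' Assign observation plots to every LUU
#'
#' Every LUU containing at least one plot uses its own plots. A
#' plot-less LUU borrows the nearest plot (LUU centroid to plot
#' distance); by default only plots lying on LUUs of the same LUS are
#' eligible, which preserves community coherence. If no plot exists
#' anywhere on the LUU's LUS (habitation and non-maize cropfields are
#' never surveyed), the LUU gets an empty set and a zero HPP.
#'
#' @param landscape a [landscape()].
#' @param plots data frame with columns `plot_id`, `x`, `y`, `luu_id`.
#' @param same_lus_only logical; if `FALSE` the nearest plot of any LUS
#'   may be borrowed.
#' @return Named list, one element per LUU (luu_id), each a character
#'   vector of plot_ids (possibly empty).
#' @export
assign_observations <- function(landscape, plots, same_lus_only = TRUE) {
  stopifnot(inherits(landscape, "landscape"))
  ids <- vapply(landscape$luus, `[[`, character(1), "luu_id")
  lus <- luu_lus(landscape)
  plot_lus <- lus[match(plots$luu_id, ids)]
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    own <- plots$plot_id[plots$luu_id == ids[i]]
    if (length(own)) { out[[i]] <- own; next }
    cand <- if (same_lus_only) which(plot_lus == lus[[i]])
            else seq_len(nrow(plots))
    if (length(cand) == 0L) { out[[i]] <- character(0); next }
    cen <- landscape$luus[[i]]$centroid
    d2 <- (plots$x[cand] - cen[1])^2 + (plots$y[cand] - cen[2])^2
    out[[i]] <- plots$plot_id[cand[which.min(d2)]]
  }
  out
}

#' Per-LUU taxon cover from assigned plots
#'
#' For each LUU, the cover rate Rt of every taxon is the mean percent
#' cover over the LUU's assigned plots, counting absence on a plot as
#' zero cover.
#'
#' @param assignments output of [assign_observations()].
#' @param records data frame `plot_id`, `taxon`, `bb_class`.
#' @return Data frame `luu_id`, `taxon`, `Rt_pct` (taxa with zero mean
#'   cover omitted).
#' @export
luu_cover <- function(assignments, records) {
  rows <- lapply(names(assignments), function(id) {
    pl <- assignments[[id]]
    if (length(pl) == 0L) return(NULL)
    sub <- records[records$plot_id %in% pl, ]
    if (nrow(sub) == 0L) return(NULL)
    tot <- tapply(cover_rate(sub$bb_class), sub$taxon, sum)
    data.frame(luu_id = id, taxon = names(tot),
               Rt_pct = as.numeric(tot) / length(pl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(luu_id = character(0), taxon = character(0),
                      Rt_pct = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Species richness by land-use class
#'
#' Total species (union over the class's plots) and mean +/- SD species
#' per plot, per LUS.
#'
#' @param plots data frame with `plot_id` and `lus`.
#' @param records data frame with `plot_id` and `taxon`.
#' @return Data frame `lus`, `total_species`, `mean_per_plot`,
#'   `sd_per_plot`, `n_plots`.
#' @export
richness_summary <- function(plots, records) {
  lus_present <- intersect(lus_levels(), unique(plots$lus))
  rows <- lapply(lus_present, function(l) {
    pl <- plots$plot_id[plots$lus == l]
    sub <- records[records$plot_id %in% pl, ]
    per_plot <- vapply(pl, function(p)
      length(unique(sub$taxon[sub$plot_id == p])), integer(1))
    data.frame(lus = l,
               total_species = length(unique(sub$taxon)),
               mean_per_plot = mean(per_plot),
               sd_per_plot = if (length(per_plot) > 1L)
                 stats::sd(per_plot) else 0,
               n_plots = length(pl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
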