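#' vulA-to-vulA distance series
#'
#' The AP distance between the outer vulA junctions, tracked over time, is the
#' standard measure of vulval cell migration towards the midline; it declines
#' as morphogenesis proceeds. Time points missing either junction yield `NA`
#' (a gap in the series), not a failure. The field-standard long-term
#' acquisition interval is 15 min.
#'
#' @param landmarks_t list of per-timepoint landmark lists, each with `vulA1`
#'   and `vulA2` as `(ap, dv)` positions (other roles optional).
#' @param times_h optional time stamps in hours.
#' @return data.frame `time_h` (when given), `distance_um`.
#' @export
vulA_distance <- function(landmarks_t, times_h = NULL) {
  d <- vapply(landmarks_t, function(lm) {
    if (is.null(lm$vulA1) || is.null(lm$vulA2)) return(NA_real_)
    abs(lm$vulA2[1] - lm$vulA1[1])
  }, numeric(1))
  if (is.null(times_h)) data.frame(distance_um = d)
  else data.frame(time_h = times_h, distance_um = d)
}

#' Per-group median trend of a distance series
#'
#' @param tab data.frame with columns `group`, `time_h`, `distance_um`.
#' @return data.frame `group`, `time_h`, `median_um`, `n`.
#' @export
distance_trend <- function(tab) {
  agg <- aggregate(distance_um ~ group + time_h, data = tab,
                   FUN = median, na.action = stats::na.omit)
  names(agg)[names(agg) == "distance_um"] <- "median_um"
  n <- aggregate(distance_um ~ group + time_h, data = tab,
                 FUN = function(x) sum(!is.na(x)))
  agg$n <- n$distance_um
  agg[order(agg$group, agg$time_h), ]
}

#' Delay between AC fusion and dorsal lumen expansion
#'
#' `Delta_t` is the period between the last time point before the beginning of
#' AC fusion (reporter diffusion into neighbouring uterine cells) and the
#' first time point at which the dorsal adherens-junction ring starts to
#' expand. Both events are manual annotations.
#'
#' @param annotation data.frame (or list) with `animal_id`, `t_pre_fusion_h`
#'   and `t_expansion_h`; a missing `t_expansion_h` (NA) flags the animal as
#'   "no expansion observed".
#' @return data.frame `animal_id`, `delta_t_h`, `flag`.
#' @export
lumen_expansion_delay <- function(annotation) {
  annotation <- as.data.frame(annotation)
  need <- c("animal_id", "t_pre_fusion_h", "t_expansion_h")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  bad <- !is.na(annotation$t_expansion_h) &
    annotation$t_expansion_h < annotation$t_pre_fusion_h
  if (any(bad))
    stop("t_expansion_h precedes t_pre_fusion_h for: ",
         paste(annotation$animal_id[bad], collapse = ", "))
  data.frame(
    animal_id = annotation$animal_id,
    delta_t_h = annotation$t_expansion_h - annotation$t_pre_fusion_h,
    flag = ifelse(is.na(annotation$t_expansion_h),
                  "no expansion observed", ""))
}

#' Actin-ring occupancy and classification
#'
#' Quantitative proxy for by-eye actin-ring classes at the AC-vulF interphase:
#' thresholded signal inside an annulus around `center` is assigned to angular
#' bins; the occupancy is the fraction of occupied bins, and the ring class
#' follows documented cut-offs — `complete` (occupancy >= 0.9), `semicircle`
#' (0.5-0.9), `disorganized` (0-0.5), `absent` (0).
#'
#' @param ventral_image 2D image of the ventrally oriented AC-vulF contact
#'   site, `(y, x)` pixels.
#' @param center ring centre `(y, x)` in pixels.
#' @param r_in,r_out annulus radii in pixels, `r_out > r_in > 0`.
#' @param n_bins number of angular bins.
#' @param level threshold (fraction of image maximum) for occupied pixels.
#' @param cutoffs named numeric `(complete, semicircle)` occupancy cut-offs.
#' @return list with `occupancy`, `ring_class` and the per-bin occupation.
#' @export
ring_occupancy <- function(ventral_image, center, r_in, r_out, n_bins = 36L,
                           level = 0.05,
                           cutoffs = c(complete = 0.9, semicircle = 0.5)) {
  stopifnot(r_out > r_in, r_in > 0)
  d <- dim(ventral_image)
  if (center[1] - r_out < 1 || center[1] + r_out > d[1] ||
      center[2] - r_out < 1 || center[2] + r_out > d[2])
    stop("annulus extends outside the image")
  if (max(ventral_image) <= 0)
    return(list(occupancy = 0, ring_class = "absent",
                bins = rep(FALSE, n_bins)))
  mask <- binarize(ventral_image, mode = "fixed-normalized", level = level)
  dy <- row(ventral_image) - center[1]
  dx <- col(ventral_image) - center[2]
  r <- sqrt(dy^2 + dx^2)
  in_annulus <- r >= r_in & r <= r_out
  occupied_px <- in_annulus & mask
  if (!any(occupied_px))
    return(list(occupancy = 0, ring_class = "absent",
                bins = rep(FALSE, n_bins)))
  theta <- atan2(dy[occupied_px], dx[occupied_px])
  bin <- pmin(floor((theta + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  bins <- seq_len(n_bins) %in% bin
  occ <- mean(bins)
  cls <- if (occ >= cutoffs[["complete"]]) "complete"
    else if (occ >= cutoffs[["semicircle"]]) "semicircle"
    else "disorganized"
  list(occupancy = occ, ring_class = cls, bins = bins)
}

#' Fraction of animals in positive ring classes
#'
#' Percentage of animals of a given stage and genotype whose ring class is in
#' `positive_classes` (by default a complete ring or a semicircle), with the
#' Wilson 95% confidence interval. Percentages are rounded to the nearest
#' integer for reporting; the raw fraction is retained.
#'
#' @param table data.frame with columns `genotype`, `stage`, `ring_class`.
#' @param stage,genotype stratum selectors.
#' @param positive_classes character vector of classes counted as positive.
#' @return data.frame `genotype`, `stage`, `k`, `n`, `fraction`, `percent`,
#'   `ci_lo`, `ci_hi`.
#' @export
class_fraction <- function(table, stage, genotype,
                           positive_classes = c("complete", "semicircle")) {
  sel <- table$stage == stage & table$genotype == genotype
  n <- sum(sel)
  if (n == 0) stop("zero animals in stratum ", genotype, " / ", stage)
  k <- sum(table$ring_class[sel] %in% positive_classes)
  ci <- proportion_ci(k, n)
  data.frame(genotype = genotype, stage = stage, k = k, n = n,
             fraction = k / n, percent = round(100 * k / n),
             ci_lo = ci$lo, ci_hi = ci$hi)
}
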