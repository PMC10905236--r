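# Months covered by each survey season window. May belongs to both spring
# and summer because the spring-migration and summer-breeding windows
# overlap in May.
SEASON_MONTHS <- list(
  winter = c(11L, 12L, 1L),
  spring = c(3L, 4L, 5L),
  summer = c(5L, 6L, 7L),
  fall = c(8L, 9L, 10L)
)

#' Classify species into urban-tolerance tertiles
#'
#' Averages monthly species-level urban-tolerance scores over the months of
#' the seasons in which each species was detected, then classifies species
#' by rank tertiles of the community score distribution: scores at or below
#' the 0.33 quantile are "urban sensitive", above 0.33 up to the 0.66
#' quantile "urban neutral", above it "urban tolerant" (boundary ties go to
#' the lower class; quantiles use linear interpolation). Species without
#' any score are labeled "unscored" and excluded from subset richness.
#'
#' @param scores Data frame with columns `species_id`, `month` (1-12),
#'   `score`; missing months are allowed.
#' @param detected_seasons Data frame with columns `species_id`, `season`
#'   listing the seasons each species was detected in.
#' @return Data frame (species_id, mean_score, class) of class
#'   `tolerance_table`, with the quantile boundaries as attribute
#'   `boundaries`.
#' @export
classify_tolerance <- function(scores, detected_seasons) {
  stopifnot(all(c("species_id", "month", "score") %in% names(scores)),
            all(c("species_id", "season") %in% names(detected_seasons)))
  spp <- unique(detected_seasons$species_id)
  mean_score <- vapply(spp, function(sp) {
    seasons <- detected_seasons$season[detected_seasons$species_id == sp]
    months <- unique(unlist(SEASON_MONTHS[seasons]))
    ss <- scores[scores$species_id == sp & scores$month %in% months, ]
    if (!nrow(ss) || all(is.na(ss$score))) return(NA_real_)
    mean(ss$score, na.rm = TRUE)
  }, 0)
  scored <- !is.na(mean_score)
  if (!any(scored)) stop("no scored species")
  q <- quantile(mean_score[scored], c(0.33, 0.66), type = 7, names = FALSE)
  cls <- ifelse(!scored, "unscored",
                ifelse(mean_score <= q[1], "urban sensitive",
                       ifelse(mean_score <= q[2], "urban neutral",
                              "urban tolerant")))
  out <- data.frame(species_id = spp, mean_score = mean_score, class = cls,
                    row.names = NULL)
  attr(out, "boundaries") <- q
  class(out) <- c("tolerance_table", "data.frame")
  out
}

#' Species in a given tolerance class
#'
#' @param tolerance A `tolerance_table` from [classify_tolerance()].
#' @param class Tolerance class label.
#' @return Character vector of species ids.
#' @export
tolerance_subset <- function(tolerance, class) {
  tolerance$species_id[tolerance$class == class]
}
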